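#' Cross-correlogram of two spike trains
#'
#' For every spike of the reference train, target spikes within +/-2 ms
#' are accumulated into 0.1 ms lag bins (lag = target time - reference
#' time, so positive lags mean the target fires after the reference).
#'
#' @param reference,target [spike_train()] objects; both must be
#'   non-empty.
#' @param window half-width of the lag window (s), default 2 ms.
#' @param bin lag bin width (s), default 0.1 ms.
#' @return object of class `correlogram`: `reference_id`, `target_id`,
#'   `breaks` (bin edges, s), `centers_ms`, `counts`, `peak_lag_ms`
#'   (centre of the fullest bin, earliest on ties), `peak_count`.
#' @export
cross_correlogram <- function(reference, target, window = 0.002, bin = 1e-4) {
  if (length(reference$times) == 0 || length(target$times) == 0)
    stop(sprintf("empty spike train in pair (%s, %s)",
                 reference$electrode_id, target$electrode_id))
  breaks <- seq(-window, window, by = bin)
  nb <- length(breaks) - 1
  tt <- target$times
  counts <- integer(nb)
  for (r in reference$times) {
    lo <- findInterval(r - window, tt) + 1
    hi <- findInterval(r + window, tt)
    if (hi < lo) next
    lag <- tt[lo:hi] - r
    k <- floor((lag + window) / bin) + 1
    k <- k[k >= 1 & k <= nb]
    if (length(k)) counts <- counts + tabulate(k, nbins = nb)
  }
  centers_ms <- (breaks[-1] - bin / 2) * 1000
  pk <- which.max(counts)
  structure(list(reference_id = reference$electrode_id,
                 target_id = target$electrode_id,
                 breaks = breaks, centers_ms = centers_ms,
                 counts = counts, peak_lag_ms = centers_ms[pk],
                 peak_count = counts[pk]),
            class = "correlogram")
}

#' Direction call from a tunnel-pair correlogram
#'
#' Compares the largest bin on the positive-lag side against the largest
#' on the negative-lag side (the two bins straddling lag zero are
#' excluded). The larger side is called FORWARD/BACKWARD when its peak is
#' significant against the flat baseline; otherwise UNDECIDED. At the
#' sparse-count regime of spontaneous recordings a normal z-score against
#' a baseline of a fraction of a count is invalid, so significance uses
#' the exact Poisson upper tail at the one-sided level corresponding to
#' `min_peak_z` normal standard deviations, Bonferroni-corrected over the
#' tested bins; at high counts this reduces to the familiar z rule.
#'
#' @param cc a [cross_correlogram()] result.
#' @param min_peak_z significance level expressed in normal sd units
#'   (default 3).
#' @param separation_um electrode separation used for the conduction
#'   velocity (um; default 200).
#' @return object of class `direction_call`: `direction` (`"FORWARD"`,
#'   `"BACKWARD"` or `"UNDECIDED"`), `peak_lag_ms`, `velocity_mps`
#'   (`separation / |peak lag|`, NA when undecided), `peak_count`,
#'   `baseline`, `p_value`.
#' @export
classify_direction <- function(cc, min_peak_z = 3, separation_um = 200) {
  bin_ms <- diff(cc$centers_ms[1:2])
  pos <- which(cc$centers_ms > bin_ms)      # exclude the two near-zero bins
  neg <- which(cc$centers_ms < -bin_ms)
  tested <- c(neg, pos)
  # flat-baseline rate over all tested bins; the peak bin is deliberately
  # included so an otherwise empty correlogram cannot yield a zero baseline
  # (which would declare any single chance coincidence significant)
  baseline <- mean(cc$counts[tested])
  p_pos <- pos[which.max(cc$counts[pos])]
  p_neg <- neg[which.max(cc$counts[neg])]
  undecided <- function(p) structure(
    list(direction = "UNDECIDED", peak_lag_ms = NA_real_,
         velocity_mps = NA_real_, peak_count = max(cc$counts[tested]),
         baseline = baseline, p_value = p), class = "direction_call")
  if (cc$counts[p_pos] == cc$counts[p_neg]) return(undecided(NA_real_))
  win <- if (cc$counts[p_pos] > cc$counts[p_neg]) p_pos else p_neg
  pval <- ppois(cc$counts[win] - 1, max(baseline, 1e-12), lower.tail = FALSE)
  if (pval > pnorm(-min_peak_z) / length(tested)) return(undecided(pval))
  lag_ms <- cc$centers_ms[win]
  structure(list(direction = if (lag_ms > 0) "FORWARD" else "BACKWARD",
                 peak_lag_ms = lag_ms,
                 velocity_mps = separation_um * 1e-6 / (abs(lag_ms) * 1e-3),
                 peak_count = cc$counts[win], baseline = baseline,
                 p_value = pval), class = "direction_call")
}

#' Bin a spike train at 1 ms and smooth with a causal exponential kernel
#'
#' Counts per `bin` are convolved with `exp(-t/tau)` for `t >= 0`,
#' truncated at `8 * tau` and normalized to unit sum, so the series of a
#' train with N spikes sums to N (up to edge truncation).
#'
#' @param train a [spike_train()].
#' @param bin bin width (s), default 1 ms.
#' @param tau kernel time constant (s), default 4 ms.
#' @return numeric series covering `[t_start, t_stop)`.
#' @export
bin_and_smooth <- function(train, bin = 0.001, tau = 0.004) {
  n <- ceiling((train$t_stop - train$t_start) / bin)
  kern <- exp(-seq(0, 8 * tau, by = bin) / tau)
  kern <- kern / sum(kern)
  y <- numeric(n)
  if (length(train$times) == 0) return(y)
  b <- floor((train$times - train$t_start) / bin) + 1
  for (bi in b) {
    idx <- bi:min(bi + length(kern) - 1, n)
    y[idx] <- y[idx] + kern[seq_along(idx)]
  }
  y
}

#' Multichannel panel of smoothed spike series
#'
#' @param recording an `mea_recording`.
#' @param electrodes electrode ids to include (default: all non-empty
#'   trains).
#' @param duration optional cap on the analysed span (s), e.g. 120 for
#'   the standard 2-min connectivity window.
#' @inheritParams bin_and_smooth
#' @return numeric matrix, one column per electrode.
#' @export
recording_to_panel <- function(recording, electrodes = NULL, bin = 0.001,
                               tau = 0.004, duration = NULL) {
  trains <- recording$trains
  if (is.null(electrodes))
    electrodes <- names(trains)[vapply(trains, length, 1L) > 0]
  t_stop <- if (is.null(duration)) recording$t_stop
            else min(recording$t_stop, recording$t_start + duration)
  cols <- lapply(electrodes, function(e) {
    tr <- trains[[e]]
    tr <- spike_train(tr$times[tr$times < t_stop], e, tr$unit_id,
                      recording$t_start, t_stop)
    bin_and_smooth(tr, bin, tau)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- electrodes
  m
}

#' Least-squares VAR fit with per-source reduced models
#'
#' Fits, for every target channel, the full regression on `order` lags of
#' all channels plus an intercept, and for every candidate source the
#' reduced regression omitting that source's lags while conditioning on
#' every remaining channel.
#'
#' @param panel numeric matrix (time x channels).
#' @param order number of lags.
#' @return list: `rss_full` (per target), `rss_reduced` (source x target
#'   matrix), `coef` (full-model coefficients), `n_obs`, `k_full`
#'   (regressors in the full model), `order`.
#' @export
fit_mvar <- function(panel, order = 10) {
  panel <- as.matrix(panel)
  nch <- ncol(panel); nt <- nrow(panel)
  if (nt <= nch * order + order + 1)
    stop("panel too short for the requested VAR order")
  bad <- which(apply(panel, 2, stats::var) == 0)
  if (length(bad))
    stop("zero-variance channel(s): ",
         paste(colnames(panel)[bad] %||% bad, collapse = ", "))
  y_rows <- (order + 1):nt
  X <- cbind(1, do.call(cbind, lapply(seq_len(order), function(l)
    panel[y_rows - l, , drop = FALSE])))
  # column j of channel c at lag l sits at 1 + (l-1)*nch + c
  Y <- panel[y_rows, , drop = FALSE]
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X))
    stop("rank-deficient regressor matrix (collinear channels); ",
         "consider fewer lags or dropping channels")
  res_full <- qr.resid(qr_full, Y)
  rss_full <- colSums(res_full^2)
  coef_full <- qr.coef(qr_full, Y)
  rss_reduced <- matrix(NA_real_, nch, nch,
                        dimnames = list(colnames(panel), colnames(panel)))
  for (s in seq_len(nch)) {
    drop_cols <- 1 + (seq_len(order) - 1) * nch + s
    qr_red <- qr(X[, -drop_cols, drop = FALSE])
    rss_reduced[s, ] <- colSums(qr.resid(qr_red, Y)^2)
  }
  list(rss_full = rss_full, rss_reduced = rss_reduced, coef = coef_full,
       n_obs = length(y_rows), k_full = ncol(X), order = order)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conditional Granger causality network
#'
#' For every ordered channel pair (source -> target), the conditional
#' Granger statistic is `ln(RSS_reduced / RSS_full)` where the reduced
#' model omits the source's lags while conditioning on all remaining
#' channels (so mediated influences are compensated). Significance comes
#' from the F statistic of the nested regressions, with Benjamini-
#' Hochberg adjustment across all ordered pairs. With two channels the
#' measure degenerates to pairwise Granger causality.
#'
#' @param panel time x channels matrix (see [recording_to_panel()]).
#' @param order VAR model order in bins (default 10, i.e. 10 ms at 1 ms
#'   bins).
#' @param p_threshold p-value below which an edge enters the adjacency
#'   (default 1e-4).
#' @param use_adjusted threshold on BH-adjusted p-values (default) or on
#'   raw p-values.
#' @return object of class `cgc_network`: `cgc`, `p`, `p_adj` (source x
#'   target matrices, diagonal NA), `adjacency` (logical), `order`,
#'   `nonstationary` (channels failing a split-half variance heuristic).
#' @export
conditional_granger <- function(panel, order = 10, p_threshold = 1e-4,
                                use_adjusted = TRUE) {
  panel <- as.matrix(panel)
  nch <- ncol(panel)
  if (nch < 2) stop("need at least 2 channels")
  fit <- fit_mvar(panel, order)
  cgc <- p <- matrix(NA_real_, nch, nch,
                     dimnames = dimnames(fit$rss_reduced))
  dfe <- fit$n_obs - fit$k_full
  for (s in seq_len(nch)) for (t in seq_len(nch)) {
    if (s == t) next
    rss_r <- fit$rss_reduced[s, t]; rss_f <- fit$rss_full[t]
    cgc[s, t] <- max(log(rss_r / rss_f), 0)
    f <- ((rss_r - rss_f) / order) / (rss_f / dfe)
    p[s, t] <- pf(max(f, 0), order, dfe, lower.tail = FALSE)
  }
  off <- !is.na(p)
  adj_p <- p
  adj_p[off] <- bh_fdr(p[off])$p_adjusted
  thr_p <- if (use_adjusted) adj_p else p
  adjacency <- !is.na(thr_p) & thr_p < p_threshold
  half <- floor(nrow(panel) / 2)
  v1 <- apply(panel[seq_len(half), , drop = FALSE], 2, stats::var)
  v2 <- apply(panel[(half + 1):nrow(panel), , drop = FALSE], 2, stats::var)
  ratio <- pmax(v1, v2) / pmax(pmin(v1, v2), 1e-12)
  nonstat <- colnames(panel)[ratio > 5] %||% which(ratio > 5)
  if (length(nonstat))
    warning("possible non-stationarity on channel(s): ",
            paste(nonstat, collapse = ", "))
  structure(list(cgc = cgc, p = p, p_adj = adj_p, adjacency = adjacency,
                 order = order, p_threshold = p_threshold,
                 use_adjusted = use_adjusted, nonstationary = nonstat),
            class = "cgc_network")
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up rule: with ordered p-values `p(1) <= ... <= p(m)`,
#' reject hypotheses `1..i*` where `i*` is the largest `i` with
#' `p(i) <= i * alpha / m`. Adjusted p-values are the monotone
#' `min_{j >= i} m * p(j) / j`, capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha target false-discovery rate (default 0.05).
#' @return list: `reject` (logical, original order), `p_adjusted`,
#'   `n_rejected`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  m <- length(pvalues)
  ord <- order(pvalues)
  ranked <- pvalues[ord]
  crit <- seq_len(m) * alpha / m
  below <- which(ranked <= crit)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  adj <- rev(cummin(rev(m * ranked / seq_len(m))))
  adj <- pmin(adj, 1)
  p_adjusted <- numeric(m)
  p_adjusted[ord] <- adj
  list(reject = reject, p_adjusted = p_adjusted, n_rejected = sum(reject))
}

#' Degree and reciprocity statistics of a directed graph
#'
#' @param network a `cgc_network` (its `adjacency` is used) or a logical
#'   adjacency matrix (source x target).
#' @param layout optional [make_layout()]; when given and the node names
#'   are electrode ids, per-region mean degrees are reported.
#' @return list of class `graph_stats`: `nodes` (data.frame with
#'   `in_degree`, `out_degree`, `degree`), `n_edges`,
#'   `reciprocity_pct` (share of directed edges whose reverse exists),
#'   `mean_degree`, `mean_in`, `mean_out`, `per_region` (optional),
#'   `empty` flag.
#' @export
graph_statistics <- function(network, layout = NULL) {
  adj <- if (inherits(network, "cgc_network")) network$adjacency else network
  adj <- as.matrix(adj); diag(adj) <- FALSE
  ids <- colnames(adj) %||% as.character(seq_len(ncol(adj)))
  out_deg <- rowSums(adj); in_deg <- colSums(adj)
  nodes <- data.frame(node = ids, in_degree = in_deg, out_degree = out_deg,
                      degree = in_deg + out_deg, row.names = NULL)
  n_edges <- sum(adj)
  recip <- if (n_edges > 0) 100 * sum(adj & t(adj)) / n_edges else NA_real_
  per_region <- NULL
  if (!is.null(layout)) {
    reg <- layout$electrodes$region[match(ids, layout$electrodes$electrode_id)]
    if (!anyNA(reg))
      per_region <- aggregate(nodes[c("in_degree", "out_degree", "degree")],
                              list(region = reg), mean)
  }
  structure(list(nodes = nodes, n_edges = n_edges, reciprocity_pct = recip,
                 mean_degree = mean(nodes$degree), mean_in = mean(in_deg),
                 mean_out = mean(out_deg), per_region = per_region,
                 empty = n_edges == 0), class = "graph_stats")
}
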
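#' Victor-Purpura spike-train distance
#'
#' Minimum total cost of editing one spike train into the other, where
#' inserting or deleting a spike costs 1 and shifting a spike by `dt`
#' costs `q * |dt|`. The cost parameter `q` (1/s) sets the timescale of
#' the comparison: at `q = 0` the distance reduces to the spike-count
#' difference (pure rate code), at large `q` non-coincident spikes are
#' cheaper to delete and re-insert than to shift (temporal code); the
#' reported scale is `1/q` in ms.
#'
#' @param x,y [spike_train()] objects or numeric vectors of spike times
#'   (s). Empty trains are allowed.
#' @param q shift cost per unit time (1/s), `q >= 0`.
#' @return the distance, a number in `[0, n_x + n_y]`.
#' @export
vp_distance <- function(x, y, q) {
  stopifnot(q >= 0)
  tx <- if (inherits(x, "spike_train")) x$times else sort(as.numeric(x))
  ty <- if (inherits(y, "spike_train")) y$times else sort(as.numeric(y))
  vp_distance_cpp(tx, ty, q)
}

#' Victor-Purpura similarity
#'
#' The distance normalized by the summed spike counts and inverted:
#' `S = 1 - D / (n_x + n_y)`, so 1 means identical and 0 maximally
#' dissimilar. Two empty trains are defined as identical (`S = 1`) and
#' flagged degenerate via the `"degenerate"` attribute.
#'
#' @inheritParams vp_distance
#' @return similarity in `[0, 1]` (attribute `degenerate` = TRUE for the
#'   empty-empty case).
#' @export
vp_similarity <- function(x, y, q) {
  tx <- if (inherits(x, "spike_train")) x$times else sort(as.numeric(x))
  ty <- if (inherits(y, "spike_train")) y$times else sort(as.numeric(y))
  n <- length(tx) + length(ty)
  if (n == 0) return(structure(1, degenerate = TRUE))
  1 - vp_distance_cpp(tx, ty, q) / n
}

#' van Rossum similarity (Pearson-correlation variant)
#'
#' Both trains are binned at 1 ms over a common window and convolved with
#' the causal exponential kernel `exp(-t/tau_R)` (truncated at
#' `8 * tau_R`, unit sum); the similarity is the Pearson correlation of
#' the two series, clamped below at 0 so it ranges from 0 (dissimilar)
#' to 1 (similar). If either series is constant (e.g. an empty train) the
#' similarity is 0 with a `degenerate` attribute; the unclamped
#' correlation is kept in the `raw` attribute.
#'
#' @inheritParams vp_distance
#' @param tau_r kernel time constant (s), `> 0`.
#' @param window common analysis window `c(start, stop)` (s); defaults to
#'   the span of the inputs when they are [spike_train()] objects.
#' @param bin bin width (s), default 1 ms.
#' @param subset_windows optional two-column matrix of `[start, end)`
#'   windows; the correlation is then computed only over bins whose
#'   centres fall inside their union (used for the in-burst /
#'   between-burst split, where shared silence outside the windows must
#'   not inflate the correlation).
#' @return similarity in `[0, 1]` with attributes `raw` and `degenerate`.
#' @export
vr_similarity <- function(x, y, tau_r, window = NULL, bin = 0.001,
                          subset_windows = NULL) {
  stopifnot(tau_r > 0)
  if (is.null(window)) {
    if (!inherits(x, "spike_train") || !inherits(y, "spike_train"))
      stop("window required when inputs are bare time vectors")
    window <- c(min(x$t_start, y$t_start), max(x$t_stop, y$t_stop))
  }
  if (window[2] <= window[1]) stop("zero-length analysis window")
  tx <- if (inherits(x, "spike_train")) x$times else as.numeric(x)
  ty <- if (inherits(y, "spike_train")) y$times else as.numeric(y)
  sx <- spike_train(tx[tx >= window[1] & tx < window[2]],
                    t_start = window[1], t_stop = window[2])
  sy <- spike_train(ty[ty >= window[1] & ty < window[2]],
                    t_start = window[1], t_stop = window[2])
  fx <- bin_and_smooth(sx, bin, tau_r)
  fy <- bin_and_smooth(sy, bin, tau_r)
  if (!is.null(subset_windows)) {
    centers <- window[1] + (seq_along(fx) - 0.5) * bin
    w <- normalize_windows(subset_windows)
    keep <- rep(FALSE, length(centers))
    for (i in seq_len(nrow(w)))
      keep <- keep | (centers >= w[i, 1] & centers < w[i, 2])
    fx <- fx[keep]; fy <- fy[keep]
  }
  if (length(fx) < 2 || sd(fx) == 0 || sd(fy) == 0)
    return(structure(0, raw = NA_real_, degenerate = TRUE))
  r <- cor(fx, fy)
  structure(max(r, 0), raw = r, degenerate = FALSE)
}

#' Transmission-fidelity profile of a recording
#'
#' Sweeps the Victor-Purpura similarity (scale `1/q`) and the van Rossum
#' similarity (scale `tau_R`) over a grid of timescales, for electrode
#' pairs split by pairing class (between layers, within Layer I, within
#' Layer II; tunnel electrodes excluded) and window class: IN_BURST uses
#' the union of the matched-overlap windows of the propagation events,
#' OUT_BURST its complement within the recording. Per-pair similarities
#' are averaged into a per-recording composite at each scale, and regime
#' means summarize scales above 50 ms (rate code) and below 20 ms
#' (temporal code). Degenerate pairs (no spikes in the window class) are
#' recorded but excluded from composites.
#'
#' @param recording an `mea_recording`.
#' @param events propagation events from [match_propagation()] (its
#'   `events` data.frame) or the full result list.
#' @param scales_ms timescale grid in ms, used both as `1/q` and `tau_R`
#'   (default `c(1, 2, 5, 10, 20, 50, 100, 200, 500)`).
#' @param metrics subset of `c("VP", "VR")`.
#' @param max_pairs optional cap on the number of electrode pairs sampled
#'   per pairing class (deterministic under the session RNG); `Inf` uses
#'   all pairs.
#' @param window_classes subset of `c("IN_BURST", "OUT_BURST")`.
#' @return object of class `fidelity_profile`: `records` (long
#'   data.frame: `pair`, `metric`, `scale_ms`, `window_class`,
#'   `pairing_class`, `similarity`, `n_x`, `n_y`, `degenerate`),
#'   `profile` (composite mean similarity per metric x scale x window x
#'   pairing), `regimes` (rate-regime mean for scales > 50 ms and
#'   temporal-regime mean for scales < 20 ms), `flags`.
#' @export
fidelity_profile <- function(recording, events,
                             scales_ms = c(1, 2, 5, 10, 20, 50, 100, 200, 500),
                             metrics = c("VP", "VR"), max_pairs = Inf,
                             window_classes = c("IN_BURST", "OUT_BURST")) {
  stopifnot(length(scales_ms) > 0)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.list(events) && !is.data.frame(events)) events <- events$events
  flags <- character(0)
  in_windows <- if (!is.null(events) && nrow(events) > 0)
    cbind(events$window_start, events$window_end)
  else matrix(numeric(0), ncol = 2)
  if (nrow(in_windows) == 0) {
    flags <- c(flags, "no propagation events: IN_BURST profile missing")
    window_classes <- setdiff(window_classes, "IN_BURST")
  }
  out_windows <- complement_windows(in_windows, recording$t_start,
                                    recording$t_stop)
  l1 <- layout_electrodes(recording$layout, "LAYER1")
  l2 <- layout_electrodes(recording$layout, "LAYER2")
  pair_classes <- list(
    BETWEEN_LAYERS = expand.grid(a = l1, b = l2, stringsAsFactors = FALSE),
    WITHIN_L1 = unordered_pairs(l1),
    WITHIN_L2 = unordered_pairs(l2))
  if (is.finite(max_pairs))
    pair_classes <- lapply(pair_classes, function(df) {
      if (nrow(df) > max_pairs) df[sample(nrow(df), max_pairs), ] else df
    })

  used <- unique(unlist(lapply(pair_classes, function(df) c(df$a, df$b))))
  bin <- 0.001
  n_bins <- ceiling((recording$t_stop - recording$t_start) / bin)
  centers <- recording$t_start + (seq_len(n_bins) - 0.5) * bin

  # long-format accumulator; one row per (pair, metric, scale, classes)
  acc_pair <- acc_metric <- acc_wc <- acc_pc <- character(0)
  acc_scale <- acc_sim <- numeric(0)
  acc_nx <- acc_ny <- integer(0); acc_deg <- logical(0)

  for (wc in window_classes) {
    wins <- if (wc == "IN_BURST") in_windows else out_windows
    wins <- normalize_windows(wins)
    sub <- lapply(recording$trains[used], extract_window_trains,
                  windows = wins)
    keep <- rep(FALSE, n_bins)
    for (i in seq_len(nrow(wins)))
      keep <- keep | (centers >= wins[i, 1] & centers < wins[i, 2])
    for (s in scales_ms) {
      # van Rossum series cached per electrode, restricted to window bins
      series <- if ("VR" %in% metrics)
        lapply(sub, function(tr) bin_and_smooth(tr, bin, s / 1000)[keep])
      for (pc in names(pair_classes)) {
        pairs <- pair_classes[[pc]]
        for (i in seq_len(nrow(pairs))) {
          a <- pairs$a[i]; b <- pairs$b[i]
          ta <- sub[[a]]; tb <- sub[[b]]
          for (m in metrics) {
            if (m == "VP") {
              sim <- vp_similarity(ta, tb, q = 1000 / s)
              deg <- isTRUE(attr(sim, "degenerate"))
            } else {
              fa <- series[[a]]; fb <- series[[b]]
              if (length(fa) < 2 || sd(fa) == 0 || sd(fb) == 0) {
                sim <- 0; deg <- TRUE
              } else { sim <- max(cor(fa, fb), 0); deg <- FALSE }
            }
            k <- length(acc_sim) + 1
            acc_pair[k] <- paste(a, b, sep = "-"); acc_metric[k] <- m
            acc_scale[k] <- s; acc_wc[k] <- wc; acc_pc[k] <- pc
            acc_sim[k] <- as.numeric(sim)
            acc_nx[k] <- length(ta$times); acc_ny[k] <- length(tb$times)
            acc_deg[k] <- deg
          }
        }
      }
    }
  }
  records <- data.frame(pair = acc_pair, metric = acc_metric,
                        scale_ms = acc_scale, window_class = acc_wc,
                        pairing_class = acc_pc, similarity = acc_sim,
                        n_x = acc_nx, n_y = acc_ny, degenerate = acc_deg)
  ok <- records[!records$degenerate, , drop = FALSE]
  profile <- if (nrow(ok)) aggregate(similarity ~ metric + scale_ms +
                                       window_class + pairing_class,
                                     data = ok, FUN = mean)
             else ok[c("metric", "scale_ms", "window_class",
                       "pairing_class", "similarity")]
  regime <- function(sel, label) {
    sub <- profile[sel(profile$scale_ms), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    out <- aggregate(similarity ~ metric + window_class + pairing_class,
                     data = sub, FUN = mean)
    out$regime <- label
    out
  }
  regimes <- rbind(regime(function(s) s > 50, "RATE"),
                   regime(function(s) s < 20, "TEMPORAL"))
  structure(list(records = records, profile = profile, regimes = regimes,
                 scales_ms = scales_ms, flags = flags),
            class = "fidelity_profile")
}

unordered_pairs <- function(ids) {
  if (length(ids) < 2)
    return(data.frame(a = character(0), b = character(0)))
  cmb <- utils::combn(ids, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

#' @export
print.fidelity_profile <- function(x, ...) {
  cat(sprintf("<fidelity_profile: %d records, %d scales, classes: %s>\n",
              nrow(x$records), length(x$scales_ms),
              paste(unique(x$records$window_class), collapse = "/")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
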
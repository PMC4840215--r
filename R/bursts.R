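#' Per-electrode burstlet detection
#'
#' A burstlet is a maximal run of at least `min_spikes` spikes whose
#' consecutive inter-spike intervals are all strictly below a
#' rate-adaptive threshold: `isi_factor` times the electrode's mean ISI
#' (the inverse of its average rate over the whole recording).
#'
#' @param train a [spike_train()].
#' @param isi_factor fraction of the mean ISI used as threshold
#'   (default 0.25).
#' @param min_spikes minimum run length (default 4).
#' @return list of burstlets; each is a list with `electrode_id`,
#'   `spike_times`, `start`, `end` (first/last spike of the run).
#' @export
detect_burstlets <- function(train, isi_factor = 0.25, min_spikes = 4) {
  dur <- train$t_stop - train$t_start
  if (dur <= 0) stop("zero-duration recording")
  n <- length(train$times)
  if (n < min_spikes) return(list())
  thr <- isi_factor * dur / n
  isi <- diff(train$times)
  fast <- isi < thr                      # strict comparison at the boundary
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (i in which(r$values & r$lengths >= min_spikes - 1)) {
    idx <- starts[i]:(ends[i] + 1)       # ISIs i..j involve spikes i..j+1
    out[[length(out) + 1]] <- list(electrode_id = train$electrode_id,
                                   spike_times = train$times[idx],
                                   start = train$times[idx[1]],
                                   end = train$times[idx[length(idx)]])
  }
  out
}

#' Merge burstlets into network bursts
#'
#' Groups burstlets (from the electrodes of a single layer) into connected
#' components under pairwise interval overlap; the component spans
#' `[min start, max end]`. Components shorter than `min_duration` or with
#' fewer than `min_channels` distinct electrodes are discarded. The peak
#' rate/time of the pooled spikes is attached via [burst_peak()].
#'
#' @param burstlets list from [detect_burstlets()] over one layer's
#'   electrodes (tunnel electrodes must not be included).
#' @param layer label stored on each burst (`"LAYER1"`/`"LAYER2"`).
#' @param min_duration minimum burst span (s), default 10 ms.
#' @param min_channels minimum number of distinct participating
#'   electrodes; the default 1 lets a single qualifying burstlet stand as
#'   a network burst (configurable; the analysis scripts use 5).
#' @return list of `network_burst` objects: `layer`, `start`, `end`,
#'   `electrodes`, `n_burstlets`, `spike_times` (pooled, sorted),
#'   `peak_rate` (Hz), `peak_time` (s).
#' @export
merge_network_bursts <- function(burstlets, layer = "LAYER1",
                                 min_duration = 0.010, min_channels = 1) {
  if (length(burstlets) == 0) return(list())
  starts <- vapply(burstlets, `[[`, 0, "start")
  ends <- vapply(burstlets, `[[`, 0, "end")
  ord <- order(starts, ends)
  comp <- integer(length(burstlets)); cur <- 0; cur_end <- -Inf
  for (i in ord) {
    if (cur > 0 && starts[i] <= cur_end) {
      comp[i] <- cur
      cur_end <- max(cur_end, ends[i])
    } else {
      cur <- cur + 1
      comp[i] <- cur
      cur_end <- ends[i]
    }
  }
  out <- list()
  for (g in split(seq_along(burstlets), comp)) {
    b_start <- min(starts[g]); b_end <- max(ends[g])
    electrodes <- unique(vapply(burstlets[g], `[[`, "", "electrode_id"))
    if (b_end - b_start < min_duration) next
    if (length(electrodes) < min_channels) next
    pooled <- sort(unlist(lapply(burstlets[g], `[[`, "spike_times")))
    pk <- burst_peak(pooled)
    out[[length(out) + 1]] <-
      structure(list(layer = layer, start = b_start, end = b_end,
                     electrodes = electrodes, n_burstlets = length(g),
                     spike_times = pooled, peak_rate = pk$peak_rate,
                     peak_time = pk$peak_time), class = "network_burst")
  }
  out[order(vapply(out, `[[`, 0, "start"))]
}

#' Smoothed peak rate and peak time of a burst
#'
#' Pools the member spikes, bins them at `bin` (1 ms), convolves with a
#' Gaussian of sd `sigma` (5 ms) truncated at +/-4 sd and normalized to
#' unit sum, and converts counts/bin to Hz. Ties take the earliest bin.
#'
#' @param burst a `network_burst` or a numeric vector of spike times (s).
#' @param bin bin width (s).
#' @param sigma Gaussian sd (s).
#' @return list with `peak_rate` (Hz) and `peak_time` (s, bin centre).
#' @export
burst_peak <- function(burst, bin = 0.001, sigma = 0.005) {
  times <- if (inherits(burst, "network_burst")) burst$spike_times else burst
  if (length(times) == 0) stop("burst has no member spikes")
  t0 <- min(times)
  idx <- floor((times - t0) / bin) + 1
  counts <- tabulate(idx)
  half <- ceiling(4 * sigma / bin)
  kern <- exp(-(seq(-half, half) * bin)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  padded <- c(numeric(half), counts, numeric(half))
  sm <- vapply(seq_along(counts), function(i)
    sum(padded[i:(i + 2 * half)] * rev(kern)), 0)
  peak_bin <- which.max(sm)
  list(peak_rate = sm[peak_bin] / bin,
       peak_time = t0 + (peak_bin - 0.5) * bin)
}

#' Detect network bursts of one layer of a recording
#'
#' Convenience wrapper: burstlet detection on every electrode of `layer`
#' (tunnel electrodes excluded by construction) followed by
#' [merge_network_bursts()].
#'
#' @param recording an `mea_recording`.
#' @param layer `"LAYER1"` or `"LAYER2"`.
#' @inheritParams detect_burstlets
#' @inheritParams merge_network_bursts
#' @export
layer_bursts <- function(recording, layer, isi_factor = 0.25, min_spikes = 4,
                         min_duration = 0.010, min_channels = 1) {
  ids <- layout_electrodes(recording$layout, layer)
  bl <- list()
  for (e in ids) {
    tr <- recording$trains[[e]]
    if (is.null(tr) || length(tr$times) == 0) next
    bl <- c(bl, detect_burstlets(tr, isi_factor, min_spikes))
  }
  merge_network_bursts(bl, layer, min_channels = min_channels)
}

#' Burst statistics of a recording
#'
#' @param bursts list of `network_burst` (one layer).
#' @param trains the layer's spike trains (used for the total spike count
#'   and the in-burst counts).
#' @param duration recording length (s).
#' @return list: `n_bursts`, `bursts_per_min`, `mean_duration_s`,
#'   `mean_in_burst_rate_hz` (in-burst spikes / (participating electrodes
#'   x duration), averaged over bursts), `mean_peak_rate_hz` (pooled
#'   smoothed peak), `fraction_in_bursts`.
#' @export
summarize_bursts <- function(bursts, trains, duration) {
  all_times <- sort(unlist(lapply(trains, `[[`, "times")))
  n_total <- length(all_times)
  if (length(bursts) == 0)
    return(list(n_bursts = 0L, bursts_per_min = 0, mean_duration_s = NA_real_,
                mean_in_burst_rate_hz = NA_real_, mean_peak_rate_hz = NA_real_,
                fraction_in_bursts = if (n_total) 0 else NA_real_))
  starts <- vapply(bursts, `[[`, 0, "start")
  ends <- vapply(bursts, `[[`, 0, "end")
  in_any <- rep(FALSE, n_total)
  rates <- numeric(length(bursts))
  for (i in seq_along(bursts)) {
    inside <- all_times >= starts[i] & all_times <= ends[i]
    in_any <- in_any | inside
    rates[i] <- sum(inside) /
      (length(bursts[[i]]$electrodes) * (ends[i] - starts[i]))
  }
  list(n_bursts = length(bursts),
       bursts_per_min = length(bursts) / duration * 60,
       mean_duration_s = mean(ends - starts),
       mean_in_burst_rate_hz = mean(rates),
       mean_peak_rate_hz = mean(vapply(bursts, `[[`, 0, "peak_rate")),
       fraction_in_bursts = if (n_total) mean(in_any) else NA_real_)
}

#' Match Layer I bursts to propagated Layer II bursts
#'
#' For each Layer I burst the temporal overlap fraction with each Layer II
#' burst is `|intersection| / (Layer I burst duration)`. Candidate pairs
#' are claimed greedily one-to-one in descending overlap; pairs at or
#' above `min_overlap` become propagation events. The propagation
#' probability is the fraction of Layer I bursts matched.
#'
#' @param bursts_l1,bursts_l2 lists of `network_burst`.
#' @param min_overlap minimum overlap fraction (default 0.20).
#' @return list: `events` (data.frame: `source`, `target`,
#'   `overlap_fraction`, `peak_delay` = L2 peak time - L1 peak time,
#'   `window_start`, `window_end` = the overlap window), `probability`
#'   (NA with `undefined = TRUE` when no Layer I bursts exist), `n_l1`,
#'   `n_l2`.
#' @export
match_propagation <- function(bursts_l1, bursts_l2, min_overlap = 0.20) {
  empty <- data.frame(source = integer(0), target = integer(0),
                      overlap_fraction = numeric(0), peak_delay = numeric(0),
                      window_start = numeric(0), window_end = numeric(0))
  if (length(bursts_l1) == 0)
    return(list(events = empty, probability = NA_real_, undefined = TRUE,
                n_l1 = 0L, n_l2 = length(bursts_l2)))
  if (length(bursts_l2) == 0)
    return(list(events = empty, probability = 0, undefined = FALSE,
                n_l1 = length(bursts_l1), n_l2 = 0L))
  cand <- expand.grid(source = seq_along(bursts_l1),
                      target = seq_along(bursts_l2))
  s1 <- vapply(bursts_l1, `[[`, 0, "start"); e1 <- vapply(bursts_l1, `[[`, 0, "end")
  s2 <- vapply(bursts_l2, `[[`, 0, "start"); e2 <- vapply(bursts_l2, `[[`, 0, "end")
  lo <- pmax(s1[cand$source], s2[cand$target])
  hi <- pmin(e1[cand$source], e2[cand$target])
  cand$overlap_fraction <- pmax(hi - lo, 0) / (e1[cand$source] - s1[cand$source])
  cand$window_start <- lo; cand$window_end <- hi
  cand <- cand[cand$overlap_fraction >= min_overlap - 1e-12, , drop = FALSE]
  cand <- cand[order(-cand$overlap_fraction, cand$source), , drop = FALSE]
  used_s <- logical(length(bursts_l1)); used_t <- logical(length(bursts_l2))
  rows <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$source[i]; t <- cand$target[i]
    if (!used_s[s] && !used_t[t]) { used_s[s] <- used_t[t] <- TRUE; rows <- c(rows, i) }
  }
  ev <- cand[rows, , drop = FALSE]
  if (nrow(ev)) {
    p1 <- vapply(bursts_l1, `[[`, 0, "peak_time")
    p2 <- vapply(bursts_l2, `[[`, 0, "peak_time")
    ev$peak_delay <- p2[ev$target] - p1[ev$source]
    ev <- ev[order(ev$window_start),
             c("source", "target", "overlap_fraction", "peak_delay",
               "window_start", "window_end")]
    rownames(ev) <- NULL
  } else ev <- empty
  list(events = ev, probability = nrow(ev) / length(bursts_l1),
       undefined = FALSE, n_l1 = length(bursts_l1), n_l2 = length(bursts_l2))
}
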
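#' Butterworth band-pass design (bilinear transform)
#'
#' Designs the 300 Hz - 3 kHz action-potential band-pass used ahead of
#' threshold detection. No signal-processing package is assumed: the
#' analog Butterworth prototype is band-transformed and discretized with
#' the bilinear transform here, and applied with a compiled direct-form
#' filter.
#'
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz).
#' @param order prototype order (the band-pass has `2*order` poles).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(fs, low = 300, high = 3000, order = 4) {
  stopifnot(low > 0, high > low, high < fs / 2)
  # analog prototype poles on the unit circle
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # prewarped band edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  # lowpass -> bandpass: each pole splits in two
  pb <- c((p * bw + sqrt((p * bw)^2 - 4 * w0^2)) / 2,
          (p * bw - sqrt((p * bw)^2 - 4 * w0^2)) / 2)
  # bilinear transform
  zp <- (2 * fs + pb) / (2 * fs - pb)
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(c(rep(1, order), rep(-1, order))))
  # unit gain at the geometric band centre
  wc <- 2 * atan(w0 / (2 * fs))
  z <- exp(1i * wc)
  gain <- abs(sum(b * z^(rev(seq_along(b)) - 1)) /
                sum(a * z^(rev(seq_along(a)) - 1)))
  list(b = b / gain, a = a)
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Zero-phase IIR filtering (forward-backward)
#'
#' @param x signal.
#' @param ba list with `b`, `a` from [butter_bandpass()].
#' @return filtered signal, same length.
#' @export
filtfilt_ba <- function(x, ba) {
  npad <- min(3 * (max(length(ba$a), length(ba$b)) - 1) * 5, length(x) - 1)
  # odd extension at both ends suppresses edge transients
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)]
  xp <- c(pre, x, post)
  y <- iir_filter_cpp(ba$b, ba$a, xp)
  y <- rev(iir_filter_cpp(ba$b, ba$a, rev(y)))
  y[(npad + 1):(npad + length(x))]
}

#' Threshold spike detection on a raw voltage trace
#'
#' Noise RMS is estimated on the first `noise_window` seconds; events are
#' excursions of either polarity beyond `threshold_multiplier` times that
#' RMS. Each contiguous supra-threshold run yields one event timed at its
#' extremum, followed by a 1 ms dead time. A +/-1 ms waveform snippet is
#' cut around each event (events too close to the trace edges carry no
#' snippet).
#'
#' @param trace numeric voltage trace (uV) or a `raw_trace` object from
#'   [simulate_raw_trace()].
#' @param fs sampling rate (Hz); taken from the `raw_trace` if given.
#' @param threshold_multiplier RMS multiples defining the threshold.
#' @param noise_window seconds of signal used for the RMS estimate.
#' @param dead_time refractory imposed after each detection (s).
#' @param bandpass if `TRUE`, apply the 300 Hz - 3 kHz zero-phase
#'   Butterworth band-pass before detection.
#' @return list of class `detection`: `train` ([spike_train()]),
#'   `waveforms` (matrix, one row per snippet-bearing event),
#'   `waveform_times` (their times), `rms`, `threshold`, and
#'   `degenerate` (TRUE when the RMS was zero and no threshold exists).
#' @export
detect_spikes <- function(trace, fs = 25000, threshold_multiplier = 5.0,
                          noise_window = 15, dead_time = 0.001,
                          bandpass = FALSE) {
  if (inherits(trace, "raw_trace")) { fs <- trace$fs; trace <- trace$trace }
  if (fs < 20000) stop("fs must be at least 20 kHz")
  nw <- min(round(noise_window * fs), length(trace))
  if (nw < 1) stop("trace shorter than the noise window")
  if (bandpass) trace <- filtfilt_ba(trace, butter_bandpass(fs))
  rms <- sqrt(mean(trace[seq_len(nw)]^2))
  half <- round(0.001 * fs)
  empty <- function(flag) {
    list(train = spike_train(numeric(0), t_start = 0,
                             t_stop = length(trace) / fs),
         waveforms = matrix(numeric(0), 0, 2 * half + 1),
         waveform_times = numeric(0), rms = rms,
         threshold = threshold_multiplier * rms, degenerate = flag)
  }
  if (rms == 0) { warning("zero noise RMS; threshold undefined"); return(empty(TRUE)) }
  thr <- threshold_multiplier * rms
  supra <- abs(trace) > thr
  if (!any(supra)) return(empty(FALSE))
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  peak_idx <- apply(runs, 1, function(se) {
    seg <- se[1]:se[2]
    seg[which.max(abs(trace[seg]))]
  })
  # dead time: drop events within dead_time of the previous accepted one
  keep <- logical(length(peak_idx)); last <- -Inf
  dead <- dead_time * fs
  for (i in seq_along(peak_idx)) {
    if (peak_idx[i] - last >= dead) { keep[i] <- TRUE; last <- peak_idx[i] }
  }
  peak_idx <- peak_idx[keep]
  times <- (peak_idx - 1) / fs
  ok <- peak_idx > half & peak_idx + half <= length(trace)
  wf <- if (any(ok)) {
    t(vapply(peak_idx[ok], function(i) trace[(i - half):(i + half)],
             numeric(2 * half + 1)))
  } else matrix(numeric(0), 0, 2 * half + 1)
  list(train = spike_train(times, t_start = 0, t_stop = length(trace) / fs),
       waveforms = wf, waveform_times = times[ok], rms = rms, threshold = thr,
       degenerate = FALSE)
}

#' PCA + k-means spike sorting
#'
#' Projects waveform snippets onto their first three principal components
#' and clusters with k-means; the number of units is chosen by a
#' spherical-Gaussian BIC over `k = 1..max_units` (a documented
#' simplification of automatic cluster-count selection).
#'
#' @param waveforms matrix of snippets, one row per spike.
#' @param max_units largest unit count considered.
#' @param seed RNG seed for k-means restarts (labels are reproducible).
#' @return list: `labels` (integer unit per spike), `k`, `scores`
#'   (PC coordinates), `flagged` (TRUE when fewer than 10 waveforms forced
#'   a single unit).
#' @export
sort_units <- function(waveforms, max_units = 5, seed = 1L) {
  n <- nrow(waveforms)
  if (is.null(n) || n < 10)
    return(list(labels = rep(1L, if (is.null(n)) 0 else n), k = 1L,
                scores = NULL, flagged = TRUE))
  npc <- min(3, ncol(waveforms), n - 1)
  scores <- prcomp(waveforms, center = TRUE, scale. = FALSE)$x[, seq_len(npc),
                                                              drop = FALSE]
  d <- ncol(scores)
  best <- NULL; best_bic <- Inf
  for (k in seq_len(min(max_units, n - 1))) {
    set.seed(seed + k)
    fit <- if (k == 1) {
      list(cluster = rep(1L, n),
           tot.withinss = sum(scale(scores, scale = FALSE)^2), size = n)
    } else kmeans(scores, k, nstart = 10, iter.max = 100)
    sig2 <- max(fit$tot.withinss / (d * max(n - k, 1)), 1e-12)
    ll <- -n * d / 2 * log(2 * pi * sig2) - d * (n - k) / 2 +
      sum(fit$size * log(fit$size / n))
    n_par <- (k - 1) + k * d + 1
    bic <- -2 * ll + n_par * log(n)
    if (bic < best_bic) { best_bic <- bic; best <- fit; bestk <- k }
  }
  list(labels = as.integer(best$cluster), k = bestk, scores = scores,
       flagged = FALSE)
}

#' Drop trains whose mean rate falls below a floor
#'
#' Electrodes firing below 0.01 spikes/s are typically noise and are
#' removed before analysis.
#'
#' @param trains list of [spike_train()].
#' @param min_rate floor (Hz); trains with `count / duration >= min_rate`
#'   are kept.
#' @export
filter_low_rate <- function(trains, min_rate = 0.01) {
  Filter(function(tr) train_rate(tr) >= min_rate, trains)
}
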
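#' Coupling anchors for a given tunnel count
#'
#' Propagation probability, Layer I to Layer II peak delay and in-burst
#' firing rate scale with the number of tunnels between the chambers.
#' Empirical anchors exist for the 2-tunnel device (propagation probability
#' 0.22, delay 280 ms, in-burst rate 42.8 Hz) and the 51-tunnel device
#' (0.72, 90 ms, 54.1 Hz); intermediate devices are interpolated linearly
#' in tunnel count, which preserves the observed monotone trend without
#' asserting a mechanism.
#'
#' @param n_tunnels tunnel count (any positive number; the physical devices
#'   have 2, 5, 10, 15 or 51).
#' @return list with `p_propagate`, `delay_mean` (s), `in_burst_rate` (Hz).
#' @export
tunnel_coupling <- function(n_tunnels) {
  f <- (pmin(pmax(n_tunnels, 2), 51) - 2) / (51 - 2)
  list(p_propagate = 0.22 + f * (0.72 - 0.22),
       delay_mean = 0.280 + f * (0.090 - 0.280),
       in_burst_rate = 42.8 + f * (54.1 - 42.8))
}

#' Simulation configuration for a two-layer feed-forward recording
#'
#' Defaults emulate the spontaneous dynamics of the cultured two-chamber
#' networks: per-electrode background firing around 0.55 Hz plus burst
#' spikes bringing total rates to ~0.8-1 Hz, Layer I network bursts at
#' ~2/min lasting ~0.49 s, roughly 40% of spikes inside bursts, and
#' tunnel conduction at 0.4 m/s over the 200 um electrode separation.
#' Coupling-dependent fields (`p_propagate`, `propagation_delay_mean`,
#' `in_burst_rate`) default to the [tunnel_coupling()] map.
#'
#' @param n_tunnels tunnel count (2, 5, 10, 15 or 51).
#' @param duration recording length (s).
#' @param seed integer seed; fully determines the recording.
#' @param background_rate asynchronous background rate per electrode (Hz).
#' @param burst_rate_layer1 Layer I network-burst rate (bursts/min).
#' @param burst_duration_mean,burst_duration_sd burst duration (s).
#' @param in_burst_rate peak of the per-electrode rate envelope during a
#'   burst (Hz); default from [tunnel_coupling()].
#' @param p_propagate probability a Layer I burst ignites a Layer II burst.
#' @param propagation_delay_mean,propagation_delay_sd onset-to-onset delay
#'   (s), drawn truncated-normal at 0.
#' @param conduction_velocity axonal conduction velocity in tunnels (m/s).
#' @param participation_fraction fraction of a layer's electrodes recruited
#'   per burst (the source data do not report this; 0.8 is a free choice).
#' @param tunnel_rate upstream tunnel-electrode rate during a Layer I
#'   burst (Hz).
#' @param tunnel_jitter sd of optional conduction jitter (s); 0 means the
#'   downstream train is an exact shifted copy.
#' @param burst_refractory minimum gap between consecutive Layer I burst
#'   onsets (s).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tunnels = 51, duration = 600, seed = 1L,
                       background_rate = 0.55,
                       burst_rate_layer1 = 2.0,
                       burst_duration_mean = 0.49, burst_duration_sd = 0.10,
                       in_burst_rate = NULL,
                       p_propagate = NULL,
                       propagation_delay_mean = NULL,
                       propagation_delay_sd = 0.04,
                       conduction_velocity = 0.4,
                       participation_fraction = 0.8,
                       tunnel_rate = 40,
                       tunnel_jitter = 0,
                       burst_refractory = 2.0) {
  map <- tunnel_coupling(n_tunnels)
  cfg <- list(n_tunnels = n_tunnels, duration = duration, seed = as.integer(seed),
              background_rate = background_rate,
              burst_rate_layer1 = burst_rate_layer1,
              burst_duration_mean = burst_duration_mean,
              burst_duration_sd = burst_duration_sd,
              in_burst_rate = if (is.null(in_burst_rate)) map$in_burst_rate else in_burst_rate,
              p_propagate = if (is.null(p_propagate)) map$p_propagate else p_propagate,
              propagation_delay_mean = if (is.null(propagation_delay_mean)) map$delay_mean else propagation_delay_mean,
              propagation_delay_sd = propagation_delay_sd,
              conduction_velocity = conduction_velocity,
              participation_fraction = participation_fraction,
              tunnel_rate = tunnel_rate,
              tunnel_jitter = tunnel_jitter,
              burst_refractory = burst_refractory)
  stopifnot(cfg$duration > 0, cfg$background_rate >= 0,
            cfg$p_propagate >= 0, cfg$p_propagate <= 1,
            cfg$conduction_velocity > 0, cfg$conduction_velocity <= 10,
            cfg$participation_fraction > 0, cfg$participation_fraction <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# burst rate envelope: half-Gaussian rise to the peak at 30% of the burst
# duration, exponential decay after it; both tails truncated at exp(-2) so
# the burst switches on and off briskly relative to its own duration.
burst_envelope <- function(u, duration, rise_frac = 0.3) {
  rise <- rise_frac * duration
  sig <- rise / 2
  tau <- (duration - rise) / 2
  out <- ifelse(u < 0 | u > duration, 0,
         ifelse(u <= rise, exp(-(u - rise)^2 / (2 * sig^2)),
                exp(-(u - rise) / tau)))
  out
}

# inhomogeneous Poisson draw on [t0, t0+duration) by thinning against the
# peak rate
rinhom_poisson <- function(t0, duration, peak_rate, envelope_fun) {
  n <- rpois(1, peak_rate * duration)
  if (n == 0) return(numeric(0))
  u <- runif(n, 0, duration)
  keep <- runif(n) < envelope_fun(u)
  sort(t0 + u[keep])
}

rtrunc_norm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x <= 0
  }
  x
}

#' Simulate a two-layer feed-forward MEA recording
#'
#' Generates a ground-truth-annotated spontaneous recording: homogeneous
#' Poisson background on every chamber electrode; Layer I network bursts as
#' a refractory renewal process; per-burst recruitment of a random subset
#' of electrodes firing an inhomogeneous Poisson envelope (half-Gaussian
#' rise, exponential decay) peaking at `in_burst_rate`; probabilistic
#' ignition of a Layer II burst after a truncated-normal delay; tunnel
#' events on instrumented upstream electrodes duplicated downstream after
#' `separation / conduction_velocity`.
#'
#' @param config a [sim_config()].
#' @return object of class `mea_recording`: list with `layout`, `trains`
#'   (named list of [spike_train()], one per electrode), `t_start`,
#'   `t_stop`, `ground_truth` and `config`. `ground_truth` carries
#'   `burst_events` (layer, onset, offset, peak_time, n_electrodes),
#'   `propagation_links` (source/target rows of `burst_events` plus
#'   `true_delay`), `tunnel_delay_s`, and spike bookkeeping
#'   (`n_background`, `n_burst`, `n_tunnel`).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duration <= 0) stop("duration must be positive")
  layout <- make_layout(config$n_tunnels)
  set.seed(config$seed)
  dur <- config$duration
  l1 <- layout_electrodes(layout, "LAYER1")
  l2 <- layout_electrodes(layout, "LAYER2")

  spikes <- stats::setNames(vector("list", nrow(layout$electrodes)),
                            layout$electrodes$electrode_id)
  for (e in names(spikes)) spikes[[e]] <- numeric(0)
  n_background <- 0L; n_burst <- 0L; n_tunnel <- 0L

  # background on chamber electrodes
  for (e in c(l1, l2)) {
    n <- rpois(1, config$background_rate * dur)
    spikes[[e]] <- sort(runif(n, 0, dur))
    n_background <- n_background + n
  }

  # Layer I burst onsets: refractory renewal targeting burst_rate_layer1
  onsets <- numeric(0)
  if (config$burst_rate_layer1 > 0) {
    mean_iei <- 60 / config$burst_rate_layer1
    exp_mean <- max(mean_iei - config$burst_refractory, 0.1)
    t <- rexp(1, 1 / exp_mean)
    while (t < dur - 0.1) {
      onsets <- c(onsets, t)
      t <- t + config$burst_refractory + rexp(1, 1 / exp_mean)
    }
  }

  bursts <- data.frame(layer = character(0), onset = numeric(0),
                       offset = numeric(0), peak_time = numeric(0),
                       n_electrodes = integer(0))
  links <- data.frame(source = integer(0), target = integer(0),
                      true_delay = numeric(0))

  add_burst <- function(layer, onset, duration_s, electrodes) {
    members <- sample(electrodes, max(1, round(config$participation_fraction *
                                                 length(electrodes))))
    for (e in members) {
      ts <- rinhom_poisson(onset, duration_s, config$in_burst_rate,
                           function(u) burst_envelope(u, duration_s))
      ts <- ts[ts < dur]
      spikes[[e]] <<- c(spikes[[e]], ts)
      n_burst <<- n_burst + length(ts)
    }
    bursts[nrow(bursts) + 1L, ] <<- list(layer, onset,
                                         min(onset + duration_s, dur),
                                         onset + 0.3 * duration_s,
                                         length(members))
    nrow(bursts)
  }

  tunnel_delay <- layout$tunnel_pairs$separation_um[1] * 1e-6 /
    config$conduction_velocity

  for (on1 in onsets) {
    d1 <- rtrunc_norm_pos(1, config$burst_duration_mean, config$burst_duration_sd)
    i1 <- add_burst("LAYER1", on1, d1, l1)
    # tunnel traffic carried by this burst
    for (k in seq_len(nrow(layout$tunnel_pairs))) {
      up <- layout$tunnel_pairs$upstream[k]
      down <- layout$tunnel_pairs$downstream[k]
      ts <- rinhom_poisson(on1, d1, config$tunnel_rate,
                           function(u) burst_envelope(u, d1))
      ts_down <- ts + tunnel_delay
      if (config$tunnel_jitter > 0)
        ts_down <- ts_down + rnorm(length(ts_down), 0, config$tunnel_jitter)
      ts <- ts[ts < dur]; ts_down <- ts_down[ts_down < dur & ts_down >= 0]
      spikes[[up]] <- c(spikes[[up]], ts)
      spikes[[down]] <- c(spikes[[down]], ts_down)
      n_tunnel <- n_tunnel + length(ts) + length(ts_down)
    }
    # probabilistic ignition of the downstream layer
    if (runif(1) < config$p_propagate) {
      delay <- rtrunc_norm_pos(1, config$propagation_delay_mean,
                               config$propagation_delay_sd)
      on2 <- on1 + delay
      if (on2 < dur - 0.05) {
        d2 <- rtrunc_norm_pos(1, config$burst_duration_mean,
                              config$burst_duration_sd)
        i2 <- add_burst("LAYER2", on2, d2, l2)
        links[nrow(links) + 1L, ] <- list(i1, i2, delay)
      }
    }
  }

  trains <- lapply(names(spikes), function(e) {
    spike_train(unique(sort(spikes[[e]])), e, 1L, 0, dur)
  })
  names(trains) <- names(spikes)

  structure(list(layout = layout, trains = trains, t_start = 0, t_stop = dur,
                 ground_truth = list(burst_events = bursts,
                                     propagation_links = links,
                                     tunnel_delay_s = tunnel_delay,
                                     directed_coupling = NULL,
                                     n_background = n_background,
                                     n_burst = n_burst, n_tunnel = n_tunnel),
                 config = config),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording: %dT, %g s, %d trains, %d spikes, %d true bursts>\n",
              x$layout$n_tunnels, x$t_stop - x$t_start, length(x$trains),
              sum(vapply(x$trains, length, 1L)),
              nrow(x$ground_truth$burst_events)))
  invisible(x)
}

#' Default extracellular spike template
#'
#' Biphasic template (sharp negative trough followed by a slower positive
#' afterpotential), ~1.4 ms long, trough amplitude `amp_uV`.
#' @param fs sampling rate (Hz).
#' @param amp_uV trough amplitude (uV).
#' @export
spike_waveform <- function(fs, amp_uV = 100) {
  t <- seq(0, 1.4e-3, by = 1 / fs)
  w <- -amp_uV * exp(-((t - 0.3e-3) / 0.08e-3)^2) +
    0.3 * amp_uV * exp(-((t - 0.7e-3) / 0.25e-3)^2)
  w
}

#' Synthesize a raw voltage trace from a spike train
#'
#' Gaussian noise of the stated RMS with a spike template added at each
#' spike time. Overlapping templates (spikes closer than the template
#' length) sum linearly; this is deliberate, not an error.
#'
#' @param train a [spike_train()].
#' @param noise_rms noise RMS (uV).
#' @param waveform template samples (uV); default [spike_waveform()].
#' @param fs sampling rate (Hz), at least 20 kHz.
#' @param duration trace length (s); defaults to the train's window.
#' @return list of class `raw_trace`: `trace` (uV), `fs`, `times` (the
#'   injected spike times) and `waveform`.
#' @export
simulate_raw_trace <- function(train, noise_rms, waveform = NULL, fs = 25000,
                               duration = NULL) {
  if (fs < 20000) stop("fs must be at least 20 kHz")
  if (is.null(waveform)) waveform <- spike_waveform(fs)
  if (length(waveform) > round(0.002 * fs) + 1)
    stop("waveform must be at most 2 ms long")
  if (is.null(duration)) duration <- train$t_stop - train$t_start
  n <- round(duration * fs)
  trace <- if (noise_rms > 0) rnorm(n, 0, noise_rms) else numeric(n)
  # align the template trough with the nominal spike time
  trough <- which.max(abs(waveform)) - 1L
  for (tt in train$times - train$t_start) {
    i0 <- round(tt * fs) + 1 - trough
    idx <- max(i0, 1):min(i0 + length(waveform) - 1, n)
    if (length(idx) > 0 && idx[1] <= n)
      trace[idx] <- trace[idx] + waveform[idx - i0 + 1]
  }
  structure(list(trace = trace, fs = fs, times = train$times,
                 waveform = waveform), class = "raw_trace")
}

#' Simulate a panel of coupled point processes
#'
#' Discrete-time (1 ms bins) Bernoulli approximation of coupled Poisson
#' processes: a spike on a source channel multiplies the target channel's
#' instantaneous rate by `strength` for one bin, `lag_ms` later. The
#' ground-truth directed edges are recorded for validation of the
#' connectivity stage. Sustained rates above 1 kHz abort with an error.
#'
#' @param coupling data.frame with columns `source`, `target` (1-based
#'   channel indices), `lag_ms` (>= 1) and `strength` (rate multiplier);
#'   `NULL` or zero rows means independent channels.
#' @param n_channels number of channels.
#' @param duration panel length (s).
#' @param base_rate baseline rate per channel (Hz); scalar or vector.
#' @param seed integer seed.
#' @param bin bin width (s), default 1 ms.
#' @return object of class `mea_recording` with `trains` named
#'   `"ch<i>"`, a `NULL` layout and `ground_truth$directed_coupling`.
#' @export
simulate_coupled_panel <- function(coupling, n_channels, duration, base_rate,
                                   seed = 1L, bin = 0.001) {
  if (is.null(coupling) || nrow(coupling) == 0)
    coupling <- data.frame(source = integer(0), target = integer(0),
                           lag_ms = numeric(0), strength = numeric(0))
  stopifnot(all(coupling$lag_ms >= 1), all(coupling$source >= 1),
            all(coupling$target <= n_channels))
  set.seed(as.integer(seed))
  n_bins <- round(duration / bin)
  base <- rep_len(base_rate, n_channels)
  mat <- panel_sim_cpp(n_bins, n_channels, base, bin,
                       as.integer(coupling$source - 1),
                       as.integer(coupling$target - 1),
                       as.integer(round(coupling$lag_ms * 0.001 / bin)),
                       as.numeric(coupling$strength),
                       1000, as.integer(0.1 / bin))
  trains <- lapply(seq_len(n_channels), function(c) {
    idx <- which(mat[, c] > 0)
    spike_train((idx - 0.5) * bin, paste0("ch", c), 1L, 0, duration)
  })
  names(trains) <- paste0("ch", seq_len(n_channels))
  structure(list(layout = NULL, trains = trains, t_start = 0,
                 t_stop = duration,
                 ground_truth = list(directed_coupling = coupling),
                 config = list(seed = seed, bin = bin, base_rate = base)),
            class = "mea_recording")
}
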
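#' Structural validation of spike data against a layout
#'
#' Checks electrode-id consistency, time ordering, the 22/22 layer
#' partition and tunnel-pair integrity. Violations are enumerated, never
#' silently fixed.
#'
#' @param trains named list of [spike_train()] (or a spike table
#'   data.frame with `electrode_id`, `unit_id`, `time_s`).
#' @param layout a [make_layout()] object.
#' @return list: `ok` (logical), `errors`, `warnings` (character
#'   vectors).
#' @export
validate_inputs <- function(trains, layout) {
  errors <- character(0); warnings <- character(0)
  n1 <- sum(layout$electrodes$region == "LAYER1")
  n2 <- sum(layout$electrodes$region == "LAYER2")
  if (n1 != 22) errors <- c(errors, sprintf(
    "layout has %d LAYER1 electrodes; each layer must contain 22", n1))
  if (n2 != 22) errors <- c(errors, sprintf(
    "layout has %d LAYER2 electrodes; each layer must contain 22", n2))
  tun <- layout_electrodes(layout, "TUNNEL")
  for (i in seq_len(nrow(layout$tunnel_pairs))) {
    pr <- layout$tunnel_pairs[i, ]
    if (!(pr$upstream %in% tun) || !(pr$downstream %in% tun))
      errors <- c(errors, sprintf(
        "tunnel pair (%s, %s) references non-tunnel electrodes",
        pr$upstream, pr$downstream))
    if (pr$separation_um != 200)
      errors <- c(errors, sprintf(
        "tunnel pair (%s, %s) separation %g um; expected 200",
        pr$upstream, pr$downstream, pr$separation_um))
  }
  if (is.data.frame(trains)) {
    if (is.unsorted(trains$time_s))
      errors <- c(errors, sprintf(
        "spike times not sorted; first offending row %d",
        which(diff(trains$time_s) < 0)[1] + 1))
    unknown <- setdiff(unique(trains$electrode_id),
                       layout$electrodes$electrode_id)
    if (length(unknown))
      errors <- c(errors, paste("spike(s) reference unknown electrode(s):",
                                paste(unknown, collapse = ", ")))
  } else {
    unknown <- setdiff(names(trains), layout$electrodes$electrode_id)
    if (length(unknown))
      errors <- c(errors, paste("train(s) reference unknown electrode(s):",
                                paste(unknown, collapse = ", ")))
    unsorted <- names(trains)[vapply(trains, function(tr)
      is.unsorted(tr$times), TRUE)]
    if (length(unsorted))
      errors <- c(errors, paste("unsorted spike times on electrode(s):",
                                paste(unsorted, collapse = ", ")))
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

#' Pipeline run configuration
#'
#' Bundles the input source and all stage parameters with their defaults.
#'
#' @param sim a [sim_config()] to generate the input synthetically, or
#'   `NULL` when reading files.
#' @param spikes_tsv,layout_json input files (used when `sim` is NULL);
#'   `t_stop` must then be given.
#' @param t_stop recording length for file input (s).
#' @param stages character subset of `c("bursts", "connectivity",
#'   "fidelity")`.
#' @param min_rate rate floor for including a train (Hz).
#' @param isi_factor burstlet ISI threshold factor.
#' @param min_channels minimum electrodes per network burst.
#' @param min_overlap propagation overlap criterion.
#' @param var_order CGC model order (bins).
#' @param fdr_threshold p threshold for CGC edges.
#' @param cgc_duration span of the connectivity window (s); the standard
#'   analysis uses a 2-min excerpt.
#' @param cgc_channels electrode ids for the CGC panel, or `"tunnel"`
#'   (instrumented tunnel electrodes plus `cgc_per_layer` sampled
#'   electrodes per layer) or `"all"`.
#' @param cgc_per_layer layer electrodes sampled when
#'   `cgc_channels = "tunnel"`.
#' @param scales_ms fidelity timescale grid (ms).
#' @param max_pairs electrode-pair cap per pairing class for the fidelity
#'   sweep.
#' @param seed integer seed for all stage randomness.
#' @param out_dir optional directory for stage artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, spikes_tsv = NULL, layout_json = NULL,
                       t_stop = NULL,
                       stages = c("bursts", "connectivity", "fidelity"),
                       min_rate = 0.01, isi_factor = 0.25, min_channels = 1,
                       min_overlap = 0.20, var_order = 10,
                       fdr_threshold = 1e-4, cgc_duration = 120,
                       cgc_channels = "tunnel", cgc_per_layer = 4,
                       scales_ms = c(1, 2, 5, 10, 20, 50, 100, 200, 500),
                       max_pairs = Inf, seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(sim) && (is.null(spikes_tsv) || is.null(layout_json) ||
                       is.null(t_stop)))
    stop("provide either `sim` or spikes_tsv + layout_json + t_stop")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: input (simulate or
#' load) -> rate filtering -> per-layer network bursts and propagation
#' matching -> tunnel direction calls and conditional Granger network ->
#' fidelity profiling. Identical configuration and seed give an identical
#' report. A failing stage stops with its name; artifacts written so far
#' are preserved.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: `burst_stats` (per layer),
#'   `propagation` (probability, delays, events), `direction_calls`,
#'   `cgc_graph` ([graph_statistics()]), `fidelity`
#'   ([fidelity_profile()]), `provenance` (config and seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  rec <- if (!is.null(config$sim)) simulate_recording(config$sim) else {
    layout <- read_layout_json(config$layout_json)
    trains <- read_spike_tsv(config$spikes_tsv, 0, config$t_stop)
    # collapse sorted units onto their electrode for electrode-level analysis
    by_el <- split(trains, vapply(trains, `[[`, "", "electrode_id"))
    trains <- lapply(by_el, function(g)
      spike_train(sort(unlist(lapply(g, `[[`, "times"))),
                  g[[1]]$electrode_id, 1L, 0, config$t_stop))
    structure(list(layout = layout, trains = trains, t_start = 0,
                   t_stop = config$t_stop, ground_truth = NULL,
                   config = NULL), class = "mea_recording")
  }
  diag <- validate_inputs(rec$trains, rec$layout)
  if (!diag$ok) stop("input validation failed:\n  ",
                     paste(diag$errors, collapse = "\n  "))
  kept <- filter_low_rate(rec$trains, config$min_rate)
  dropped <- setdiff(names(rec$trains), names(kept))
  for (e in dropped) rec$trains[[e]]$times <- numeric(0)

  report <- list(provenance = list(config = config, seed = config$seed,
                                   dropped_electrodes = dropped))
  out <- config$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_spike_tsv(rec$trains, file.path(out, "spikes.tsv"))
    write_layout_json(rec$layout, file.path(out, "layout.json"))
  }

  b1 <- b2 <- NULL; prop <- NULL
  if ("bursts" %in% config$stages) {
    b1 <- layer_bursts(rec, "LAYER1", config$isi_factor,
                       min_channels = config$min_channels)
    b2 <- layer_bursts(rec, "LAYER2", config$isi_factor,
                       min_channels = config$min_channels)
    trains1 <- rec$trains[layout_electrodes(rec$layout, "LAYER1")]
    trains2 <- rec$trains[layout_electrodes(rec$layout, "LAYER2")]
    dur <- rec$t_stop - rec$t_start
    report$burst_stats <- list(LAYER1 = summarize_bursts(b1, trains1, dur),
                               LAYER2 = summarize_bursts(b2, trains2, dur))
    prop <- match_propagation(b1, b2, config$min_overlap)
    report$propagation <- list(
      probability = prop$probability, undefined = isTRUE(prop$undefined),
      n_events = nrow(prop$events),
      mean_peak_delay_s = if (nrow(prop$events)) mean(prop$events$peak_delay)
                          else NA_real_,
      events = prop$events)
    if (!is.null(out)) {
      write.csv(prop$events, file.path(out, "propagation_events.csv"),
                row.names = FALSE)
      write.csv(burst_table(c(b1, b2)), file.path(out, "bursts.csv"),
                row.names = FALSE)
    }
  }

  if ("connectivity" %in% config$stages) {
    calls <- list()
    for (i in seq_len(nrow(rec$layout$tunnel_pairs))) {
      pr <- rec$layout$tunnel_pairs[i, ]
      up <- rec$trains[[pr$upstream]]; down <- rec$trains[[pr$downstream]]
      calls[[i]] <- if (length(up$times) && length(down$times)) {
        cc <- cross_correlogram(up, down)
        cl <- classify_direction(cc, separation_um = pr$separation_um)
        data.frame(upstream = pr$upstream, downstream = pr$downstream,
                   direction = cl$direction, peak_lag_ms = cl$peak_lag_ms,
                   velocity_mps = cl$velocity_mps)
      } else data.frame(upstream = pr$upstream, downstream = pr$downstream,
                        direction = "UNDECIDED", peak_lag_ms = NA_real_,
                        velocity_mps = NA_real_)
    }
    report$direction_calls <- do.call(rbind, calls)
    chans <- cgc_channel_set(rec, config)
    if (length(chans) >= 2) {
      panel <- recording_to_panel(rec, chans, duration = config$cgc_duration)
      net <- suppressWarnings(
        conditional_granger(panel, config$var_order, config$fdr_threshold))
      report$cgc_graph <- graph_statistics(net, rec$layout)
      report$cgc_network <- net
      if (!is.null(out))
        write.csv(net$cgc, file.path(out, "cgc_matrix.csv"))
    }
    if (!is.null(out))
      write.csv(report$direction_calls,
                file.path(out, "direction_calls.csv"), row.names = FALSE)
  }

  if ("fidelity" %in% config$stages) {
    if (is.null(prop)) {
      b1 <- layer_bursts(rec, "LAYER1", config$isi_factor,
                         min_channels = config$min_channels)
      b2 <- layer_bursts(rec, "LAYER2", config$isi_factor,
                         min_channels = config$min_channels)
      prop <- match_propagation(b1, b2, config$min_overlap)
    }
    report$fidelity <- fidelity_profile(rec, prop, config$scales_ms,
                                        max_pairs = config$max_pairs)
    if (!is.null(out))
      write.csv(report$fidelity$records,
                file.path(out, "fidelity_records.csv"), row.names = FALSE)
  }

  if (!is.null(out)) {
    summ <- report[setdiff(names(report),
                           c("cgc_network", "fidelity", "propagation"))]
    summ$propagation <- report$propagation[c("probability", "n_events",
                                             "mean_peak_delay_s")]
    jsonlite::write_json(summ, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
  }
  class(report) <- "run_report"
  report
}

#' Flat table of network bursts
#' @param bursts list of `network_burst`.
#' @export
burst_table <- function(bursts) {
  if (length(bursts) == 0)
    return(data.frame(layer = character(0), start = numeric(0),
                      end = numeric(0), peak_time = numeric(0),
                      peak_rate = numeric(0), n_electrodes = integer(0)))
  do.call(rbind, lapply(bursts, function(b)
    data.frame(layer = b$layer, start = b$start, end = b$end,
               peak_time = b$peak_time, peak_rate = b$peak_rate,
               n_electrodes = length(b$electrodes))))
}

cgc_channel_set <- function(rec, config) {
  active <- names(rec$trains)[vapply(rec$trains, length, 1L) > 0]
  if (identical(config$cgc_channels, "all")) return(active)
  if (identical(config$cgc_channels, "tunnel")) {
    tun <- unique(c(rec$layout$tunnel_pairs$upstream,
                    rec$layout$tunnel_pairs$downstream))
    pick <- function(layer) {
      ids <- intersect(layout_electrodes(rec$layout, layer), active)
      if (length(ids) > config$cgc_per_layer)
        sort(sample(ids, config$cgc_per_layer)) else ids
    }
    return(intersect(c(tun, pick("LAYER1"), pick("LAYER2")), active))
  }
  intersect(config$cgc_channels, active)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$burst_stats))
    cat(sprintf("  bursts: L1 %d (%.2f/min), L2 %d; propagation p=%.2f (%d events)\n",
                x$burst_stats$LAYER1$n_bursts,
                x$burst_stats$LAYER1$bursts_per_min,
                x$burst_stats$LAYER2$n_bursts,
                x$propagation$probability, x$propagation$n_events))
  if (!is.null(x$direction_calls))
    cat("  direction calls:",
        paste(sprintf("%s", x$direction_calls$direction), collapse = ", "),
        "\n")
  if (!is.null(x$cgc_graph))
    cat(sprintf("  CGC graph: %d edges, reciprocity %.1f%%\n",
                x$cgc_graph$n_edges, x$cgc_graph$reciprocity_pct))
  if (!is.null(x$fidelity))
    cat(sprintf("  fidelity records: %d\n", nrow(x$fidelity$records)))
  invisible(x)
}
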
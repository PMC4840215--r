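#!/usr/bin/env Rscript
# Network-burst statistics per layer and Layer I -> Layer II propagation:
# burst rates, durations, in-burst firing, fraction of spikes inside
# bursts, propagation probability and peak-to-peak delay per group.

source("analysis/00_config.R")

burst_rows <- list(); prop_rows <- list()
for (nt in GROUPS) {
  rec <- load_or_simulate(nt)
  b <- group_bursts(rec)
  for (layer in c("LAYER1", "LAYER2")) {
    trains <- rec$trains[layout_electrodes(rec$layout, layer)]
    st <- summarize_bursts(if (layer == "LAYER1") b$L1 else b$L2, trains,
                           DURATION)
    burst_rows[[length(burst_rows) + 1]] <- data.frame(
      group = sprintf("%dT", nt), layer = layer,
      bursts_per_min = st$bursts_per_min,
      mean_duration_ms = 1000 * st$mean_duration_s,
      in_burst_rate_hz = st$mean_in_burst_rate_hz,
      peak_rate_hz = st$mean_peak_rate_hz,
      fraction_in_bursts = st$fraction_in_bursts)
  }
  pr <- match_propagation(b$L1, b$L2)
  truth <- rec$ground_truth
  prop_rows[[length(prop_rows) + 1]] <- data.frame(
    group = sprintf("%dT", nt),
    probability = pr$probability,
    true_probability = nrow(truth$propagation_links) /
      sum(truth$burst_events$layer == "LAYER1"),
    n_events = nrow(pr$events),
    mean_peak_delay_ms = 1000 * mean(pr$events$peak_delay),
    mean_overlap_pct = 100 * mean(pr$events$overlap_fraction))
  cat(sprintf("%3dT: p=%.2f (true %.2f), delay %.0f ms, overlap %.0f%%\n",
              nt, pr$probability,
              prop_rows[[length(prop_rows)]]$true_probability,
              prop_rows[[length(prop_rows)]]$mean_peak_delay_ms,
              prop_rows[[length(prop_rows)]]$mean_overlap_pct))
}
write.csv(do.call(rbind, burst_rows), "results/burst_stats.csv",
          row.names = FALSE)
write.csv(do.call(rbind, prop_rows), "results/propagation.csv",
          row.names = FALSE)
cat("wrote results/burst_stats.csv, results/propagation.csv\n")
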
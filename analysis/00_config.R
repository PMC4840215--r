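# Shared configuration for the analysis scripts: one simulated culture per
# tunnel-count group, 10-minute recordings, deterministic seeds. Recordings
# are cached under results/data/ as plain-text spike tables so the later
# stages can be re-run independently.

library(ffmea)

GROUPS <- c(2, 5, 10, 15, 51)
DURATION <- 600          # s, matching the 10-min recording sessions
BURST_RATE <- 4          # bursts/min, concentrated for desk-scale runs
MIN_CHANNELS <- 5        # electrodes required to call a network burst
SEED_BASE <- 2026

group_dir <- function(nt) file.path("results", "data", sprintf("%02dT", nt))

load_or_simulate <- function(nt) {
  dir <- group_dir(nt)
  cfg <- sim_config(nt, duration = DURATION, seed = SEED_BASE + nt,
                    burst_rate_layer1 = BURST_RATE)
  if (!file.exists(file.path(dir, "spikes.tsv"))) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rec <- simulate_recording(cfg)
    write_spike_tsv(rec$trains, file.path(dir, "spikes.tsv"))
    write_layout_json(rec$layout, file.path(dir, "layout.json"))
    jsonlite::write_json(rec$ground_truth, file.path(dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
    return(rec)
  }
  # deterministic: re-simulation reproduces the cached tables exactly
  simulate_recording(cfg)
}

group_bursts <- function(rec) {
  list(L1 = layer_bursts(rec, "LAYER1", min_channels = MIN_CHANNELS),
       L2 = layer_bursts(rec, "LAYER2", min_channels = MIN_CHANNELS))
}

# connectivity panel: instrumented tunnel electrodes plus a small sample of
# chamber electrodes per layer (keeps the VAR fit tractable on one CPU)
cgc_channel_set_for <- function(rec, per_layer = 3) {
  active <- names(rec$trains)[vapply(rec$trains, length, 1L) > 0]
  tun <- unique(c(rec$layout$tunnel_pairs$upstream,
                  rec$layout$tunnel_pairs$downstream))
  pick <- function(layer) {
    ids <- intersect(layout_electrodes(rec$layout, layer), active)
    sort(sample(ids, min(per_layer, length(ids))))
  }
  intersect(c(tun, pick("LAYER1"), pick("LAYER2")), active)
}

# share of significant inter-region CGC edges pointing downstream
# (Layer I -> tunnel -> Layer II) among all inter-region edges
feed_forward_fraction <- function(net, layout) {
  adj <- net$adjacency
  reg <- layout$electrodes$region[match(colnames(adj),
                                        layout$electrodes$electrode_id)]
  rank <- c(LAYER1 = 1, TUNNEL = 2, LAYER2 = 3)[reg]
  src_rank <- matrix(rank, nrow(adj), ncol(adj))
  tgt_rank <- t(src_rank)
  inter <- adj & (src_rank != tgt_rank)
  if (!any(inter)) return(NA_real_)
  100 * sum(adj & src_rank < tgt_rank) / sum(inter)
}
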
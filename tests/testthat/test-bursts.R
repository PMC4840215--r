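mk_burst <- function(start, end, peak = (start + end) / 2, layer = "LAYER1") {
  structure(list(layer = layer, start = start, end = end,
                 electrodes = "x", n_burstlets = 1L, spike_times = c(start, end),
                 peak_rate = NA_real_, peak_time = peak),
            class = "network_burst")
}

test_that("burstlet detection follows the adaptive ISI threshold rule", {
  # 20 spikes over 10 s -> mean rate 2 Hz, threshold 0.25 * 0.5 s = 125 ms
  fast <- 1 + (0:4) * 0.010
  sparse <- 2 + (0:14) * 0.5
  tr <- spike_train(c(fast, sparse), t_start = 0, t_stop = 10)
  bl <- detect_burstlets(tr)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$spike_times, fast)
  expect_equal(bl[[1]]$start, 1.0)
  expect_equal(bl[[1]]$end, 1.04)

  # fewer than four spikes never form a burstlet
  tr3 <- spike_train(c(0.1, 0.102, 0.104, 3, 6, 9), t_start = 0, t_stop = 12)
  expect_length(detect_burstlets(tr3), 0)  # run of 3 at 2 ms ISIs

  # ISIs exactly at the threshold do not qualify (strict inequality)
  tr_eq <- spike_train(c(0.5, 0.75, 1.0, 1.25, 1.5), t_start = 0, t_stop = 5)
  # 5 spikes / 5 s -> threshold 0.25 * 1 = 0.25 s; all ISIs == 0.25
  expect_length(detect_burstlets(tr_eq), 0)
})

test_that("each spike belongs to at most one burstlet", {
  set.seed(8)
  for (i in 1:20) {
    tr <- spike_train(rand_times(60, 20), t_start = 0, t_stop = 20)
    bl <- detect_burstlets(tr)
    all_times <- unlist(lapply(bl, `[[`, "spike_times"))
    expect_equal(anyDuplicated(all_times), 0)
    for (b in bl) expect_true(all(diff(b$spike_times) <
                                    0.25 * 20 / length(tr$times)))
  }
})

test_that("a smaller ISI factor never yields more burstlets", {
  set.seed(9)
  for (i in 1:20) {
    tr <- spike_train(rand_times(80, 10), t_start = 0, t_stop = 10)
    n <- vapply(c(0.25, 0.15, 0.05), function(f)
      length(detect_burstlets(tr, isi_factor = f)), 1L)
    expect_true(all(diff(n) <= 0))
  }
})

test_that("network-burst merging is the transitive closure of overlap", {
  # direct overlap
  m <- merge_network_bursts(list(mk_burstlet("a", c(0, 0.02, 0.05)),
                                 mk_burstlet("b", c(0.04, 0.07, 0.09))))
  expect_length(m, 1)
  expect_equal(m[[1]]$start, 0); expect_equal(m[[1]]$end, 0.09)
  expect_setequal(m[[1]]$electrodes, c("a", "b"))

  # sub-minimum span is discarded
  expect_length(merge_network_bursts(list(mk_burstlet("a", c(0, 0.008)))), 0)

  # transitive chain merges into one burst
  ch <- merge_network_bursts(list(mk_burstlet("a", c(0, 0.020)),
                                  mk_burstlet("b", c(0.015, 0.035)),
                                  mk_burstlet("c", c(0.030, 0.060))))
  expect_length(ch, 1)
  expect_equal(c(ch[[1]]$start, ch[[1]]$end), c(0, 0.060))

  # random instances against the brute-force closure oracle
  set.seed(10)
  for (i in 1:15) {
    s <- runif(25, 0, 5); e <- s + runif(25, 0.001, 0.4)
    bl <- lapply(seq_along(s), function(j)
      mk_burstlet(paste0("e", j), c(s[j], e[j])))
    m <- merge_network_bursts(bl, min_duration = 0)
    comp <- interval_components_brute(s, e)
    expect_length(m, length(unique(comp)))
    spans <- sort(vapply(m, function(b) b$end - b$start, 0))
    spans_brute <- sort(unname(vapply(split(seq_along(s), comp), function(g)
      max(e[g]) - min(s[g]), 0)))
    expect_equal(spans, spans_brute)
  }
})

test_that("merged bursts within a layer are pairwise disjoint", {
  rec <- simulate_recording(sim_config(51, 120, seed = 17))
  b <- layer_bursts(rec, "LAYER1")
  if (length(b) > 1) {
    s <- vapply(b, `[[`, 0, "start"); e <- vapply(b, `[[`, 0, "end")
    expect_true(all(s[-1] > e[-length(e)]))
  }
  expect_gt(length(b), 0)
})

test_that("burst peak matches the closed-form single-impulse response", {
  g0 <- 1 / sum(exp(-((-20:20) * 0.001)^2 / (2 * 0.005^2)))
  b <- merge_network_bursts(list(mk_burstlet("a", rep(0.2, 8) + 1e-9 * (0:7)),
                                 mk_burstlet("a", c(0.25, 0.26))))
  pk <- burst_peak(c(rep(0.2, 10)))
  expect_equal(pk$peak_time, 0.2005)
  expect_equal(pk$peak_rate, 10 * g0 / 0.001, tolerance = 1e-10)

  # two equal impulses 100 ms apart: earliest local maximum wins
  pk2 <- burst_peak(c(rep(0.1, 5), rep(0.2, 5)))
  expect_equal(pk2$peak_time, 0.1005)
})

test_that("burst summaries compute the stated ratios", {
  # one burst spanning exactly [1.0, 1.5] on two electrodes, 50 spikes inside
  e1 <- seq(1.0, 1.5, length.out = 25)
  e2 <- seq(1.0, 1.5, length.out = 25)
  bursts <- merge_network_bursts(list(mk_burstlet("e1", e1),
                                      mk_burstlet("e2", e2)))
  trains <- list(e1 = spike_train(c(e1, seq(3, 32, 1)), "e1", t_stop = 60),
                 e2 = spike_train(c(e2, seq(3.5, 22.5, 1)), "e2", t_stop = 60))
  st <- summarize_bursts(bursts, trains, 60)
  expect_equal(st$mean_in_burst_rate_hz, 50 / (2 * 0.5))
  expect_equal(st$fraction_in_bursts, 50 / (50 + 30 + 20))

  # 12 disjoint bursts in 600 s -> 1.2 bursts/min
  bl <- lapply(1:12, function(k) mk_burstlet("a", c(k * 40, k * 40 + 0.2)))
  st2 <- summarize_bursts(merge_network_bursts(bl),
                          list(a = spike_train(seq(1, 500, 1), t_stop = 600)),
                          600)
  expect_equal(st2$n_bursts, 12L)
  expect_equal(st2$bursts_per_min, 1.2)
})

test_that("propagation matching applies the 20% overlap criterion", {
  # overlap 0.05/0.5 = 0.10 -> no event
  r1 <- match_propagation(list(mk_burst(0, 0.5, 0.10)),
                          list(mk_burst(0.45, 0.9, 0.60, "LAYER2")))
  expect_equal(nrow(r1$events), 0)
  expect_equal(r1$probability, 0)

  # overlap 0.25/0.5 = 0.50 -> event with peak delay 0.50
  r2 <- match_propagation(list(mk_burst(0, 0.5, 0.10)),
                          list(mk_burst(0.25, 0.9, 0.60, "LAYER2")))
  expect_equal(nrow(r2$events), 1)
  expect_equal(r2$events$overlap_fraction, 0.5)
  expect_equal(r2$events$peak_delay, 0.5)
  expect_equal(r2$events$window_start, 0.25)
  expect_equal(r2$events$window_end, 0.5)

  # boundary: exactly 20% overlap is kept
  r3 <- match_propagation(list(mk_burst(0, 0.5, 0.1)),
                          list(mk_burst(0.4, 1.0, 0.7, "LAYER2")))
  expect_equal(nrow(r3$events), 1)

  # identical burst lists -> probability 1, zero delays
  b <- lapply(c(0, 2, 4), function(s) mk_burst(s, s + 0.5, s + 0.2))
  r4 <- match_propagation(b, b)
  expect_equal(r4$probability, 1)
  expect_true(all(r4$events$peak_delay == 0))

  # no Layer I bursts: probability undefined, flagged
  r5 <- match_propagation(list(), b)
  expect_true(is.na(r5$probability))
  expect_true(r5$undefined)
})

test_that("ground-truth bursts are recovered by the detector", {
  rec <- simulate_recording(sim_config(51, 300, seed = 19))
  gt <- rec$ground_truth$burst_events
  ok <- 0
  for (layer in c("LAYER1", "LAYER2")) {
    det <- layer_bursts(rec, layer, min_channels = 5)
    tg <- gt[gt$layer == layer, ]
    for (i in seq_len(nrow(tg)))
      if (any(vapply(det, function(b)
        b$start <= tg$offset[i] && b$end >= tg$onset[i], TRUE)))
        ok <- ok + 1
  }
  expect_gte(ok / nrow(gt), 0.95)
})
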
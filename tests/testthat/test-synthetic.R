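test_that("layout geometry matches the two-chamber device", {
  for (nt in c(2, 5, 10, 15, 51)) {
    lay <- make_layout(nt)
    expect_equal(nrow(lay$electrodes), 60)
    expect_equal(sum(lay$electrodes$region == "LAYER1"), 22)
    expect_equal(sum(lay$electrodes$region == "LAYER2"), 22)
    expect_true(all(lay$electrodes$region[lay$electrodes$grid_row %in% 4:5] ==
                      "TUNNEL"))
    tun <- layout_electrodes(lay, "TUNNEL")
    expect_true(all(lay$tunnel_pairs$upstream %in% tun))
    expect_true(all(lay$tunnel_pairs$downstream %in% tun))
    expect_true(all(lay$tunnel_pairs$separation_um == 200))
    # upstream member on the Layer-I-facing tunnel row
    up_rows <- lay$electrodes$grid_row[match(lay$tunnel_pairs$upstream,
                                             lay$electrodes$electrode_id)]
    expect_true(all(up_rows == 4))
  }
  expect_equal(nrow(make_layout(2)$tunnel_pairs), 1)
  expect_equal(nrow(make_layout(5)$tunnel_pairs), 1)
  expect_equal(nrow(make_layout(10)$tunnel_pairs), 2)
  expect_equal(nrow(make_layout(15)$tunnel_pairs), 3)
  expect_equal(nrow(make_layout(51)$tunnel_pairs), 7)
  expect_error(make_layout(4), "unsupported")
})

test_that("recording simulation is seed-deterministic", {
  cfg <- sim_config(10, duration = 60, seed = 42)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(trains_to_table(r1$trains), trains_to_table(r2$trains))
  expect_identical(r1$ground_truth$burst_events, r2$ground_truth$burst_events)
  r3 <- simulate_recording(sim_config(10, duration = 60, seed = 43))
  expect_false(identical(trains_to_table(r1$trains), trains_to_table(r3$trains)))
})

test_that("zero propagation probability yields no Layer II bursts", {
  rec <- simulate_recording(sim_config(51, duration = 120, seed = 5,
                                       p_propagate = 0))
  gt <- rec$ground_truth
  expect_equal(nrow(gt$propagation_links), 0)
  expect_false(any(gt$burst_events$layer == "LAYER2"))
})

test_that("background-only firing rates match the Poisson expectation", {
  cfg <- sim_config(51, duration = 600, seed = 9, background_rate = 1,
                    burst_rate_layer1 = 0)
  rec <- simulate_recording(cfg)
  expect_equal(nrow(rec$ground_truth$burst_events), 0)
  counts <- vapply(rec$trains[layout_electrodes(rec$layout, "LAYER1")],
                   length, 1L)
  # per-electrode empirical rate within 3 SE of 1 Hz (Poisson counts)
  se <- sqrt(600) / 600
  expect_true(all(abs(counts / 600 - 1) < 3 * se))
})

test_that("spike bookkeeping is conserved and tunnel copies are exact", {
  cfg <- sim_config(51, duration = 120, seed = 7)
  rec <- simulate_recording(cfg)
  gt <- rec$ground_truth
  tot <- sum(vapply(rec$trains, length, 1L))
  expect_equal(tot, gt$n_background + gt$n_burst + gt$n_tunnel)
  # downstream = upstream + separation/velocity, exactly
  delay <- 200e-6 / cfg$conduction_velocity
  expect_equal(gt$tunnel_delay_s, delay)
  pr <- rec$layout$tunnel_pairs[1, ]
  up <- rec$trains[[pr$upstream]]$times
  down <- rec$trains[[pr$downstream]]$times
  shifted <- up + delay
  expect_true(all(shifted[shifted < rec$t_stop] %in% down))
})

test_that("propagation links respect the programmed onset delays", {
  rec <- simulate_recording(sim_config(51, duration = 300, seed = 3))
  gt <- rec$ground_truth
  expect_gt(nrow(gt$propagation_links), 0)
  src <- gt$burst_events[gt$propagation_links$source, ]
  tgt <- gt$burst_events[gt$propagation_links$target, ]
  expect_equal(tgt$onset, src$onset + gt$propagation_links$true_delay)
})

test_that("the coupling knob is monotone in tunnel count", {
  maps <- lapply(c(2, 5, 10, 15, 51), tunnel_coupling)
  p <- vapply(maps, `[[`, 0, "p_propagate")
  d <- vapply(maps, `[[`, 0, "delay_mean")
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(d) < 0))
  expect_equal(p[c(1, 5)], c(0.22, 0.72))
  expect_equal(d[c(1, 5)], c(0.280, 0.090), tolerance = 1e-12)
})

test_that("around 40% of simulated spikes fall inside detected bursts", {
  rec <- simulate_recording(sim_config(51, duration = 600, seed = 13))
  b1 <- layer_bursts(rec, "LAYER1", min_channels = 5)
  st <- summarize_bursts(b1, rec$trains[layout_electrodes(rec$layout, "LAYER1")],
                         600)
  expect_gt(st$fraction_in_bursts, 0.3)
  expect_lt(st$fraction_in_bursts, 0.6)
})

test_that("raw traces have the requested noise floor and clean templates", {
  set.seed(1)
  empty <- spike_train(numeric(0), t_start = 0, t_stop = 60)
  tr <- simulate_raw_trace(empty, noise_rms = 10, fs = 25000)
  expect_equal(sqrt(mean(tr$trace^2)), 10, tolerance = 0.05)
  one <- spike_train(0.5, t_start = 0, t_stop = 1)
  wf <- spike_waveform(25000, amp_uV = 80)
  clean <- simulate_raw_trace(one, noise_rms = 0, waveform = wf, fs = 25000)
  expect_equal(sum(clean$trace != 0), sum(wf != 0))
  expect_equal(min(clean$trace), min(wf))
  trough_idx <- which.min(clean$trace)
  expect_equal((trough_idx - 1) / 25000, 0.5, tolerance = 1e-4)
})

test_that("coupled panels are seed-deterministic and honour programmed edges", {
  p1 <- simulate_coupled_panel(NULL, 3, 60, 15, seed = 4)
  p2 <- simulate_coupled_panel(NULL, 3, 60, 15, seed = 4)
  expect_identical(trains_to_table(p1$trains), trains_to_table(p2$trains))
  # independent channels: binned count correlations near zero
  bins <- lapply(p1$trains, function(tr)
    tabulate(floor(tr$times / 0.05) + 1, nbins = 1200))
  cors <- c(cor(bins[[1]], bins[[2]]), cor(bins[[1]], bins[[3]]),
            cor(bins[[2]], bins[[3]]))
  expect_true(all(abs(cors) < 0.1))
  # programmed edge: target rate is elevated right after source spikes
  cp <- simulate_coupled_panel(
    data.frame(source = 1, target = 2, lag_ms = 2, strength = 30),
    2, 120, 20, seed = 6)
  src <- cp$trains[[1]]$times; tgt <- cp$trains[[2]]$times
  hits <- sum(vapply(src, function(s)
    any(tgt > s + 0.0015 & tgt <= s + 0.0025), TRUE))
  cond_rate <- hits / (length(src) * 0.001)
  expect_gt(cond_rate, 3 * 20)   # far above the 20 Hz baseline
})

test_that("spike tables and layouts round-trip through their text formats", {
  rec <- simulate_recording(sim_config(2, duration = 30, seed = 2))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_spike_tsv(rec$trains, tsv)
  back <- read_spike_tsv(tsv, 0, rec$t_stop)
  nonempty <- Filter(function(tr) length(tr$times) > 0, rec$trains)
  expect_equal(sum(vapply(back, length, 1L)),
               sum(vapply(nonempty, length, 1L)))
  e1 <- names(nonempty)[1]
  expect_equal(back[[paste0(e1, ".1")]]$times, nonempty[[e1]]$times,
               tolerance = 1e-12)
  write_layout_json(rec$layout, js)
  lay2 <- read_layout_json(js)
  expect_equal(lay2$electrodes, rec$layout$electrodes)
  expect_equal(lay2$tunnel_pairs, rec$layout$tunnel_pairs)
})
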
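test_that("Victor-Purpura distance obeys its closed forms", {
  expect_equal(vp_distance(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3), 50), 0)
  # q = 0: spike-count comparison
  expect_equal(vp_distance(rand_times(3), rand_times(5), 0), 2)
  # shift vs delete+insert tie at q|dt| = 2; here q|dt| = 1 wins
  expect_equal(vp_distance(0, 0.010, 100), 1.0)
  # q -> infinity: only exact coincidences survive
  x <- c(0.1, 0.2, 0.35); y <- c(0.2, 0.35, 0.5, 0.9)
  expect_equal(vp_distance(x, y, 1e9), 3 + 4 - 2 * 2)
  # empty trains
  expect_equal(vp_distance(numeric(0), y, 10), 4)
  expect_equal(vp_distance(numeric(0), numeric(0), 10), 0)
})

test_that("dynamic programme equals the brute-force edit minimum", {
  set.seed(22)
  for (i in 1:200) {
    x <- rand_times(sample(0:4, 1))
    y <- rand_times(sample(0:4, 1))
    q <- sample(c(0, 10, 100, 1000), 1)
    expect_equal(vp_distance(x, y, q), vp_brute(x, y, q), tolerance = 1e-12)
  }
})

test_that("the distance satisfies the metric axioms on random trains", {
  set.seed(23)
  for (i in 1:60) {
    x <- rand_times(sample(0:3, 1)); y <- rand_times(sample(0:3, 1))
    z <- rand_times(sample(0:3, 1)); q <- runif(1, 0, 500)
    dxy <- vp_distance(x, y, q)
    expect_gte(dxy, 0)
    expect_equal(vp_distance(x, x, q), 0)
    expect_equal(dxy, vp_distance(y, x, q), tolerance = 1e-12)
    expect_lte(dxy, vp_distance(x, z, q) + vp_distance(z, y, q) + 1e-12)
    expect_lte(dxy, length(x) + length(y))
  }
})

test_that("distance is non-decreasing in q, so similarity rises with 1/q", {
  set.seed(24)
  scales <- c(1, 2, 5, 10, 20, 50, 100, 200, 500)
  for (i in 1:40) {
    x <- rand_times(sample(1:6, 1)); y <- rand_times(sample(1:6, 1))
    d <- vapply(1000 / scales, function(q) vp_distance(x, y, q), 0)
    expect_true(all(diff(d) <= 1e-12))          # q decreasing along scales
    s <- vapply(1000 / scales, function(q) vp_similarity(x, y, q), 0)
    expect_true(all(diff(s) >= -1e-12))         # S_v non-decreasing in 1/q
  }
})

test_that("similarity normalization handles boundary cases", {
  expect_equal(vp_similarity(c(0.1, 0.5), c(0.1, 0.5), 100), 1.0)
  expect_equal(vp_similarity(numeric(0), c(1, 2, 3, 4), 10), 0.0)
  expect_equal(vp_similarity(0, 0.010, 100), 0.5)
  s <- vp_similarity(numeric(0), numeric(0), 10)
  expect_equal(as.numeric(s), 1)
  expect_true(attr(s, "degenerate"))
})

test_that("van Rossum similarity matches a direct kernel-correlation oracle", {
  mk <- function(t) spike_train(t, t_start = 0, t_stop = 2)
  # identity
  expect_equal(as.numeric(vr_similarity(mk(c(0.3, 0.7, 1.1)),
                                        mk(c(0.3, 0.7, 1.1)), 0.01)), 1.0)
  # two empty trains: degenerate 0
  s0 <- vr_similarity(mk(numeric(0)), mk(numeric(0)), 0.01)
  expect_equal(as.numeric(s0), 0); expect_true(attr(s0, "degenerate"))
  # single spikes: direct correlation of the two truncated exponentials
  oracle <- function(t1, t2, tau, t_stop = 2, bin = 0.001) {
    n <- t_stop / bin
    kern <- exp(-seq(0, 8 * tau, by = bin) / tau); kern <- kern / sum(kern)
    f <- function(t) { y <- numeric(n); b <- floor(t / bin) + 1
      idx <- b:min(b + length(kern) - 1, n); y[idx] <- kern[seq_along(idx)]; y }
    cor(f(t1), f(t2))
  }
  for (tau in c(0.005, 0.02)) {
    got <- vr_similarity(mk(0.4), mk(0.45), tau)
    expect_equal(attr(got, "raw"), oracle(0.4, 0.45, tau), tolerance = 1e-6)
  }
  # spikes separated by far more than 8*tau: clamped to 0
  far <- vr_similarity(mk(0.1), mk(1.9), 0.005)
  expect_equal(as.numeric(far), 0)
  expect_lt(attr(far, "raw"), 0)
  expect_error(vr_similarity(mk(0.1), mk(0.2), 0.01, window = c(1, 1)),
               "window")
})

test_that("van Rossum similarity is invariant to a common time shift", {
  set.seed(25)
  x <- rand_times(20, 1) + 0.2; y <- rand_times(25, 1) + 0.2
  s1 <- vr_similarity(x, y, 0.02, window = c(0, 1.5))
  s2 <- vr_similarity(x + 3, y + 3, 0.02, window = c(3, 4.5))
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-10)
})

test_that("window extraction keeps exactly the spikes inside the union", {
  tr <- spike_train(c(0.1, 0.3, 0.5), t_start = 0, t_stop = 1)
  expect_equal(extract_window_trains(tr, cbind(0, 1))$times, tr$times)
  expect_length(extract_window_trains(tr, matrix(numeric(0), ncol = 2))$times, 0)
  expect_equal(extract_window_trains(tr, cbind(0.2, 0.4))$times, 0.3)
  # overlapping windows are merged; times preserved on the recording clock
  got <- extract_window_trains(tr, rbind(c(0.05, 0.35), c(0.25, 0.55)))
  expect_equal(got$times, c(0.1, 0.3, 0.5))
  expect_equal(complement_windows(cbind(0.2, 0.4), 0, 1),
               rbind(c(0, 0.2), c(0.4, 1)))
})

test_that("a copied layer yields perfect between-layer VP fidelity", {
  lay <- make_layout(51)
  base <- sort(runif(40, 0, 10))
  times <- setNames(rep(list(base), 60), lay$electrodes$electrode_id)
  rec <- mk_recording(times)
  events <- data.frame(source = 1, target = 1, overlap_fraction = 1,
                       peak_delay = 0, window_start = 0, window_end = 10)
  fp <- fidelity_profile(rec, events, scales_ms = c(5, 50, 500),
                         metrics = "VP", max_pairs = 20)
  expect_true(all(fp$records$similarity == 1))
})

test_that("profile fast path agrees with the public metric functions", {
  set.seed(26)
  lay <- make_layout(2)
  times <- lapply(setNames(nm = lay$electrodes$electrode_id),
                  function(e) sort(runif(30, 0, 10)))
  rec <- mk_recording(times, n_tunnels = 2)
  events <- data.frame(source = 1, target = 1, overlap_fraction = 1,
                       peak_delay = 0, window_start = 2, window_end = 6)
  fp <- fidelity_profile(rec, events, scales_ms = 20, max_pairs = Inf)
  wins <- cbind(2, 6)
  r <- fp$records
  picks <- r[r$window_class == "IN_BURST" &
               r$pairing_class == "BETWEEN_LAYERS", ][c(1, 7, 40), ]
  for (i in seq_len(nrow(picks))) {
    ids <- strsplit(picks$pair[i], "-")[[1]]
    ta <- extract_window_trains(rec$trains[[ids[1]]], wins)
    tb <- extract_window_trains(rec$trains[[ids[2]]], wins)
    if (picks$metric[i] == "VP") {
      expect_equal(picks$similarity[i], as.numeric(vp_similarity(ta, tb, 50)))
    } else {
      expect_equal(picks$similarity[i],
                   as.numeric(vr_similarity(ta, tb, 0.02, window = c(0, 10),
                                            subset_windows = wins)),
                   tolerance = 1e-10)
    }
  }
})

test_that("independent layers carry more rate than temporal similarity", {
  set.seed(27)
  lay <- make_layout(51)
  times <- lapply(setNames(nm = lay$electrodes$electrode_id), function(e) {
    # common slow rate modulation, independent spike timing
    n1 <- rpois(1, 40); n2 <- rpois(1, 160)
    sort(c(runif(n1, 0, 5), runif(n2, 5, 10)))
  })
  rec <- mk_recording(times)
  events <- data.frame(source = 1, target = 1, overlap_fraction = 1,
                       peak_delay = 0, window_start = 0, window_end = 10)
  fp <- fidelity_profile(rec, events, scales_ms = c(5, 10, 100, 200),
                         metrics = "VP", max_pairs = 30,
                         window_classes = "IN_BURST")
  rg <- fp$regimes
  rate <- rg$similarity[rg$regime == "RATE" &
                          rg$pairing_class == "BETWEEN_LAYERS"]
  temporal <- rg$similarity[rg$regime == "TEMPORAL" &
                              rg$pairing_class == "BETWEEN_LAYERS"]
  expect_gt(rate, temporal)
})

test_that("missing propagation events flag the in-burst profile", {
  lay <- make_layout(2)
  times <- lapply(setNames(nm = lay$electrodes$electrode_id),
                  function(e) sort(runif(5, 0, 10)))
  rec <- mk_recording(times, n_tunnels = 2)
  fp <- fidelity_profile(rec, NULL, scales_ms = 50, metrics = "VP",
                         max_pairs = 5)
  expect_match(fp$flags, "IN_BURST")
  expect_false("IN_BURST" %in% fp$records$window_class)
})
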
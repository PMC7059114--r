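test_that("trigger selection modes follow the published rules", {
  dur <- 100
  inn <- spike_train(c(1.0, 2.0, 5.0, 5.030), dur, "IN", "in1")
  cs <- spike_train(c(1.990, 4.970), dur, "PC_COMPLEX", "cs")
  # spikes within 25 ms after a complex spike are dropped as triggers:
  # 2.0 is 10 ms after a CS (dropped); 5.0 is 30 ms after (kept)
  kept <- select_trigger_spikes(inn, cs, "EXCLUDE_POST_CS")
  expect_equal(kept, c(1.0, 5.0, 5.030))
  expect_error(select_trigger_spikes(inn, NULL, "EXCLUDE_POST_CS"),
               "complex")
  # no complex spikes: identity
  empty_cs <- spike_train(numeric(0), dur, "PC_COMPLEX", "cs")
  expect_equal(select_trigger_spikes(inn, empty_cs, "EXCLUDE_POST_CS"),
               inn$times)
  # ISI range [0, 20 ms): only the spike with the 15 ms preceding ISI
  t2 <- spike_train(c(1.0, 1.015, 1.165), dur, "IN", "i")
  expect_equal(select_trigger_spikes(t2, mode = "ISI_RANGE",
                                     params = list(lo = 0, hi = 0.020)),
               1.015)
  # SENSORY_FAST keeps spikes within 20 ms of an onset
  t3 <- spike_train(c(0.5, 10.005, 10.025, 12.0), dur, "IN", "i")
  expect_equal(select_trigger_spikes(t3, mode = "SENSORY_FAST",
                                     params = list(onsets = c(10, 12.5))),
               10.005)
})

test_that("compute_ccg places counts in half-open bins", {
  cc <- compute_ccg(1.0, c(1.005), bin_size = 0.010, duration = 2)
  expect_equal(cc$n_triggers, 1L)
  expect_equal(sum(cc$counts), 1)
  expect_equal(cc$counts[cc$lags == 0], 1)  # lag 0 bin is [0, 10) ms
  # exactly at lag 0 belongs to the first post-trigger bin
  cc0 <- compute_ccg(1.0, c(1.0), bin_size = 0.010, duration = 2)
  expect_equal(cc0$counts[cc0$lags == 0], 1)
  # empty target: all-zero counts, flagged baseline
  cce <- compute_ccg(1.0, numeric(0), bin_size = 0.010, duration = 2)
  expect_true(all(cce$counts == 0))
  expect_true(cce$baseline_flagged)
  expect_true(all(is.na(cce$normalized)))
})

test_that("compute_ccg equals the brute-force O(n^2) oracle", {
  set.seed(20)
  for (r in 1:12) {
    dur <- 50
    trig <- sort(runif(rpois(1, 150), 0, dur))
    targ <- sort(runif(rpois(1, 400), 0, dur))
    bin <- sample(c(0.010, 0.005, 0.001, 0.0005), 1)
    cc <- compute_ccg(trig, targ, bin_size = bin, duration = dur)
    keep <- trig >= 0.1 & trig <= dur - 0.1
    expect_equal(cc$counts * cc$n_triggers,
                 brute_ccg_counts(trig[keep], targ, bin, 0.1))
    expect_equal(cc$n_edge_dropped, sum(!keep))
  }
})

test_that("total CCG counts are conserved", {
  set.seed(21)
  dur <- 120
  trig <- sort(runif(300, 0.1, dur - 0.1))
  targ <- sort(runif(800, 0, dur))
  cc <- compute_ccg(trig, targ, bin_size = 0.010, duration = dur)
  n_pairs <- sum(vapply(trig, function(t)
    sum(targ >= t - 0.1 & targ < t + 0.1), 0))
  expect_equal(sum(cc$counts) * cc$n_triggers, n_pairs)
})

test_that("block shuffle conserves spikes and within-block structure", {
  set.seed(22)
  tt <- sort(runif(100, 0, 37))           # 37 s: final partial block
  sh <- block_shuffle(tt, 37, block = 5)
  expect_length(sh, 100L)
  expect_error(block_shuffle(tt, 8, block = 5), "impossible")
  # all spikes in one block keep their relative intervals
  t2 <- c(2.0, 2.1, 2.5)
  for (i in 1:10) {
    s2 <- block_shuffle(t2, 20, block = 5)
    expect_equal(diff(s2), diff(t2))
  }
})

test_that("two-block shuffle is a uniform coin flip", {
  set.seed(23)
  tt <- c(1, 2, 6)
  # 10 s = exactly 2 blocks; the second spike is 2 (identity) or 6 (swap)
  draws <- replicate(1000, block_shuffle(tt, 10, block = 5)[2])
  counts <- table(round(draws, 6))
  expect_equal(sort(unique(round(draws, 6))), c(2, 6))
  expect_gt(min(counts), 420)             # ~50/50 over 1000 draws
})

test_that("shuffle null is flat, reproducible, and flags degenerate n", {
  set.seed(24)
  dur <- 600
  trig <- sort(runif(8 * dur, 0, dur))
  targ <- spike_train(sort(runif(26 * dur, 0, dur)), dur, "PC_SIMPLE", "pc",
                      refractory = 0)
  null <- build_shuffle_null(trig, targ, n_shuffles = 500, seed = 31)
  expect_true(all(abs(null$mean_norm - 1) < 0.05))
  null2 <- build_shuffle_null(trig, targ, n_shuffles = 500, seed = 31)
  expect_identical(null$mean_norm, null2$mean_norm)
  expect_identical(null$sd_raw, null2$sd_raw)
  n1 <- build_shuffle_null(trig, targ, n_shuffles = 1, seed = 32)
  expect_true(n1$unusable)
})

test_that("shuffling destroys short-lag coupling but preserves rates", {
  ses <- simulate_pair(world_inhibition(0.7), 600, seed = 33)
  trig <- ses$trains$IN1$times
  cc <- compute_ccg(trig, ses$trains$PC1s)
  expect_lt(cc$normalized[cc$lags == 0], 0.85)   # visible ~30% dip
  null <- build_shuffle_null(trig, ses$trains$PC1s, 500, seed = 34)
  expect_true(all(abs(null$mean_norm - 1) < 0.05))
})

test_that("zscore_ccg implements the stated normalization identity", {
  lags <- seq(-0.1, 0.09, by = 0.010)
  cc <- structure(list(lags = lags, counts = rep(0.2, 20),
                       normalized = rep(1, 20), bin_size = 0.010,
                       window = 0.1, baseline_rate = 0.2,
                       baseline_flagged = FALSE, n_triggers = 100L),
                  class = "ccg")
  null <- structure(list(lags = lags, bin_size = 0.010,
                         mean_norm = rep(1, 20),
                         sd_raw = rep(0.02, 20)),
                    class = "shuffle_null")
  # original equals shuffle mean -> z = 0
  z <- zscore_ccg(cc, null)
  expect_true(all(z$z == 0))
  # normalized 0.70, shuffle mean 1.00, SD (normalized to baseline) 0.10
  cc$normalized[11] <- 0.70
  null$sd_raw <- rep(0.02, 20)             # 0.02 / 0.2 = 0.10 normalized
  z2 <- zscore_ccg(cc, null)
  expect_equal(z2$z[11], -3.0)
  # SD = 0 bins are excluded and reported
  null$sd_raw[3] <- 0
  z3 <- zscore_ccg(cc, null)
  expect_true(is.na(z3$z[3]))
  expect_equal(z3$undefined_bins, 3L)
  # mismatched binning errors
  null$bin_size <- 0.005
  expect_error(zscore_ccg(cc, null), "mismatched")
})

test_that("threshold crossing latency reads the first signed crossing", {
  zv <- rep(0, 200)
  z <- zccg_stub(zv, bin_size = 0.001)
  expect_true(is.na(threshold_crossing_latency(z, -1)))
  zv[z$ccg$lags >= 0.014 - 1e-12 & z$ccg$lags < 0.015 - 1e-12] <- -3.5
  z <- zccg_stub(zv, bin_size = 0.001)
  expect_equal(threshold_crossing_latency(z, -1), 0.014)
  zv2 <- rep(0, 200); zv2[105] <- 4         # lag 4 ms bin
  z2 <- zccg_stub(zv2, bin_size = 0.001)
  expect_equal(threshold_crossing_latency(z2, +1), 0.004)
})

test_that("synchrony fraction matches closed forms", {
  a <- spike_train(seq(1, 99, by = 1), 100, "IN", "a")
  expect_equal(synchrony_fraction(a, a)$pair, 1.0)
  b <- spike_train(seq(1, 99, by = 1) + 0.006, 100, "IN", "b")
  expect_equal(synchrony_fraction(a, b, tol = 0.005)$pair, 0)
  # independent Poisson 8 Hz pair over 10 min: 1 - exp(-2 * 8 * 0.005)
  set.seed(25)
  dur <- 600
  p1 <- spike_train(sort(runif(8 * dur, 0, dur)), dur, "IN", "p1",
                    refractory = 0)
  p2 <- spike_train(sort(runif(8 * dur, 0, dur)), dur, "IN", "p2",
                    refractory = 0)
  expect_lt(abs(synchrony_fraction(p1, p2)$pair -
                  (1 - exp(-8 * 0.01))), 0.02)
})

test_that("simulated excitation latency precedes inhibition latency", {
  cfg <- analysis_config()
  ords <- vapply(1:5, function(s) {
    exc <- ground_truth(kernels = list(
      gt_kernel("PC1c", "IN1", "ALPHA", gain = 3, onset = 0.003,
                par = 0.008)))
    inh <- ground_truth(kernels = list(
      gt_kernel("PC1c", "IN1", "BOX_GAIN", gain = 0.2, onset = 0.012,
                par = 0.020)))
    se <- simulate_pair(exc, 600, seed = 100 + s)
    si <- simulate_pair(inh, 600, seed = 200 + s)
    ze <- session_zccg(se, "PC1c", "IN1", cfg$bin_in_in, cfg, seed = s)
    zi <- session_zccg(si, "PC1c", "IN1", cfg$bin_in_in, cfg, seed = s)
    le <- threshold_crossing_latency(ze, +1)
    li <- threshold_crossing_latency(zi, -1)
    isTRUE(le < li)
  }, TRUE)
  expect_gte(mean(ords), 0.8)
})
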
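test_that("IN-PC classification applies the 0-10 ms / -10-0 ms windows", {
  zv <- rep(0, 20)
  zv[11] <- -3.5                            # [0, 10) ms bin
  cl <- classify_in_pc(zccg_stub(zv))
  expect_true(cl$in_pc_inhibition)
  expect_false(cl$in_pc_coactivation)
  zv[11] <- -2.9                            # just under threshold
  expect_false(classify_in_pc(zccg_stub(zv))$in_pc_inhibition)
  zv[11] <- 0; zv[10] <- 3.4                # [-10, 0) ms bin
  expect_true(classify_in_pc(zccg_stub(zv))$in_pc_coactivation)
})

test_that("CF-IN classification uses the published bins and ordering", {
  zv <- rep(0, 20)
  zv[12] <- 3.2                             # 10-20 ms: excitation window
  cl <- classify_cf_in(zccg_stub(zv))
  expect_true(cl$cf_in_excitation)
  expect_false(cl$cf_in_inhibition)
  zv <- rep(0, 20); zv[13] <- -3.2          # 20-30 ms: inhibition window
  cl <- classify_cf_in(zccg_stub(zv))
  expect_true(cl$cf_in_inhibition)
  expect_false(cl$cf_in_excitation)
  # 30-40 ms crossing alone is not significant for either
  zv <- rep(0, 20); zv[14] <- -5
  cl <- classify_cf_in(zccg_stub(zv))
  expect_false(cl$cf_in_inhibition || cl$cf_in_excitation)
  # combined: both present, excitation onset earlier
  zv <- rep(0, 20); zv[11] <- 4; zv[13] <- -4
  cl <- classify_cf_in(zccg_stub(zv))
  expect_true(cl$cf_in_combined)
  expect_false(cl$cf_in_excitation || cl$cf_in_inhibition)
  expect_lt(cl$latency_excitation, cl$latency_inhibition)
})

test_that("IN-IN classification assigns direction from the deficit side", {
  z0 <- rep(0, 40)
  za <- z0; za[21] <- -4                    # A-triggered, 0-5 ms deficit
  cl <- classify_in_in(zccg_stub(za, bin_size = 0.005),
                       zccg_stub(z0, bin_size = 0.005))
  expect_true(cl$in_in_inhibition)
  expect_equal(cl$direction, "A->B")
  # the mirrored case: deficit before the B-trigger also means A->B
  zb <- z0; zb[19] <- -4                    # B-triggered, -10..-5 ms
  cl2 <- classify_in_in(zccg_stub(z0, bin_size = 0.005),
                        zccg_stub(zb, bin_size = 0.005))
  expect_equal(cl2$direction, "A->B")
  # both directions -> bidirectional
  cl3 <- classify_in_in(zccg_stub(za, bin_size = 0.005),
                        zccg_stub(za, bin_size = 0.005))
  expect_equal(cl3$direction, "bidirectional")
  # co-activation from a positive bin within +/-10 ms
  zc <- z0; zc[20] <- 3.5
  cl4 <- classify_in_in(zccg_stub(zc, bin_size = 0.005),
                        zccg_stub(z0, bin_size = 0.005))
  expect_true(cl4$in_in_coactivation)
  expect_false(cl4$in_in_inhibition)
})

test_that("gap junction flag needs prominent twin peaks at +/-1 ms", {
  nb <- 400                                  # 0.5 ms bins over +/-100 ms
  zv <- rep(0, nb)
  norm <- rep(1, nb)
  lags <- seq(-0.1, 0.1 - 0.0005, by = 0.0005)
  pos <- which(lags >= 0.0005 & lags < 0.0015)
  neg <- which(lags >= -0.0015 & lags < -0.0005)
  # twin peaks, high and prominent
  zv[c(pos, neg)] <- 6; norm[c(pos, neg)] <- 5
  z <- zccg_stub(zv, bin_size = 0.0005, normalized = norm)
  expect_true(gap_junction_flag(z))
  # one-sided peak fails
  zv2 <- rep(0, nb); n2 <- rep(1, nb)
  zv2[pos] <- 6; n2[pos] <- 5
  expect_false(gap_junction_flag(zccg_stub(zv2, bin_size = 0.0005,
                                           normalized = n2)))
  # broad elevation without prominence fails
  zv3 <- rep(4, nb); n3 <- rep(1.3, nb)
  expect_false(gap_junction_flag(zccg_stub(zv3, bin_size = 0.0005,
                                           normalized = n3)))
})

test_that("pair geometry distances and normalized positions", {
  g0 <- soma_geometry(0, 0, 250, 250, 50)
  expect_equal(unclass(compute_pair_geometry(g0, g0))[1:3],
               list(transverse_distance = 0, sagittal_distance = 0,
                    ml_depth_distance = 0))
  # soma midway between PC layer and dura
  gm <- soma_geometry(0, 0, 150, 250, 50)
  pg <- compute_pair_geometry(g0, gm)
  expect_equal(pg$normalized_ml_position_b, 0.5)
  expect_equal(pg$normalized_ml_position_a, 0)
  # 3-4-5 in the transverse plane
  g3 <- soma_geometry(3, 0, 250 - 4, 250, 50)
  expect_equal(compute_pair_geometry(g0, g3)$transverse_distance, 5)
  expect_equal(compute_pair_geometry(g0, g3)$ml_depth_distance, 4)
  expect_error(soma_geometry(0, 0, 100, 100, 200), "shallower")
})

test_that("prevalence by distance bins with bootstrap SD", {
  flags <- rep(TRUE, 12)
  d <- runif(12, 0, 24)
  pv <- prevalence_by_distance(flags, d, breaks = c(0, 25, 50),
                               n_boot = 200, seed = 1)
  expect_equal(pv$fraction[1], 1.0)
  expect_equal(pv$n[2], 0L)
  expect_true(is.na(pv$fraction[2]))
  pv2 <- prevalence_by_distance(flags, d, breaks = c(0, 25, 50),
                                n_boot = 200, seed = 1)
  expect_identical(pv, pv2)
  # bootstrap SD tracks the exact binomial SD in a single bin
  set.seed(2)
  flags <- runif(40) < 0.5
  pv3 <- prevalence_by_distance(flags, rep(10, 40), breaks = c(0, 25),
                                n_boot = 2000, seed = 3)
  p <- mean(flags)
  expect_lt(abs(pv3$boot_sd - sqrt(p * (1 - p) / 40)),
            0.1 * sqrt(p * (1 - p) / 40))
})

test_that("Fisher small-p sum matches the established two-sided test", {
  expect_equal(fisher_exact_small_p(matrix(c(1, 0, 0, 1), 2)), 1.0)
  expect_equal(fisher_exact_small_p(matrix(c(7, 3, 1, 10), 2)),
               fisher.test(matrix(c(7, 3, 1, 10), 2))$p.value,
               tolerance = 1e-10)
  expect_lt(abs(fisher_exact_small_p(matrix(c(7, 3, 1, 10), 2)) - 0.00752),
            5e-5)
  # proportional rows: independence, p = 1
  expect_equal(fisher_exact_small_p(matrix(c(4, 8, 3, 6), 2)), 1.0)
  # exhaustive agreement for all tables with N <= 16 (full N <= 40 sweep
  # runs in the acceptance suite)
  for (N in 0:16) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      m <- matrix(c(a, cc, b, N - a - b - cc), 2)
      expect_equal(fisher_exact_small_p(m), fisher.test(m)$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("depth regression recovers linear structure and filters", {
  d <- c(10, 40, 70, 100, 130)
  y <- 0.5 + 0.002 * d
  r <- depth_regression(y, d, transverse_distance = rep(10, 5))
  expect_equal(r$r_squared, 1.0)
  expect_equal(r$slope, 0.002, tolerance = 1e-12)
  # the transverse filter drops distant pairs
  r2 <- depth_regression(c(y, 5), c(d, 50),
                         transverse_distance = c(rep(10, 5), 100))
  expect_equal(r2$n, 5L)
  expect_error(depth_regression(y[1:2], d[1:2],
                                transverse_distance = rep(1, 2)),
               "fewer than 3")
})

test_that("rank-based group comparisons behave as published", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(group_compare(list(x, x), "unpaired")$p, 1)
  expect_equal(group_compare(list(x, x), "paired")$p, 1)
  # power: shift of 2 SD at n = 20
  set.seed(5)
  hits <- vapply(1:10, function(s) {
    a <- rnorm(20); b <- rnorm(20, 2)
    group_compare(list(a, b), "unpaired")$p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # Kruskal-Wallis + Tukey-Kramer pairwise on ranks
  set.seed(6)
  g <- list(rnorm(15), rnorm(15), rnorm(15, 3))
  kw <- group_compare(g, "kruskal")
  expect_lt(kw$p, 0.01)
  pw <- kw$pairwise
  expect_equal(nrow(pw), 3L)
  p13 <- pw$p_adj[pw$group_i == 1 & pw$group_j == 3]
  p12 <- pw$p_adj[pw$group_i == 1 & pw$group_j == 2]
  expect_lt(p13, 0.05)
  expect_gt(p12, 0.05)
  # 3-group null p is diffuse
  set.seed(7)
  ps <- vapply(1:30, function(s)
    group_compare(list(rnorm(10), rnorm(10), rnorm(10)), "kruskal")$p, 0)
  expect_gt(mean(ps), 0.3)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("motif flags are recomputable from stored Z-scores (audit)", {
  ses <- simulate_pair(world_inhibition(0.6), 600, seed = 500)
  cfg <- analysis_config(n_shuffles_ccg = 200L)
  call <- classify_session(ses, cfg, seed = 7)
  expect_true(call$flags$in_pc_inhibition)
  sup <- call$support$in_pc
  re <- classify_in_pc(sup$zccg, cfg$z_threshold)
  expect_identical(re$in_pc_inhibition, call$flags$in_pc_inhibition)
  expect_identical(re$z_post, sup$z_post)
  expect_true(sup$z_post < -cfg$z_threshold)
})
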
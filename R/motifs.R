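#' Classify IN -> PC interaction from a Z-scored correlogram
#'
#' At 10 ms bins: IN-PC inhibition is a Z-score below -threshold in the
#' 0-10 ms bin after the IN spike; IN-PC co-activation is a Z-score above
#' +threshold in the -10-0 ms bin preceding it.
#'
#' @param z a [zscore_ccg] result at 10 ms bins (IN triggers, PC simple
#'   spike targets).
#' @param threshold Z threshold (default 3).
#' @return list of flags with supporting Z values.
#' @export
classify_in_pc <- function(z, threshold = 3) {
  z_post <- z_at(z, 0)
  z_pre <- z_at(z, -z$ccg$bin_size)
  list(in_pc_inhibition = isTRUE(z_post < -threshold),
       in_pc_coactivation = isTRUE(z_pre > threshold),
       z_post = z_post, z_pre = z_pre,
       normalized_post = z$ccg$normalized[which(
         abs(z$ccg$lags - 0) < z$ccg$bin_size * 1e-6)])
}

#' Classify CF -> IN interaction from a complex-spike-triggered correlogram
#'
#' At 10 ms bins with complex spikes as triggers: CF-IN excitation if
#' either the 0-10 or the 10-20 ms bin exceeds +threshold (glutamate
#' spillover: slow rise, peak 10-20 ms); CF-IN inhibition if either the
#' 10-20 or the 20-30 ms bin falls below -threshold (delayed, disynaptic).
#' A combined call requires both, with the excitation onset earlier than
#' the inhibition onset; onsets come from [threshold_crossing_latency] on
#' `z_fine` (1 ms bins) when supplied, otherwise from the coarse bins.
#'
#' @param z a [zscore_ccg] at 10 ms bins.
#' @param z_fine optional [zscore_ccg] at 1 ms bins for onset latencies.
#' @param threshold Z threshold.
#' @return list of flags, supporting Z values and onset latencies (s).
#' @export
classify_cf_in <- function(z, z_fine = NULL, threshold = 3) {
  z0 <- z_at(z, 0); z10 <- z_at(z, 0.010); z20 <- z_at(z, 0.020)
  exc <- isTRUE(z0 > threshold) || isTRUE(z10 > threshold)
  inh <- isTRUE(z10 < -threshold) || isTRUE(z20 < -threshold)
  zl <- if (!is.null(z_fine)) z_fine else z
  lat_exc <- if (exc) threshold_crossing_latency(zl, +1, threshold) else NA_real_
  lat_inh <- if (inh) threshold_crossing_latency(zl, -1, threshold) else NA_real_
  combined <- exc && inh && is.finite(lat_exc) && is.finite(lat_inh) &&
    lat_exc < lat_inh
  list(cf_in_excitation = exc && !combined,
       cf_in_inhibition = inh && !combined,
       cf_in_combined = combined,
       z_bins = c(z0 = z0, z10 = z10, z20 = z20),
       latency_excitation = lat_exc, latency_inhibition = lat_inh)
}

#' Classify IN -> IN interaction
#'
#' At 5 ms bins over +/-10 ms lag: co-activation is any Z above +threshold;
#' inhibition is any Z below -threshold, with direction assigned so that
#' the presynaptic unit is the one whose spikes precede the deficit (a
#' deficit at positive lag in the A-triggered correlogram means A inhibits
#' B). If both directions are significant the call is bidirectional.
#' Gap-junction synchrony requires, on the 0.5 ms fine correlogram,
#' significant peaks at both the +1 ms and the -1 ms lag (bins within
#' +/-(0.5-1.5) ms).
#'
#' @param z_ab correlogram triggered on A, target B (5 ms bins,
#'   [zscore_ccg]).
#' @param z_ba correlogram triggered on B, target A.
#' @param z_fine optional fine (0.5 ms bin) [zscore_ccg], A-triggered.
#' @param threshold Z threshold.
#' @return list of flags, `direction` (`"A->B"`, `"B->A"`,
#'   `"bidirectional"`, or `NA`) and supporting Z values.
#' @export
classify_in_in <- function(z_ab, z_ba, z_fine = NULL, threshold = 3) {
  win <- function(z, lo, hi) {
    i <- z$ccg$lags >= lo - 1e-12 & z$ccg$lags < hi - 1e-12
    z$z[i]
  }
  lag_z_ab <- win(z_ab, -0.010, 0.010)
  lag_z_ba <- win(z_ba, -0.010, 0.010)
  coact <- any(lag_z_ab > threshold, na.rm = TRUE) ||
    any(lag_z_ba > threshold, na.rm = TRUE)
  inh_ab <- any(win(z_ab, 0, 0.010) < -threshold, na.rm = TRUE) ||
    any(win(z_ba, -0.010, 0) < -threshold, na.rm = TRUE)
  inh_ba <- any(win(z_ba, 0, 0.010) < -threshold, na.rm = TRUE) ||
    any(win(z_ab, -0.010, 0) < -threshold, na.rm = TRUE)
  direction <- if (inh_ab && inh_ba) "bidirectional" else
    if (inh_ab) "A->B" else if (inh_ba) "B->A" else NA_character_
  gap <- FALSE
  if (!is.null(z_fine)) {
    zpos <- win(z_fine, 0.0005, 0.0015)
    zneg <- win(z_fine, -0.0015, -0.0005)
    gap <- any(zpos > threshold, na.rm = TRUE) &&
      any(zneg > threshold, na.rm = TRUE)
  }
  list(in_in_inhibition = inh_ab || inh_ba,
       direction = direction,
       in_in_coactivation = coact,
       gap_junction_synchrony = gap,
       z_ab = lag_z_ab, z_ba = lag_z_ba)
}

#' Pairwise soma geometry
#'
#' Plane-projected Euclidean distances between two somata in the rotated
#' frame (PC dendrites vertical): transverse-plane distance from the
#' transverse and depth offsets, sagittal-plane distance from the sagittal
#' and depth offsets, and the molecular-layer depth difference
#' (`z_b - z_a`, so with the PC as unit `a` a positive value places the IN
#' above the PC soma... by convention the result is reported as
#' `|z_a - z_b|` with the PC soma as the 0 reference). Each unit also gets
#' its normalized molecular-layer position (0 at the PC layer, 1 at the
#' dura).
#'
#' @param geom_a,geom_b [soma_geometry] objects (`geom_a` conventionally
#'   the PC of an IN-PC pair).
#' @return an object of class `pair_geometry`.
#' @export
compute_pair_geometry <- function(geom_a, geom_b) {
  dx <- geom_b$x_transverse - geom_a$x_transverse
  dy <- geom_b$y_sagittal - geom_a$y_sagittal
  dz <- geom_b$z_depth - geom_a$z_depth
  norm_pos <- function(g)
    (g$pc_layer_depth - g$z_depth) / (g$pc_layer_depth - g$dura_depth)
  structure(list(transverse_distance = sqrt(dx^2 + dz^2),
                 sagittal_distance = sqrt(dy^2 + dz^2),
                 ml_depth_distance = abs(dz),
                 normalized_ml_position_a = norm_pos(geom_a),
                 normalized_ml_position_b = norm_pos(geom_b)),
            class = "pair_geometry")
}

#' Motif prevalence by distance bin with bootstrap SD
#'
#' Fraction of flagged pairs per distance bin, with the SD of that fraction
#' across `n_boot` resamples of the pairs (with replacement). Bins with no
#' pairs are reported as `NA`.
#'
#' @param flags logical vector (one per pair).
#' @param distances numeric vector (same length).
#' @param breaks bin edges (um), default 25 um bins covering the data.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional seed.
#' @return data.frame with `bin_lo`, `bin_hi`, `n`, `fraction`, `boot_sd`.
#' @export
prevalence_by_distance <- function(flags, distances, breaks = NULL,
                                   n_boot = 1000L, seed = NULL) {
  stopifnot(length(flags) == length(distances))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(breaks))
    breaks <- seq(0, 25 * ceiling(max(distances) / 25 + 1e-9), by = 25)
  bin <- cut(distances, breaks, right = FALSE, labels = FALSE)
  n <- length(flags)
  boot_frac <- function(idx_bin) {
    vapply(seq_len(n_boot), function(i) {
      s <- sample.int(n, n, replace = TRUE)
      b <- bin[s] == idx_bin
      if (!any(b, na.rm = TRUE)) NA_real_ else
        mean(flags[s][which(b)], na.rm = TRUE)
    }, 0)
  }
  out <- lapply(seq_len(length(breaks) - 1L), function(k) {
    in_bin <- which(bin == k)
    if (!length(in_bin))
      return(data.frame(bin_lo = breaks[k], bin_hi = breaks[k + 1],
                        n = 0L, fraction = NA_real_, boot_sd = NA_real_))
    bf <- boot_frac(k)
    data.frame(bin_lo = breaks[k], bin_hi = breaks[k + 1],
               n = length(in_bin), fraction = mean(flags[in_bin]),
               boot_sd = sd(bf, na.rm = TRUE))
  })
  do.call(rbind, out)
}

#' Two-sided Fisher's exact test by summing small p values
#'
#' Exact hypergeometric enumeration over all 2x2 tables with the observed
#' margins; the two-sided p value is the sum of the probabilities of all
#' tables at most as probable as the observed one (relative tie tolerance
#' 1e-7).
#'
#' @param table a 2x2 matrix of nonnegative integer counts.
#' @return the two-sided p value.
#' @export
fisher_exact_small_p <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)),
            all(table >= 0), all(table == round(table)))
  m <- sum(table[1, ])           # row-1 total
  n <- sum(table[2, ])           # row-2 total
  k <- sum(table[, 1])           # column-1 total
  a_obs <- table[1, 1]
  lo <- max(0L, k - n)
  hi <- min(k, m)
  a <- lo:hi
  pr <- dhyper(a, m, n, k)
  p_obs <- dhyper(a_obs, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Depth regression of inhibition strength
#'
#' Ordinary least-squares regression of the per-pair baseline-normalized
#' 0-10 ms PC spike count on the molecular-layer depth distance, restricted
#' to pairs within `max_transverse` um transverse intersomatic distance.
#'
#' @param normalized_count numeric vector (one per pair).
#' @param ml_depth_distance numeric vector (um).
#' @param transverse_distance numeric vector (um) used for the filter.
#' @param max_transverse filter cutoff (um), default 30.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
depth_regression <- function(normalized_count, ml_depth_distance,
                             transverse_distance = NULL,
                             max_transverse = 30) {
  keep <- if (is.null(transverse_distance))
    rep(TRUE, length(normalized_count))
  else transverse_distance <= max_transverse
  keep <- keep & complete.cases(normalized_count, ml_depth_distance)
  if (sum(keep) < 3L) stop("fewer than 3 pairs after the transverse filter")
  ft <- lm(normalized_count[keep] ~ ml_depth_distance[keep])
  sm <- summary(ft)
  list(slope = unname(coef(ft)[2]), intercept = unname(coef(ft)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]), n = sum(keep))
}

#' Rank-based group comparisons
#'
#' Nonparametric comparisons matching the published statistics: Wilcoxon
#' signed-rank for paired designs, Wilcoxon rank-sum for unpaired two-group
#' designs, and Kruskal-Wallis followed by Tukey-Kramer comparisons on rank
#' means for three or more groups.
#'
#' @param samples list of numeric vectors (named groups) or, for
#'   `design = "paired"`, a list of exactly two equal-length vectors.
#' @param design `"paired"`, `"unpaired"`, or `"kruskal"`.
#' @return list with `statistic`, `p`, and for `"kruskal"` a `pairwise`
#'   data.frame of Tukey-Kramer adjusted p values on rank means.
#' @export
group_compare <- function(samples, design = c("unpaired", "paired",
                                              "kruskal")) {
  design <- match.arg(design)
  if (any(vapply(samples, length, 0L) < 3L))
    stop("each group needs at least 3 observations")
  if (design == "paired") {
    stopifnot(length(samples) == 2L,
              length(samples[[1]]) == length(samples[[2]]))
    if (all(samples[[1]] == samples[[2]]))
      return(list(statistic = 0, p = 1))  # no nonzero differences to rank
    w <- wilcox.test(samples[[1]], samples[[2]], paired = TRUE,
                     exact = FALSE)
    return(list(statistic = unname(w$statistic), p = w$p.value))
  }
  if (design == "unpaired") {
    stopifnot(length(samples) == 2L)
    w <- wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
    return(list(statistic = unname(w$statistic), p = w$p.value))
  }
  kw <- kruskal.test(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), vapply(samples, length, 0L)))
  r <- rank(x)
  N <- length(x)
  mr <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  # tie correction for the rank variance
  ties <- table(x)
  tiecor <- 1 - sum(ties^3 - ties) / (N^3 - N)
  s2 <- N * (N + 1) / 12 * tiecor
  cmb <- utils::combn(seq_along(samples), 2)
  pw <- apply(cmb, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(s2 * (1 / ni[i] + 1 / ni[j]))
    q <- abs(mr[i] - mr[j]) / se * sqrt(2)
    p <- 1 - ptukey(q, nmeans = length(samples), df = Inf)
    c(group_i = i, group_j = j, diff_rank = unname(mr[i] - mr[j]),
      p_adj = unname(p))
  })
  list(statistic = unname(kw$statistic), p = kw$p.value,
       pairwise = as.data.frame(t(pw)))
}
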
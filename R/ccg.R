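#' Select trigger spikes for a cross-correlogram
#'
#' Trigger selection modes used throughout the analyses:
#' \describe{
#'   \item{ALL}{every spike of the trigger train.}
#'   \item{EXCLUDE_POST_CS}{drop trigger spikes with a complex spike in the
#'     preceding 25 ms (the published rule for IN-triggered PC simple-spike
#'     correlograms, which removes complex-spike-driven coupling).}
#'   \item{ISI_RANGE}{keep spikes whose preceding inter-spike interval lies
#'     in `[params$lo, params$hi)` seconds; the first spike has no
#'     preceding ISI and is dropped.}
#'   \item{SENSORY_FAST}{keep spikes within `params$window` (default 20 ms)
#'     after a stimulus onset in `params$onsets`.}
#'   \item{TRIGGERED}{return electrically triggered spike times
#'     (`params$triggered`).}
#' }
#'
#' @param trigger a [spike_train].
#' @param complex the complex-spike [spike_train] (required for
#'   `EXCLUDE_POST_CS`).
#' @param mode selection mode.
#' @param params list of mode parameters (see Details).
#' @return numeric vector of selected trigger spike times.
#' @export
select_trigger_spikes <- function(trigger, complex = NULL,
                                  mode = c("ALL", "EXCLUDE_POST_CS",
                                           "ISI_RANGE", "SENSORY_FAST",
                                           "TRIGGERED"),
                                  params = list()) {
  mode <- match.arg(mode)
  tt <- trigger$times
  switch(mode,
    ALL = tt,
    EXCLUDE_POST_CS = {
      if (is.null(complex))
        stop("EXCLUDE_POST_CS requires the complex-spike train")
      win <- params$window %||% 0.025
      cs <- complex$times
      if (!length(cs) || !length(tt)) return(tt)
      idx <- findInterval(tt, cs)  # last CS at or before each trigger
      keep <- idx == 0L | (tt - cs[pmax(idx, 1L)]) > win
      tt[keep]
    },
    ISI_RANGE = {
      lo <- params$lo %||% 0
      hi <- params$hi %||% Inf
      if (length(tt) < 2L) return(numeric(0))
      isi <- diff(tt)
      tt[-1L][isi >= lo & isi < hi]
    },
    SENSORY_FAST = {
      onsets <- params$onsets
      if (is.null(onsets)) stop("SENSORY_FAST requires params$onsets")
      win <- params$window %||% 0.020
      if (!length(tt) || !length(onsets)) return(numeric(0))
      idx <- findInterval(tt, onsets)
      keep <- idx >= 1L & (tt - onsets[pmax(idx, 1L)]) < win &
        (tt - onsets[pmax(idx, 1L)]) >= 0
      tt[keep]
    },
    TRIGGERED = {
      if (is.null(params$triggered))
        stop("TRIGGERED requires params$triggered")
      sort(as.numeric(params$triggered))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute a baseline-normalized cross-correlogram
#'
#' The correlogram is the mean target-spike count per lag bin per trigger
#' spike over a +/-`window` span, with half-open bins `[l, l + bin)` so that
#' lag 0 belongs to the first post-trigger bin. Triggers whose window is
#' truncated by the recording bounds are dropped (and counted in
#' `n_edge_dropped`). Counts are normalized by the mean count per bin over
#' the baseline window (for IN-triggered correlograms the published baseline
#' is -100 to -80 ms; for complex-spike-triggered ones -100 to 0 ms).
#'
#' @param trigger_times numeric vector of trigger spike times (seconds).
#' @param target a [spike_train] (or a numeric vector of spike times plus
#'   `duration`).
#' @param bin_size bin width (s).
#' @param window half-width of the lag span (s).
#' @param baseline_window length-2 numeric, lag span of the baseline (s).
#' @param duration recording duration; taken from `target` if a
#'   [spike_train].
#' @return an object of class `ccg` with fields `lags` (bin lower edges),
#'   `counts` (mean count/bin/trigger), `normalized`, `baseline_rate`,
#'   `n_triggers`, `n_edge_dropped`, `baseline_flagged`.
#' @export
compute_ccg <- function(trigger_times, target, bin_size = 0.010,
                        window = 0.1, baseline_window = c(-0.1, -0.08),
                        duration = NULL) {
  if (inherits(target, "spike_train")) {
    duration <- duration %||% target$duration
    target_times <- target$times
    target_id <- target$unit_id
  } else {
    target_times <- as.numeric(target)
    target_id <- NA_character_
    if (is.null(duration)) stop("duration required for bare target times")
  }
  if (!length(trigger_times)) stop("at least one trigger spike required")
  nbins <- round(2 * window / bin_size)
  if (abs(nbins - 2 * window / bin_size) > 1e-9)
    stop("window must be an integer multiple of bin_size")
  keep <- trigger_times >= window & trigger_times <= duration - window
  trig <- trigger_times[keep]
  lags <- seq(-window, window - bin_size, by = bin_size)
  bl_bins <- which(lags >= baseline_window[1] - 1e-12 &
                     lags < baseline_window[2] - 1e-12)
  if (!length(bl_bins)) stop("baseline window contains no bins")
  if (!length(trig)) {
    counts <- rep(0, nbins)
    n_triggers <- 0L
  } else {
    counts <- ccg_counts_cpp(trig, target_times, bin_size, window) /
      length(trig)
    n_triggers <- length(trig)
  }
  baseline_rate <- mean(counts[bl_bins])
  flagged <- baseline_rate <= 0 || n_triggers == 0L
  structure(list(lags = lags, counts = counts,
                 normalized = if (flagged) rep(NA_real_, nbins) else
                   counts / baseline_rate,
                 bin_size = bin_size, window = window,
                 baseline_window = baseline_window,
                 baseline_bins = bl_bins,
                 baseline_rate = baseline_rate,
                 n_triggers = n_triggers,
                 n_edge_dropped = sum(!keep),
                 baseline_flagged = flagged,
                 target_id = target_id, duration = duration),
            class = "ccg")
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf(
    "<ccg> %d triggers (%d edge-dropped), %.1f ms bins, baseline %.4g/bin%s\n",
    x$n_triggers, x$n_edge_dropped, x$bin_size * 1e3, x$baseline_rate,
    if (x$baseline_flagged) " [FLAGGED: baseline undefined]" else ""))
  invisible(x)
}

#' Block-shuffle a spike train
#'
#' Cuts the recording into consecutive segments of `block` seconds (the
#' final partial segment carries its own length, or is dropped when
#' `drop_partial = TRUE`), permutes the segment order uniformly at random,
#' and reassembles. Within-segment relative spike times are preserved, so
#' slow rate structure survives while short-lag coupling to any other train
#' is destroyed. Uses R's RNG: call `set.seed()` for reproducibility.
#'
#' @param times numeric vector of spike times.
#' @param duration recording duration (s).
#' @param block segment length (s), default 5.
#' @param drop_partial drop the final partial segment (and its spikes).
#' @return shuffled, sorted spike times.
#' @export
block_shuffle <- function(times, duration, block = 5, drop_partial = FALSE) {
  if (duration < 2 * block)
    stop("shuffle impossible: duration shorter than two blocks")
  if (drop_partial) {
    nfull <- floor(duration / block)
    duration <- nfull * block
    times <- times[times < duration]
  }
  block_shuffle_cpp(as.numeric(times), duration, block)
}

#' Build a block-shuffle surrogate null for a cross-correlogram
#'
#' Computes `n_shuffles` correlograms from block-shuffled trigger trains and
#' summarizes them per bin: the mean of the baseline-normalized shuffled
#' correlograms (each normalized to its own baseline) and the standard
#' deviation of the raw (count-per-trigger) shuffled correlograms. The
#' published convention divides that raw SD by the original correlogram's
#' baseline rate when forming Z-scores (see [zscore_ccg]).
#'
#' @param trigger_times trigger spike times (seconds).
#' @param target target [spike_train].
#' @param n_shuffles number of surrogates (default 500).
#' @param bin_size,window,baseline_window as in [compute_ccg].
#' @param block shuffle segment length (s).
#' @param seed optional integer seed (applied via `set.seed`).
#' @param duration recording duration; from `target` if a [spike_train].
#' @return an object of class `shuffle_null`.
#' @export
build_shuffle_null <- function(trigger_times, target, n_shuffles = 500L,
                               bin_size = 0.010, window = 0.1,
                               baseline_window = c(-0.1, -0.08),
                               block = 5, seed = NULL, duration = NULL) {
  if (inherits(target, "spike_train")) {
    duration <- duration %||% target$duration
    target_times <- target$times
  } else {
    target_times <- as.numeric(target)
    if (is.null(duration)) stop("duration required for bare target times")
  }
  if (duration < 2 * block)
    stop("shuffle impossible: duration shorter than two blocks")
  if (!is.null(seed)) set.seed(seed)
  nbins <- round(2 * window / bin_size)
  lags <- seq(-window, window - bin_size, by = bin_size)
  bl_bins <- which(lags >= baseline_window[1] - 1e-12 &
                     lags < baseline_window[2] - 1e-12)
  res <- shuffle_null_cpp(as.numeric(trigger_times), target_times, duration,
                          block, as.integer(n_shuffles), bin_size, window,
                          as.integer(bl_bins - 1L))
  structure(list(lags = lags, bin_size = bin_size, window = window,
                 baseline_window = baseline_window,
                 n_shuffles = as.integer(n_shuffles),
                 n_used = res$n_used,
                 block_length = block,
                 mean_norm = res$mean_norm,
                 mean_raw = res$mean_raw,
                 sd_raw = res$sd_raw,
                 unusable = n_shuffles < 2L || any(res$sd_raw == 0),
                 seed = seed),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null> %d shuffles, block %.1f s, %.1f ms bins%s\n",
              x$n_shuffles, x$block_length, x$bin_size * 1e3,
              if (x$unusable) " [FLAGGED: unusable SD]" else ""))
  invisible(x)
}

#' Z-score a cross-correlogram against its shuffle null
#'
#' Per-bin standard score
#' `z = (normalized_original - shuffle_mean_normalized) /
#'      (shuffle_SD_raw / original_baseline_rate)`,
#' i.e. the original and shuffled correlograms are each normalized to their
#' respective baseline rates while the shuffle SD is normalized to the
#' original's baseline rate. Bins where the shuffle SD is 0 get `NA`
#' (excluded from classification, reported in `undefined_bins`).
#'
#' @param ccg a [compute_ccg] result.
#' @param null a [build_shuffle_null] result on the same binning.
#' @return an object of class `zccg` carrying the input ccg, the null and
#'   the per-bin `z`.
#' @export
zscore_ccg <- function(ccg, null) {
  if (!isTRUE(all.equal(ccg$lags, null$lags)) ||
      ccg$bin_size != null$bin_size)
    stop("ccg and null have mismatched binning")
  if (ccg$baseline_flagged)
    stop("baseline rate is zero/undefined; Z-scores not assessable")
  sd_norm <- null$sd_raw / ccg$baseline_rate
  z <- (ccg$normalized - null$mean_norm) / sd_norm
  z[sd_norm == 0] <- NA_real_
  structure(list(ccg = ccg, null = null, z = z,
                 undefined_bins = which(sd_norm == 0)),
            class = "zccg")
}

#' @export
print.zccg <- function(x, ...) {
  print(x$ccg)
  zr <- range(x$z, na.rm = TRUE)
  cat(sprintf("  z range [%.2f, %.2f]\n", zr[1], zr[2]))
  invisible(x)
}

#' Z value in the bin whose lag span starts at `from` seconds
#' @param z a [zscore_ccg] result.
#' @param from lower lag edge of the bin (s).
#' @return the Z-score of that bin.
#' @export
z_at <- function(z, from) {
  i <- which(abs(z$ccg$lags - from) < z$ccg$bin_size * 1e-6)
  if (!length(i)) stop("no bin with lower edge at ", from)
  z$z[i]
}

#' Latency of the first post-trigger threshold crossing
#'
#' Scans the Z-scores over lags 0 to +`window` (intended for 1 ms bins) and
#' returns the lower edge of the first bin where z crosses the signed
#' threshold (`sign = +1` for excitation, `-1` for inhibition), or `NA` if
#' no bin crosses.
#'
#' @param z a [zscore_ccg] result.
#' @param sign +1 or -1.
#' @param threshold threshold magnitude (default 3).
#' @return latency in seconds, or `NA_real_`.
#' @export
threshold_crossing_latency <- function(z, sign = -1, threshold = 3) {
  post <- which(z$ccg$lags >= -1e-12)
  zz <- z$z[post]
  hit <- if (sign > 0) which(zz > threshold) else which(zz < -threshold)
  if (!length(hit)) return(NA_real_)
  z$ccg$lags[post[hit[1]]]
}

#' Fraction of synchronized spikes between two trains
#'
#' The fraction of spikes of one train with a spike of the other within
#' `tol` seconds (default +/-5 ms), computed in both directions; the pair
#' summary is the mean of the two directions.
#'
#' @param a,b [spike_train] objects (both nonempty).
#' @param tol tolerance in seconds.
#' @return list with `frac_a`, `frac_b`, `pair` (their mean).
#' @export
synchrony_fraction <- function(a, b, tol = 0.005) {
  if (!length(a$times) || !length(b$times))
    stop("both trains must be nonempty")
  near <- function(x, y) {
    idx <- findInterval(x, y)
    d_lo <- ifelse(idx >= 1L, x - y[pmax(idx, 1L)], Inf)
    d_hi <- ifelse(idx < length(y), y[pmin(idx + 1L, length(y))] - x, Inf)
    mean(pmin(d_lo, d_hi) <= tol)
  }
  fa <- near(a$times, b$times)
  fb <- near(b$times, a$times)
  list(frac_a = fa, frac_b = fb, pair = (fa + fb) / 2)
}
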
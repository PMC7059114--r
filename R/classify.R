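#' Z-scored cross-correlogram for a trigger/target pair in a session
#'
#' Convenience wrapper chaining [select_trigger_spikes], [compute_ccg],
#' [build_shuffle_null] and [zscore_ccg] with the published conventions:
#' IN-triggered correlograms exclude triggers within 25 ms after a complex
#' spike and use the -100 to -80 ms baseline; complex-spike-triggered
#' correlograms use the -100 to 0 ms baseline.
#'
#' @param session a [session].
#' @param trigger_id,target_id unit ids.
#' @param bin_size bin width (s).
#' @param config an [analysis_config].
#' @param seed optional seed for the shuffle null.
#' @return a [zscore_ccg] result, or `NULL` when the baseline is flagged
#'   (not assessable).
#' @export
session_zccg <- function(session, trigger_id, target_id,
                         bin_size = 0.010, config = analysis_config(),
                         seed = NULL) {
  trig_tr <- session$trains[[trigger_id]]
  targ_tr <- session$trains[[target_id]]
  if (is.null(trig_tr) || is.null(targ_tr)) stop("unknown unit id")
  cs_tr <- session_train(session, "PC_COMPLEX", required = FALSE)
  if (trig_tr$role == "IN" && targ_tr$role == "PC_SIMPLE" &&
      !is.null(cs_tr)) {
    trig <- select_trigger_spikes(trig_tr, cs_tr, "EXCLUDE_POST_CS",
                                  list(window = config$exclude_post_cs))
  } else trig <- trig_tr$times
  trig <- spontaneous_times(
    spike_train(trig, trig_tr$duration, trig_tr$role, trig_tr$unit_id,
                refractory = 0),
    session$stimulus_onsets, config$spontaneous_exclusion)
  baseline <- if (trig_tr$role == "PC_COMPLEX") c(-0.1, 0) else
    c(-0.1, -0.08)
  if (!length(trig)) return(NULL)
  cc <- compute_ccg(trig, targ_tr, bin_size = bin_size,
                    window = config$ccg_window, baseline_window = baseline)
  if (cc$baseline_flagged) return(NULL)
  null <- build_shuffle_null(trig, targ_tr, n_shuffles = config$n_shuffles_ccg,
                             bin_size = bin_size, window = config$ccg_window,
                             baseline_window = baseline,
                             block = config$shuffle_block, seed = seed)
  zscore_ccg(cc, null)
}

#' Classify all assessable motifs of a session
#'
#' Runs the motif classifiers appropriate to the units present: IN-PC
#' inhibition/co-activation (10 ms bins), CF-IN excitation/inhibition/
#' combined (10 ms bins, 5 ms bins for onset latencies), IN-IN
#' inhibition/co-activation (5 ms bins, both directions) and gap-junction
#' synchrony (0.5 ms bins). Inclusion floors from
#' [apply_inclusion_criteria] gate the corresponding analyses. Every flag
#' is backed by the stored Z-scores, so calls can be audited by
#' recomputation.
#'
#' @param session a [session].
#' @param config an [analysis_config].
#' @param seed optional seed for the shuffle nulls (default
#'   `config$seed`).
#' @return an object of class `motif_call`: flags, supporting statistics,
#'   and the underlying `zccg` objects.
#' @export
classify_session <- function(session, config = analysis_config(),
                             seed = config$seed) {
  ins <- Filter(function(tr) tr$role == "IN", session$trains)
  pcs <- session_train(session, "PC_SIMPLE", required = FALSE)
  cs <- session_train(session, "PC_COMPLEX", required = FALSE)
  incl <- apply_inclusion_criteria(session, config)
  flags <- list(in_pc_inhibition = NA, in_pc_coactivation = NA,
                cf_in_excitation = NA, cf_in_inhibition = NA,
                cf_in_combined = NA, in_in_inhibition = NA,
                in_in_coactivation = NA, gap_junction_synchrony = NA)
  support <- list()
  if (length(ins) >= 1L && !is.null(pcs) &&
      incl$eligible[incl$analysis == "spontaneous_ccg"]) {
    z <- session_zccg(session, names(ins)[1], pcs$unit_id,
                      config$bin_coarse, config, seed = seed)
    if (!is.null(z)) {
      cl <- classify_in_pc(z, config$z_threshold)
      flags$in_pc_inhibition <- cl$in_pc_inhibition
      flags$in_pc_coactivation <- cl$in_pc_coactivation
      support$in_pc <- c(cl, list(zccg = z))
    }
  }
  if (length(ins) >= 1L && !is.null(cs) &&
      incl$eligible[incl$analysis == "cf_in_ccg"]) {
    z <- session_zccg(session, cs$unit_id, names(ins)[1],
                      config$bin_coarse, config, seed = seed)
    zf <- session_zccg(session, cs$unit_id, names(ins)[1],
                       config$bin_in_in, config, seed = seed)
    if (!is.null(z)) {
      cl <- classify_cf_in(z, z_fine = zf, threshold = config$z_threshold)
      flags$cf_in_excitation <- cl$cf_in_excitation
      flags$cf_in_inhibition <- cl$cf_in_inhibition
      flags$cf_in_combined <- cl$cf_in_combined
      support$cf_in <- c(cl, list(zccg = z, zccg_latency = zf))
    }
  }
  if (length(ins) >= 2L) {
    a <- names(ins)[1]; b <- names(ins)[2]
    z_ab <- session_zccg(session, a, b, config$bin_in_in, config, seed = seed)
    z_ba <- session_zccg(session, b, a, config$bin_in_in, config, seed = seed)
    z_fine <- session_zccg(session, a, b, config$bin_fine, config, seed = seed)
    if (!is.null(z_ab) && !is.null(z_ba)) {
      cl <- classify_in_in(z_ab, z_ba, z_fine = NULL,
                           threshold = config$z_threshold)
      cl$gap_junction_synchrony <- if (!is.null(z_fine))
        gap_junction_flag(z_fine, config$z_threshold) else FALSE
      flags$in_in_inhibition <- cl$in_in_inhibition
      flags$in_in_coactivation <- cl$in_in_coactivation
      flags$gap_junction_synchrony <- cl$gap_junction_synchrony
      support$in_in <- c(cl, list(zccg_ab = z_ab, zccg_ba = z_ba,
                                  zccg_fine = z_fine))
    }
  }
  structure(list(flags = flags, support = support, inclusion = incl),
            class = "motif_call")
}

#' Gap-junction twin-peak flag on a fine correlogram
#'
#' Symmetric peaks at +/-1 ms lag on the 0.5 ms-bin correlogram: a bin
#' with Z above threshold within +0.5 to +1.5 ms AND within -1.5 to
#' -0.5 ms, each forming a genuine local peak (normalized count at least
#' 1.5 times the mean normalized count at flanking lags 2-6 ms). The
#' prominence requirement distinguishes electrical-coupling coincidences
#' from broad common-input co-modulation, which elevates all fine bins
#' about equally.
#'
#' @param z_fine a [zscore_ccg] at 0.5 ms bins.
#' @param threshold Z threshold.
#' @return logical flag.
#' @export
gap_junction_flag <- function(z_fine, threshold = 3) {
  lag <- z_fine$ccg$lags
  norm <- z_fine$ccg$normalized
  z <- z_fine$z
  flank <- abs(lag + z_fine$ccg$bin_size / 2) >= 0.002 &
    abs(lag + z_fine$ccg$bin_size / 2) <= 0.006
  flank_level <- mean(norm[flank], na.rm = TRUE)
  peak_side <- function(lo, hi) {
    i <- lag >= lo - 1e-12 & lag < hi - 1e-12
    any(z[i] > threshold & norm[i] > 1.5 * flank_level, na.rm = TRUE)
  }
  peak_side(0.0005, 0.0015) && peak_side(-0.0015, -0.0005)
}

#' @export
print.motif_call <- function(x, ...) {
  on <- names(x$flags)[vapply(x$flags, isTRUE, TRUE)]
  cat("<motif_call>", if (length(on)) paste(on, collapse = ", ") else
    "no significant motif", "\n")
  invisible(x)
}

#' Predicted motif class of a session (for ground-truth scoring)
#'
#' Maps a [classify_session] result to a single class label, in priority
#' order gap-junction synchrony, IN-IN inhibition, CF-IN combined/
#' excitation/inhibition, IN-PC inhibition, otherwise `"NONE"`. Used to
#' build confusion matrices against a simulated population's truth table.
#'
#' @param call a `motif_call`.
#' @return a class label string.
#' @export
predicted_class <- function(call) {
  f <- call$flags
  if (isTRUE(f$gap_junction_synchrony)) return("GAP_JUNCTION")
  if (isTRUE(f$in_in_inhibition)) return("IN_IN_INHIBITION")
  if (isTRUE(f$cf_in_combined)) return("CF_IN_COMBINED")
  if (isTRUE(f$cf_in_excitation)) return("CF_IN_EXCITATION")
  if (isTRUE(f$cf_in_inhibition)) return("CF_IN_INHIBITION")
  if (isTRUE(f$in_pc_inhibition)) return("IN_PC_INHIBITION")
  "NONE"
}
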
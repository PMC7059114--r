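#' Construct a spike train
#'
#' A spike train is the fundamental unit of data: the sorted spike times of
#' one recorded unit together with its functional role and the recording
#' duration. Roles follow the cerebellar paired-recording setting: molecular
#' layer interneuron (`"IN"`), Purkinje cell simple spikes (`"PC_SIMPLE"`)
#' and Purkinje cell complex spikes (`"PC_COMPLEX"`, the climbing-fiber
#' readout).
#'
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing, all within `[0, duration]`.
#' @param duration recording duration in seconds.
#' @param role one of `"IN"`, `"PC_SIMPLE"`, `"PC_COMPLEX"`.
#' @param unit_id character scalar identifying the unit.
#' @param refractory absolute refractory floor in seconds used for
#'   validation (default 0.5 ms). Set to 0 to disable the check.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, duration, role, unit_id,
                        refractory = 5e-4) {
  role <- match.arg(role, .roles)
  times <- as.numeric(times)
  if (length(times) && is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be a positive scalar (seconds)")
  if (length(times) > 1L && refractory > 0 &&
      min(diff(times)) < refractory - 1e-12)
    stop(sprintf("inter-spike interval below refractory floor (%.3g s)",
                 refractory))
  structure(list(times = times, duration = as.numeric(duration),
                 role = role, unit_id = as.character(unit_id)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s [%s]: %d spikes over %.1f s (%.2f Hz)\n",
              x$unit_id, x$role, length(x$times), x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Soma geometry of a recorded unit
#'
#' Coordinates are measured in the rotated reference frame in which Purkinje
#' cell dendrites run vertically: `x_transverse` (mediolateral),
#' `y_sagittal` (rostrocaudal) and `z_depth` (from the pial surface,
#' positive down), all in micrometers. `pc_layer_depth` and `dura_depth`
#' bracket the molecular layer; the normalized molecular-layer position of a
#' soma is 0 at the PC layer and 1 at the dura.
#'
#' @param x_transverse,y_sagittal,z_depth soma coordinates (um).
#' @param pc_layer_depth,dura_depth depths of the Purkinje cell layer and of
#'   the dura mater (um); the dura is the shallower of the two.
#' @return an object of class `soma_geometry`.
#' @export
soma_geometry <- function(x_transverse, y_sagittal, z_depth,
                          pc_layer_depth, dura_depth) {
  if (dura_depth >= pc_layer_depth)
    stop("dura_depth must be shallower (smaller) than pc_layer_depth")
  structure(list(x_transverse = x_transverse, y_sagittal = y_sagittal,
                 z_depth = z_depth, pc_layer_depth = pc_layer_depth,
                 dura_depth = dura_depth),
            class = "soma_geometry")
}

#' Construct a recording session
#'
#' A session bundles the simultaneously recorded spike trains of one paired
#' recording with optional soma geometry, sensory stimulus onsets (airpuff),
#' and electrically triggered IN spike times.
#'
#' @param trains list of [spike_train] objects with unique `unit_id`s.
#' @param geometry optional named list of [soma_geometry], keyed by unit id.
#' @param stimulus_onsets optional sorted numeric vector of stimulus onset
#'   times (seconds).
#' @param stimulus_duration stimulus duration in seconds (default 0.060, a
#'   60 ms airpuff).
#' @param triggered_spike_times optional numeric vector of electrically
#'   triggered IN spike times (seconds).
#' @param sampling_rate optional sampling rate in Hz for raw traces.
#' @return an object of class `session`.
#' @export
session <- function(trains, geometry = NULL, stimulus_onsets = NULL,
                    stimulus_duration = 0.060,
                    triggered_spike_times = NULL, sampling_rate = NULL) {
  if (!length(trains) || !all(vapply(trains, inherits, TRUE, "spike_train")))
    stop("trains must be a non-empty list of spike_train objects")
  ids <- vapply(trains, `[[`, "", "unit_id")
  if (anyDuplicated(ids)) stop("duplicate unit_id in session: ",
                               ids[duplicated(ids)][1])
  names(trains) <- ids
  dur <- max(vapply(trains, `[[`, 0, "duration"))
  if (!is.null(stimulus_onsets)) {
    stimulus_onsets <- as.numeric(stimulus_onsets)
    if (is.unsorted(stimulus_onsets)) stop("stimulus onsets must be sorted")
  }
  if (!is.null(triggered_spike_times)) {
    triggered_spike_times <- sort(as.numeric(triggered_spike_times))
    if (length(triggered_spike_times) &&
        (min(triggered_spike_times) < 0 || max(triggered_spike_times) > dur))
      stop("triggered spike times must lie within [0, duration]")
  }
  if (!is.null(geometry)) {
    if (!all(names(geometry) %in% ids))
      stop("geometry refers to unknown unit ids")
  }
  structure(list(trains = trains, geometry = geometry,
                 stimulus_onsets = stimulus_onsets,
                 stimulus_duration = stimulus_duration,
                 triggered_spike_times = triggered_spike_times,
                 sampling_rate = sampling_rate),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %d units%s%s\n", length(x$trains),
              if (is.null(x$stimulus_onsets)) "" else
                sprintf(", %d stimuli", length(x$stimulus_onsets)),
              if (is.null(x$triggered_spike_times)) "" else
                sprintf(", %d triggered spikes",
                        length(x$triggered_spike_times))))
  for (tr in x$trains) print(tr)
  invisible(x)
}

#' Find the first train of a given role in a session
#' @param session a [session].
#' @param role a role string.
#' @param required error (rather than return `NULL`) when absent.
#' @return a [spike_train] or `NULL`.
#' @export
session_train <- function(session, role, required = TRUE) {
  for (tr in session$trains) if (tr$role == role) return(tr)
  if (required) stop("session has no train with role ", role)
  NULL
}

#' Analysis configuration
#'
#' All tunable analysis parameters with their defaults. Defaults follow the
#' published analysis where it states them: a +/-100 ms correlogram window;
#' 10 ms significance bins (5 ms for IN-IN, 0.5 ms for the gap-junction
#' check, 1 ms for display/latency); 500 block-shuffle surrogates built by
#' randomly reordering 5 s segments of the recording; Z-score threshold 3;
#' 1000 shuffles for the triggered-spike ISI test; inclusion floors of 200
#' spontaneous IN spikes, 200 IN spikes near complex spikes, and 20 trials
#' with sensory-evoked IN spikes.
#'
#' @param ccg_window half-width of the correlogram window (s).
#' @param bin_coarse,bin_in_in,bin_fine,bin_display bin sizes (s).
#' @param n_shuffles_ccg number of block-shuffle surrogates.
#' @param shuffle_block shuffle segment length (s).
#' @param n_shuffles_isi number of shuffles for the ISI test.
#' @param z_threshold significance threshold on per-bin Z-scores.
#' @param min_spontaneous_in_spikes,min_cs_locked_in_spikes,min_evoked_trials
#'   inclusion floors.
#' @param exclude_post_cs window after a complex spike within which IN
#'   trigger spikes are excluded (s).
#' @param evoked_window window after stimulus onset defining fast evoked IN
#'   spikes (s).
#' @param cs_evoked_window window after stimulus onset within which complex
#'   spikes count as sensory-evoked (s).
#' @param spontaneous_exclusion span after each stimulus onset excluded from
#'   "spontaneous" activity (s).
#' @param refractory absolute refractory floor (s).
#' @param drop_partial_block drop the final partial shuffle segment instead
#'   of carrying it.
#' @param seed session-level RNG seed.
#' @return an object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(ccg_window = 0.1,
                            bin_coarse = 0.010, bin_in_in = 0.005,
                            bin_fine = 0.0005, bin_display = 0.001,
                            n_shuffles_ccg = 500L, shuffle_block = 5,
                            n_shuffles_isi = 1000L, z_threshold = 3,
                            min_spontaneous_in_spikes = 200L,
                            min_cs_locked_in_spikes = 200L,
                            min_evoked_trials = 20L,
                            exclude_post_cs = 0.025,
                            evoked_window = 0.020,
                            cs_evoked_window = 0.100,
                            spontaneous_exclusion = 0.300,
                            refractory = 5e-4,
                            drop_partial_block = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  for (b in c("bin_coarse", "bin_in_in", "bin_fine", "bin_display")) {
    r <- cfg$ccg_window / cfg[[b]]
    if (abs(r - round(r)) > 1e-9)
      stop("ccg_window must be an integer multiple of ", b)
  }
  stopifnot(cfg$z_threshold > 0, cfg$n_shuffles_ccg > 0,
            cfg$n_shuffles_isi > 0, cfg$shuffle_block > 0)
  structure(cfg, class = "analysis_config")
}

#' Spontaneous spike times of a train
#'
#' With no stimuli, all spikes are spontaneous. With stimuli, spikes falling
#' in `[onset, onset + exclusion)` around any onset are excluded (the
#' exclusion span defaults to the 300 ms analysis trace used for evoked
#' activity; the boundary is a package convention, documented in the methods
#' vignette).
#'
#' @param train a [spike_train].
#' @param stimulus_onsets numeric vector of onsets or `NULL`.
#' @param exclusion seconds excluded after each onset.
#' @return numeric vector of spontaneous spike times.
#' @export
spontaneous_times <- function(train, stimulus_onsets = NULL,
                              exclusion = 0.300) {
  tt <- train$times
  if (is.null(stimulus_onsets) || !length(stimulus_onsets) || !length(tt))
    return(tt)
  idx <- findInterval(tt, stimulus_onsets)
  evoked <- idx >= 1L & (tt - stimulus_onsets[pmax(idx, 1L)]) < exclusion
  tt[!evoked]
}
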
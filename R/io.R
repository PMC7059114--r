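#' Write a session to a directory
#'
#' One tab-separated file per unit (`<unit_id>.tsv`, single column `time_s`)
#' plus a `session.json` metadata file listing units, roles, durations,
#' geometry, stimulus onsets and triggered spike times. Times are written
#' with 0.01 ms precision, finer than the 0.05 ms sampling step of a 20 kHz
#' acquisition, so `load_session(write_session(s))` reproduces `s` within
#' the quantization bound. Output is deterministic for a fixed session.
#'
#' @param session a [session].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  units <- lapply(session$trains, function(tr) {
    list(unit_id = tr$unit_id, role = tr$role, duration = tr$duration,
         file = paste0(tr$unit_id, ".tsv"))
  })
  names(units) <- NULL
  meta <- list(format = "spikemotifs-session", version = 1L, units = units)
  if (!is.null(session$geometry))
    meta$geometry <- lapply(session$geometry, unclass)
  if (!is.null(session$stimulus_onsets)) {
    meta$stimulus_onsets <- round(session$stimulus_onsets, 5)
    meta$stimulus_duration <- session$stimulus_duration
  }
  if (!is.null(session$triggered_spike_times))
    meta$triggered_spike_times <- round(session$triggered_spike_times, 5)
  if (!is.null(session$sampling_rate))
    meta$sampling_rate <- session$sampling_rate
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(path, "session.json"))
  for (tr in session$trains) {
    con <- file(file.path(path, paste0(tr$unit_id, ".tsv")), "w")
    writeLines(c("time_s", sprintf("%.5f", tr$times)), con)
    close(con)
  }
  invisible(path)
}

#' Load a session from a directory
#'
#' Counterpart of [write_session]. Validation is strict: missing metadata,
#' duplicate unit ids, unparseable rows, unsorted times, or times beyond the
#' recorded duration are reported as errors naming the file (and the first
#' offending row where applicable).
#'
#' @param path session directory.
#' @return a [session].
#' @export
load_session <- function(path) {
  mf <- file.path(path, "session.json")
  if (!file.exists(mf)) stop("no session.json metadata file in ", path)
  meta <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  if (!identical(meta$format, "spikemotifs-session"))
    stop("not a spikemotifs session: ", mf)
  ids <- vapply(meta$units, `[[`, "", "unit_id")
  if (anyDuplicated(ids))
    stop("duplicate unit id in metadata: ", ids[duplicated(ids)][1])
  trains <- lapply(meta$units, function(u) {
    f <- file.path(path, u$file)
    if (!file.exists(f)) stop("missing spike-time file: ", f)
    lines <- readLines(f)
    if (!length(lines) || lines[1] != "time_s")
      stop("expected header 'time_s' in ", f)
    body <- lines[-1]
    times <- suppressWarnings(as.numeric(body))
    if (anyNA(times))
      stop(sprintf("unparseable time in %s at row %d", f,
                   which(is.na(times))[1] + 1L))
    if (length(times) > 1L && is.unsorted(times, strictly = TRUE)) {
      bad <- which(diff(times) <= 0)[1] + 1L
      stop(sprintf("times not strictly increasing in %s at row %d", f,
                   bad + 1L))
    }
    if (length(times) && times[length(times)] > u$duration + 1e-9)
      stop(sprintf("time exceeds duration in %s at row %d", f,
                   which(times > u$duration + 1e-9)[1] + 1L))
    spike_train(times, u$duration, u$role, u$unit_id)
  })
  geometry <- NULL
  if (!is.null(meta$geometry))
    geometry <- lapply(meta$geometry, function(g) do.call(soma_geometry, g))
  session(trains, geometry = geometry,
          stimulus_onsets = if (!is.null(meta$stimulus_onsets))
            unlist(meta$stimulus_onsets),
          stimulus_duration = if (!is.null(meta$stimulus_duration))
            meta$stimulus_duration else 0.060,
          triggered_spike_times = if (!is.null(meta$triggered_spike_times))
            unlist(meta$triggered_spike_times),
          sampling_rate = meta$sampling_rate)
}

#' Eligibility of a session for each analysis
#'
#' Applies the published inclusion floors and reports, per analysis, a
#' boolean verdict with the supporting count: at least 200 spontaneous IN
#' spikes for the spontaneous correlogram analyses; at least 200 IN spikes
#' within +/-100 ms of Purkinje complex spikes for the climbing-fiber
#' analyses; stimulus onsets present and at least 20 trials with a
#' sensory-evoked IN spike (0-20 ms from onset) for the sensory analyses.
#'
#' @param session a [session].
#' @param config an [analysis_config].
#' @return a data.frame with columns `analysis`, `eligible`, `count`,
#'   `required`.
#' @export
apply_inclusion_criteria <- function(session, config = analysis_config()) {
  in_tr <- session_train(session, "IN", required = FALSE)
  cs_tr <- session_train(session, "PC_COMPLEX", required = FALSE)
  res <- list()
  n_spont <- if (is.null(in_tr)) 0L else
    length(spontaneous_times(in_tr, session$stimulus_onsets,
                             config$spontaneous_exclusion))
  res[["spontaneous_ccg"]] <-
    c(n_spont, config$min_spontaneous_in_spikes)
  n_cs_locked <- 0L
  if (!is.null(in_tr) && !is.null(cs_tr) && length(cs_tr$times) &&
      length(in_tr$times)) {
    cs <- cs_tr$times
    idx <- findInterval(in_tr$times, cs)
    d_lo <- ifelse(idx >= 1L, in_tr$times - cs[pmax(idx, 1L)], Inf)
    d_hi <- ifelse(idx < length(cs), cs[pmin(idx + 1L, length(cs))] -
                     in_tr$times, Inf)
    n_cs_locked <- sum(pmin(d_lo, d_hi) <= config$ccg_window)
  }
  res[["cf_in_ccg"]] <- c(n_cs_locked, config$min_cs_locked_in_spikes)
  n_evoked <- 0L
  if (!is.null(session$stimulus_onsets) && length(session$stimulus_onsets) &&
      !is.null(in_tr)) {
    n_evoked <- sum(vapply(session$stimulus_onsets, function(on)
      any(in_tr$times >= on & in_tr$times < on + config$evoked_window), TRUE))
  }
  res[["sensory"]] <- c(n_evoked, config$min_evoked_trials)
  data.frame(analysis = names(res),
             eligible = vapply(res, function(x) x[1] >= x[2], TRUE),
             count = vapply(res, `[[`, 0, 1),
             required = vapply(res, `[[`, 0, 2),
             row.names = NULL)
}
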
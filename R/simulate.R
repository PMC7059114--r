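#' Ground-truth unit description
#'
#' @param unit_id unit id.
#' @param role one of `"IN"`, `"PC_SIMPLE"`, `"PC_COMPLEX"`.
#' @param rate baseline mean rate (Hz). Defaults to the published
#'   population means: IN 8.0 Hz, PC simple spikes 26.4 Hz, complex spikes
#'   1.2 Hz.
#' @param shape renewal shape (gamma). 1 = Poisson; the PC simple-spike
#'   default is 4, mimicking regular PC firing.
#' @return a `gt_unit` list.
#' @export
gt_unit <- function(unit_id, role, rate = NULL, shape = NULL) {
  role <- match.arg(role, .roles)
  if (is.null(rate))
    rate <- c(IN = 8.0, PC_SIMPLE = 26.4, PC_COMPLEX = 1.2)[[role]]
  if (is.null(shape)) shape <- if (role == "PC_SIMPLE") 4 else 1
  list(unit_id = unit_id, role = role, rate = rate, shape = shape)
}

#' Ground-truth coupling kernel
#'
#' Kernels act on the target's conditional intensity for each source spike:
#' \describe{
#'   \item{BOX_GAIN}{multiplies the hazard by `gain` for lags in
#'     `[onset, onset + par)`; `gain < 1` is inhibition, `> 1` excitation,
#'     0 a hard veto.}
#'   \item{ALPHA}{multiplies the hazard by `1 + (gain - 1) * a(lag)` where
#'     `a` is an alpha function rising after `onset` and peaking (value 1)
#'     at `onset + par`; models the slow-rising glutamate-spillover
#'     excitation.}
#'   \item{ADD_GAUSS}{adds a Gaussian rate bump of total area `gain`
#'     spikes, centered `onset` seconds after the source event with SD
#'     `par`; used for stimulus-locked components.}
#' }
#' Gains from multiple active source spikes multiply (additive kernels
#' sum).
#'
#' @param source,target unit ids (the specials `".stim"` and
#'   `".evoked_cs"` refer to stimulus onsets and sensory-evoked complex
#'   spikes).
#' @param type kernel shape.
#' @param gain see Details.
#' @param onset lag offset (s).
#' @param par BOX width / ALPHA time-to-peak / Gaussian SD (s).
#' @return a `gt_kernel` list.
#' @export
gt_kernel <- function(source, target,
                      type = c("BOX_GAIN", "ALPHA", "ADD_GAUSS"),
                      gain, onset = 0, par) {
  type <- match.arg(type)
  stopifnot(gain >= 0, onset >= 0, par > 0)
  list(source = source, target = target, type = type, gain = gain,
       onset = onset, par = par)
}

#' Ground truth for a simulated session
#'
#' The full stated world of the generator: baseline rates and renewal
#' shapes per unit, coupling kernels, optional gap-junction coincidence
#' injection, optional shared log-rate (Ornstein-Uhlenbeck) co-modulation,
#' and stimulus-locked sensory response parameters. Everything is plain
#' data (serializable to JSON), so a simulated session is exactly
#' reproducible from the truth plus a seed.
#'
#' Default units are one IN (8 Hz, Poisson-like), one PC simple-spike train
#' (26.4 Hz, gamma renewal shape 4) and one complex-spike train (1.2 Hz),
#' with a hard post-complex-spike pause of the simple spikes (15 ms veto).
#'
#' @param units list of [gt_unit]s.
#' @param kernels list of [gt_kernel]s.
#' @param gap_junction `NULL` or `list(source, target, p, offset, jitter)`:
#'   with probability `p` each source spike gets a coincident partner spike
#'   in `target` at `+/-offset` (random sign) with Gaussian `jitter`.
#' @param common_input `NULL` or `list(units, amplitude, timescale)`:
#'   shared OU log-rate modulation (stationary SD `amplitude`, correlation
#'   time `timescale` seconds) applied multiplicatively to the listed
#'   units, mean-corrected so the average rate is preserved.
#' @param sensory `NULL` or a list of stimulus-locked components, see
#'   [simulate_sensory_session].
#' @param cs_pause include the post-complex-spike simple-spike pause
#'   (default `TRUE`; BOX gain 0 for 15 ms).
#' @param refractory absolute refractory period (s).
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(units = list(gt_unit("IN1", "IN"),
                                      gt_unit("PC1s", "PC_SIMPLE"),
                                      gt_unit("PC1c", "PC_COMPLEX")),
                         kernels = list(), gap_junction = NULL,
                         common_input = NULL, sensory = NULL,
                         cs_pause = TRUE, refractory = 5e-4) {
  ids <- vapply(units, `[[`, "", "unit_id")
  if (anyDuplicated(ids)) stop("duplicate unit ids in ground truth")
  names(units) <- ids
  if (cs_pause) {
    cs <- ids[vapply(units, `[[`, "", "role") == "PC_COMPLEX"]
    pcs <- ids[vapply(units, `[[`, "", "role") == "PC_SIMPLE"]
    if (length(cs) && length(pcs))
      kernels <- c(kernels, list(gt_kernel(cs[1], pcs[1], "BOX_GAIN",
                                           gain = 0, onset = 0,
                                           par = 0.015)))
  }
  for (k in kernels)
    if (!k$target %in% ids) stop("kernel targets unknown unit: ", k$target)
  structure(list(units = units, kernels = kernels,
                 gap_junction = gap_junction, common_input = common_input,
                 sensory = sensory, refractory = refractory),
            class = "ground_truth")
}

# max number of source events in any active-span window (for the
# intensity upper bound used by the thinning algorithm)
.max_overlap <- function(times, span) {
  if (length(times) < 2L) return(length(times))
  i <- 1L; best <- 1L
  for (j in seq_along(times)) {
    while (times[j] - times[i] > span) i <- i + 1L
    best <- max(best, j - i + 1L)
  }
  best
}

.kernel_span <- function(k) switch(k$type,
  BOX_GAIN = k$onset + k$par,
  ALPHA = k$onset + 10 * k$par,
  ADD_GAUSS = k$onset + 6 * k$par)

#' Simulate one spike train by exact thinning
#'
#' Exact (Ogata) thinning of a conditional-intensity process: a gamma
#' renewal baseline hazard (shape 1 = Poisson) modulated multiplicatively
#' by BOX/ALPHA kernels of already-simulated source trains, additively by
#' Gaussian stimulus kernels, and by an optional shared log-rate signal,
#' with an absolute refractory period. The intensity upper bound is
#' computed from the kernel gains and the maximum kernel overlap of each
#' source train; an unbounded intensity is an error.
#'
#' @param duration recording duration (s).
#' @param rate baseline mean rate (Hz).
#' @param kernels list of kernels as `list(times, type, gain, onset, par)`
#'   with `type` in `BOX_GAIN`/`ALPHA`/`ADD_GAUSS`.
#' @param shape renewal shape.
#' @param refractory absolute refractory period (s).
#' @param common `NULL` or `list(dt, log_rate)` piecewise-constant shared
#'   log-rate.
#' @return numeric vector of spike times.
#' @export
simulate_conditional_intensity <- function(duration, rate, kernels = list(),
                                           shape = 1, refractory = 5e-4,
                                           common = NULL) {
  base_max <- shape * rate
  mult_max <- 1; add_max <- 0
  kk <- lapply(kernels, function(k) {
    type_i <- match(k$type, c("BOX_GAIN", "ALPHA", "ADD_GAUSS")) - 1L
    ov <- .max_overlap(k$times, .kernel_span(k))
    if (k$type == "ADD_GAUSS") {
      add_max <<- add_max + ov * k$gain / (k$par * sqrt(2 * pi))
    } else {
      mult_max <<- mult_max * max(1, k$gain)^ov
    }
    list(times = as.numeric(k$times), type = type_i, gain = k$gain,
         onset = k$onset, par = k$par)
  })
  com_dt <- 1; com_log <- numeric(0); com_max <- 1
  if (!is.null(common)) {
    com_dt <- common$dt; com_log <- common$log_rate
    com_max <- exp(max(com_log))
  }
  lambda_max <- (base_max * mult_max + add_max) * com_max * (1 + 1e-9)
  if (!is.finite(lambda_max) || lambda_max > 1e6)
    stop("conditional intensity bound is unbounded or absurdly large")
  sim_thinning_cpp(duration, rate, refractory, shape, kk, lambda_max,
                   com_dt, com_log)
}

# shared OU log-rate on a grid, mean-corrected so E[exp(x)] = 1
.simulate_common <- function(duration, amplitude, timescale, dt = 0.005) {
  n <- ceiling(duration / dt) + 1L
  a <- exp(-dt / timescale)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, amplitude)
  innov <- rnorm(n - 1L, 0, amplitude * sqrt(1 - a^2))
  for (i in 2:n) x[i] <- a * x[i - 1L] + innov[i - 1L]
  list(dt = dt, log_rate = x - amplitude^2 / 2)
}

# enforce the absolute refractory floor on a sorted time vector
.enforce_refractory <- function(times, refractory) {
  if (length(times) < 2L) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Simulate a session from a ground truth
#'
#' Units are simulated in dependency order (kernel sources before their
#' targets) with [simulate_conditional_intensity]; gap-junction
#' coincidences are injected afterwards and the refractory floor is
#' re-enforced. With stimulus `onsets`, sensory components of the truth are
#' attached: additive stimulus-locked kernels per unit, evoked complex
#' spikes injected per trial with the configured probability and latency
#' jitter, and (optionally CS-conditional) delayed IN components sourced on
#' the evoked complex spikes.
#'
#' @param truth a [ground_truth].
#' @param duration recording duration (s).
#' @param seed optional integer seed.
#' @param onsets optional stimulus onsets (s).
#' @param fixed_sources named list of fixed event-time vectors that kernels
#'   may name as sources (e.g. electrically triggered spike times).
#' @return a [session]; the truth used is attached as attribute `"truth"`.
#' @export
simulate_session <- function(truth, duration, seed = NULL, onsets = NULL,
                             fixed_sources = list()) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(truth$units)
  kernels <- truth$kernels
  sens <- truth$sensory
  if (!is.null(onsets) && !is.null(sens) && !is.null(sens$components)) {
    for (comp in sens$components)
      kernels <- c(kernels, list(gt_kernel(
        if (isTRUE(comp$conditional_on_cs)) ".evoked_cs" else ".stim",
        comp$unit, "ADD_GAUSS", gain = comp$spikes,
        onset = comp$latency, par = comp$jitter)))
  }
  # dependency order (Kahn); special sources are always available
  deps <- lapply(ids, function(u) {
    s <- unique(vapply(kernels, function(k)
      if (k$target == u) k$source else NA_character_, ""))
    s <- s[!is.na(s) & !startsWith(s, ".") & !s %in% names(fixed_sources)]
    s
  })
  names(deps) <- ids
  cs_ids <- ids[vapply(truth$units, `[[`, "", "role") == "PC_COMPLEX"]
  uses_evoked <- any(vapply(kernels, function(k)
    k$source == ".evoked_cs", TRUE))
  if (uses_evoked && length(cs_ids))
    for (u in setdiff(ids, cs_ids))
      if (any(vapply(kernels, function(k)
        k$source == ".evoked_cs" && k$target == u, TRUE)))
        deps[[u]] <- unique(c(deps[[u]], cs_ids[1]))
  order <- character(0)
  pend <- ids
  while (length(pend)) {
    ready <- pend[vapply(pend, function(u)
      all(deps[[u]] %in% order), TRUE)]
    if (!length(ready)) stop("cyclic kernel dependencies in ground truth")
    order <- c(order, ready)
    pend <- setdiff(pend, ready)
  }
  common <- NULL
  if (!is.null(truth$common_input))
    common <- .simulate_common(duration, truth$common_input$amplitude,
                               truth$common_input$timescale)
  sim <- list()
  evoked_cs <- numeric(0)
  for (u in order) {
    uu <- truth$units[[u]]
    kk <- list()
    for (k in kernels) {
      if (k$target != u) next
      st <- if (k$source == ".stim") onsets
        else if (k$source == ".evoked_cs") evoked_cs
        else if (k$source %in% names(fixed_sources)) fixed_sources[[k$source]]
        else sim[[k$source]]
      if (is.null(st)) st <- numeric(0)
      kk <- c(kk, list(list(times = st, type = k$type, gain = k$gain,
                            onset = k$onset, par = k$par)))
    }
    com_u <- if (!is.null(common) && !is.null(truth$common_input$units) &&
                 u %in% truth$common_input$units) common else
      if (!is.null(common) && is.null(truth$common_input$units)) common
      else NULL
    tt <- simulate_conditional_intensity(duration, uu$rate, kk,
                                         shape = uu$shape,
                                         refractory = truth$refractory,
                                         common = com_u)
    if (uu$role == "PC_COMPLEX" && !is.null(onsets) && !is.null(sens) &&
        !is.null(sens$cs_prob) && sens$cs_prob > 0) {
      hit <- runif(length(onsets)) < sens$cs_prob
      inj <- onsets[hit] + rnorm(sum(hit), sens$cs_latency %||% 0.030,
                                 sens$cs_jitter %||% 0.010)
      inj <- inj[inj > 0 & inj < duration]
      tt <- .enforce_refractory(sort(c(tt, inj)), truth$refractory)
      idx <- findInterval(tt, onsets)
      evoked_cs <- tt[idx >= 1L & (tt - onsets[pmax(idx, 1L)]) >= 0 &
                        (tt - onsets[pmax(idx, 1L)]) < 0.100]
    } else if (uu$role == "PC_COMPLEX" && !is.null(onsets)) {
      idx <- findInterval(tt, onsets)
      evoked_cs <- tt[idx >= 1L & (tt - onsets[pmax(idx, 1L)]) >= 0 &
                        (tt - onsets[pmax(idx, 1L)]) < 0.100]
    }
    sim[[u]] <- tt
  }
  gj <- truth$gap_junction
  if (!is.null(gj) && gj$p > 0) {
    src <- sim[[gj$source]]
    hit <- runif(length(src)) < gj$p
    off <- (gj$offset %||% 0.001) * sample(c(-1, 1), sum(hit), TRUE) +
      rnorm(sum(hit), 0, gj$jitter %||% 2e-4)
    inj <- src[hit] + off
    inj <- inj[inj > 0 & inj < duration]
    sim[[gj$target]] <- .enforce_refractory(
      sort(c(sim[[gj$target]], inj)), truth$refractory)
  }
  trains <- lapply(ids, function(u)
    spike_train(sim[[u]], duration, truth$units[[u]]$role, u,
                refractory = truth$refractory))
  out <- session(trains, stimulus_onsets = onsets)
  attr(out, "truth") <- truth
  out
}

#' Simulate a spontaneous paired recording
#'
#' Convenience wrapper around [simulate_session] without stimuli.
#'
#' @param truth a [ground_truth].
#' @param duration recording duration (s), default 600 (10 min).
#' @param seed optional integer seed.
#' @return a [session] with attribute `"truth"`.
#' @export
simulate_pair <- function(truth = ground_truth(), duration = 600,
                          seed = NULL) {
  simulate_session(truth, duration, seed = seed)
}

#' Simulate a sensory (airpuff) session
#'
#' Stimulus onsets with 1-2 s inter-stimulus intervals; stimulus-locked
#' additive response components per unit as configured in
#' `truth$sensory$components` (defaults: fast granule-cell-driven responses
#' of 1 spike/trial at 13 ms latency for the PC and 14 ms for the IN, 1 ms
#' jitter); evoked complex spikes per trial with probability
#' `truth$sensory$cs_prob`; delayed IN components may be conditioned on the
#' evoked complex spike (`conditional_on_cs`), in which case they are
#' sourced on the evoked CS times themselves.
#'
#' @param truth a [ground_truth]; if its `sensory` slot is `NULL` the
#'   default components above are used.
#' @param n_trials number of stimuli.
#' @param isi_range length-2 inter-stimulus interval range (s).
#' @param seed optional integer seed.
#' @return a [session] with stimulus onsets and attribute `"truth"`.
#' @export
simulate_sensory_session <- function(truth = ground_truth(), n_trials = 100,
                                     isi_range = c(1, 2), seed = NULL) {
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(truth$sensory)) truth$sensory <- default_sensory()
  onsets <- 0.5 + cumsum(runif(n_trials, isi_range[1], isi_range[2]))
  duration <- onsets[n_trials] + 0.6
  simulate_session(truth, duration, onsets = onsets)
}

#' Default sensory response parameters
#'
#' Fast granule-cell components at the published latency peaks (PC 13 ms,
#' IN 14 ms; 1 ms jitter), a 40% per-trial evoked-complex-spike
#' probability at 30 +/- 10 ms, and a delayed CS-conditional IN component
#' (55 ms after the evoked CS). Amplitudes (spikes/trial) are package
#' choices documented in the methods vignette.
#'
#' @param pc_spikes,in_spikes fast component areas (spikes/trial).
#' @param in_delayed_spikes delayed IN component area.
#' @param cs_prob evoked-CS probability per trial.
#' @return a sensory configuration list.
#' @export
default_sensory <- function(pc_spikes = 1.0, in_spikes = 1.0,
                            in_delayed_spikes = 0.5, cs_prob = 0.4) {
  list(components = list(
         list(unit = "PC1s", latency = 0.013, jitter = 0.001,
              spikes = pc_spikes),
         list(unit = "IN1", latency = 0.014, jitter = 0.001,
              spikes = in_spikes),
         list(unit = "IN1", latency = 0.055, jitter = 0.015,
              spikes = in_delayed_spikes, conditional_on_cs = TRUE)),
       cs_prob = cs_prob, cs_latency = 0.030, cs_jitter = 0.010)
}

#' Simulate a population implementing the depth-organized circuit rules
#'
#' Generates `n_pairs` sessions, each realizing one ground-truth motif
#' class, with soma geometry sampled so the published depth rules hold:
#' IN-PC inhibition strength graded by IN depth (deep INs, close to the PC
#' layer, inhibit strongly), IN-IN inhibition directed superficial to deep,
#' climbing-fiber spillover excitation for superficial/intermediate INs and
#' CF-linked (disynaptic) inhibition for deep INs.
#'
#' @param n_pairs number of pairs.
#' @param duration per-session duration (s).
#' @param seed optional integer seed.
#' @param classes motif classes to cycle through.
#' @return list with `sessions` (list of [session]) and `truth_table`
#'   (data.frame: pair id, class, geometry, generative parameters).
#' @export
simulate_population <- function(n_pairs = 50, duration = 600, seed = NULL,
                                classes = c("IN_PC_INHIBITION",
                                            "IN_IN_INHIBITION",
                                            "CF_IN_EXCITATION",
                                            "CF_IN_INHIBITION",
                                            "GAP_JUNCTION", "NONE")) {
  if (!is.null(seed)) set.seed(seed)
  if (n_pairs == 0)
    return(list(sessions = list(),
                truth_table = data.frame(pair_id = character(0),
                                         class = character(0))))
  dura_depth <- 50; pc_layer <- 250  # um; molecular layer 200 um thick
  rows <- list(); sessions <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    cls <- classes[(i - 1L) %% length(classes) + 1L]
    z_in <- runif(1, dura_depth + 10, pc_layer - 10)
    ml_dist <- pc_layer - z_in                  # PC soma = 0 reference
    geom_pc <- soma_geometry(0, 0, pc_layer, pc_layer, dura_depth)
    geom_in <- soma_geometry(runif(1, -20, 20), runif(1, -20, 20), z_in,
                             pc_layer, dura_depth)
    gain <- NA_real_
    tr <- switch(cls,
      IN_PC_INHIBITION = {
        # inhibition graded by depth: deep INs (small ml_dist) strongest,
        # superficial INs weakest but still within detection range
        gain <- 0.5 + 0.0015 * ml_dist
        ground_truth(kernels = list(gt_kernel("IN1", "PC1s", "BOX_GAIN",
                                              gain = gain, par = 0.010)))
      },
      IN_IN_INHIBITION = {
        gain <- 0.6
        # superficial IN1 inhibits deeper IN2
        ground_truth(units = list(gt_unit("IN1", "IN"),
                                  gt_unit("IN2", "IN")),
                     kernels = list(gt_kernel("IN1", "IN2", "BOX_GAIN",
                                              gain = gain, par = 0.010)))
      },
      CF_IN_EXCITATION = {
        gain <- 3
        ground_truth(kernels = list(gt_kernel("PC1c", "IN1", "ALPHA",
                                              gain = gain, onset = 0.002,
                                              par = 0.013)))
      },
      CF_IN_INHIBITION = {
        gain <- 0.3
        ground_truth(kernels = list(gt_kernel("PC1c", "IN1", "BOX_GAIN",
                                              gain = gain, onset = 0.010,
                                              par = 0.020)))
      },
      GAP_JUNCTION = {
        gain <- 0.2
        ground_truth(units = list(gt_unit("IN1", "IN"),
                                  gt_unit("IN2", "IN")),
                     gap_junction = list(source = "IN1", target = "IN2",
                                         p = gain))
      },
      NONE = ground_truth())
    # depth rules for geometry of the IN-IN classes
    if (cls %in% c("IN_IN_INHIBITION", "GAP_JUNCTION")) {
      z2 <- min(z_in + runif(1, 20, 60), pc_layer - 5)
      geom_in2 <- soma_geometry(runif(1, -20, 20), runif(1, -20, 20), z2,
                                pc_layer, dura_depth)
    }
    ses <- simulate_session(tr, duration)
    geom <- list(PC1s = geom_pc, IN1 = geom_in)
    if (cls %in% c("IN_IN_INHIBITION", "GAP_JUNCTION"))
      geom <- list(IN1 = geom_in, IN2 = geom_in2)
    ses$geometry <- geom[intersect(names(geom), names(ses$trains))]
    sessions[[i]] <- ses
    rows[[i]] <- data.frame(pair_id = sprintf("pair%03d", i), class = cls,
                            gain = gain, ml_depth_distance = ml_dist,
                            transverse_distance = abs(geom_in$x_transverse),
                            z_in = z_in)
  }
  list(sessions = sessions, truth_table = do.call(rbind, rows))
}

#' Lengthen the target inter-spike interval containing each event
#'
#' Ground-truth world for the shuffled-ISI test: for every event, the
#' target spike ending the interval containing the event is delayed by
#' `delta` seconds (borrowed from the following interval, so all later
#' spike times are unchanged and events keep their containing intervals).
#' The delay is capped so the following interval keeps at least
#' `min_gap`. Events not inside any ISI are ignored.
#'
#' @param times sorted target spike times (s).
#' @param events event times (s).
#' @param delta lengthening per event (s).
#' @param duration recording duration; spikes pushed beyond it are dropped.
#' @param min_gap minimum remaining following interval (s).
#' @return modified spike-time vector.
#' @export
lengthen_isis <- function(times, events, delta, duration = Inf,
                          min_gap = 1e-3) {
  if (!length(times) || !length(events)) return(times)
  idx <- findInterval(events, times)
  idx <- idx[idx >= 1L & idx < length(times) - 1L]
  out <- times
  for (i in idx) {
    room <- out[i + 2L] - out[i + 1L] - min_gap
    out[i + 1L] <- out[i + 1L] + min(delta, max(room, 0))
  }
  out[out <= duration]
}

#' Synthesize a raw voltage-clamp trace from labeled spike times
#'
#' Superimposes spike waveform templates on white noise at the acquisition
#' sampling rate (20 kHz). Simple spikes are a biphasic wavelet; complex
#' spikes add a 3 ms afterdischarge oscillation after the initial wavelet
#' (which is what the post-spike variance split detects). Spikes are
#' negative-going by default, as in cell-attached recordings.
#'
#' @param simple_times,complex_times spike times (s).
#' @param duration trace duration (s).
#' @param fs sampling rate (Hz).
#' @param amplitude spike peak amplitude (arbitrary units).
#' @param noise_sd white-noise SD.
#' @param polarity `"negative"` or `"positive"`.
#' @return list of class `raw_trace`: `samples`, `sampling_rate`,
#'   `truth` (times + labels).
#' @export
synthesize_raw_trace <- function(simple_times, complex_times = numeric(0),
                                 duration, fs = 20000, amplitude = 1,
                                 noise_sd = 0.05,
                                 polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  n <- round(duration * fs)
  x <- rnorm(n, 0, noise_sd)
  tpl_len <- round(0.001 * fs)                      # 1 ms biphasic wavelet
  tt <- seq_len(tpl_len) / fs
  wavelet <- -amplitude * sin(2 * pi * tt / 0.001) *
    exp(-((tt - 2.5e-4) / 3e-4)^2)
  after_len <- round(0.003 * fs)                    # 3 ms afterdischarge
  ta <- seq_len(after_len) / fs
  after <- -0.45 * amplitude * sin(2 * pi * ta / 0.0015) *
    exp(-ta / 0.002)
  add_at <- function(x, t0, w) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0:min(i0 + length(w) - 1L, n)
    x[idx] <- x[idx] + w[seq_along(idx)]
    x
  }
  for (t0 in simple_times) x <- add_at(x, t0, wavelet)
  for (t0 in complex_times) x <- add_at(x, t0, c(wavelet, after))
  if (polarity == "positive") x <- -x
  structure(list(samples = x, sampling_rate = fs,
                 truth = list(simple_times = simple_times,
                              complex_times = complex_times,
                              polarity = polarity)),
            class = "raw_trace")
}
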
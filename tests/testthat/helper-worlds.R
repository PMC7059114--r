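# Shared ground-truth worlds and small utilities for the test suite.
# All stochastic fixtures are generated in code under fixed seeds.

# Poisson-PC world in which the closed-form inhibition expectations hold
# (the gamma-renewal default partially compensates a transient hazard drop,
# see the methods vignette).
world_inhibition <- function(gain = 0.7, width = 0.010, pc_shape = 1) {
  ground_truth(
    units = list(gt_unit("IN1", "IN"),
                 gt_unit("PC1s", "PC_SIMPLE", shape = pc_shape),
                 gt_unit("PC1c", "PC_COMPLEX")),
    kernels = list(gt_kernel("IN1", "PC1s", "BOX_GAIN", gain = gain,
                             par = width)))
}

world_cf_excitation <- function(gain = 3)
  ground_truth(kernels = list(gt_kernel("PC1c", "IN1", "ALPHA", gain = gain,
                                        onset = 0.002, par = 0.013)))

world_cf_inhibition <- function(gain = 0.3)
  ground_truth(kernels = list(gt_kernel("PC1c", "IN1", "BOX_GAIN",
                                        gain = gain, onset = 0.010,
                                        par = 0.020)))

world_cf_combined <- function()
  ground_truth(kernels = list(
    gt_kernel("PC1c", "IN1", "ALPHA", gain = 3, onset = 0.002, par = 0.008),
    gt_kernel("PC1c", "IN1", "BOX_GAIN", gain = 0.2, onset = 0.020,
              par = 0.020)))

world_gap_junction <- function(p = 0.2)
  ground_truth(units = list(gt_unit("IN1", "IN"), gt_unit("IN2", "IN")),
               gap_junction = list(source = "IN1", target = "IN2", p = p))

world_common_input <- function(amplitude = 0.5, timescale = 0.02)
  ground_truth(units = list(gt_unit("IN1", "IN"), gt_unit("IN2", "IN")),
               common_input = list(units = c("IN1", "IN2"),
                                   amplitude = amplitude,
                                   timescale = timescale))

# sensory world with explicit fast + (unconditional) delayed IN components
world_sensory_amplitude <- function(fast = 0.3, delayed = 0.2) {
  tr <- ground_truth()
  tr$sensory <- list(components = list(
    list(unit = "IN1", latency = 0.014, jitter = 0.001, spikes = fast),
    list(unit = "IN1", latency = 0.080, jitter = 0.015, spikes = delayed)),
    cs_prob = 0)
  tr
}

# O(n^2) brute-force cross-correlogram used as the independent oracle
brute_ccg_counts <- function(trig, targ, bin, win) {
  nb <- round(2 * win / bin)
  counts <- numeric(nb)
  for (t in trig) for (s in targ) {
    lag <- s - t
    if (lag >= -win && lag < win)
      counts[floor((lag + win) / bin) + 1] <-
        counts[floor((lag + win) / bin) + 1] + 1
  }
  counts
}

# hand-built zccg stub with given z values on a lag grid
zccg_stub <- function(z_values, bin_size = 0.010, window = 0.1,
                      normalized = NULL) {
  lags <- seq(-window, window - bin_size, by = bin_size)
  stopifnot(length(z_values) == length(lags))
  if (is.null(normalized)) normalized <- 1 + 0.1 * z_values
  structure(list(
    ccg = structure(list(lags = lags, bin_size = bin_size, window = window,
                         normalized = normalized, counts = normalized,
                         baseline_rate = 1, n_triggers = 100L,
                         baseline_flagged = FALSE),
                    class = "ccg"),
    null = NULL, z = z_values, undefined_bins = integer(0)),
    class = "zccg")
}

quiet_session_dir <- function() {
  d <- tempfile("ses")
  dir.create(d)
  d
}
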
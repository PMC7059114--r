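#' Detect spikes by amplitude threshold crossing
#'
#' Spike time = time of the first threshold-crossing sample of each event
#' (not the peak), matching the triggering semantics used for the
#' correlogram lags. The trace median is subtracted first, so detection is
#' invariant to a DC offset. Events closer than `dead_time` to the
#' previous detection are suppressed. Negative-going spikes (the
#' cell-attached default) are detected by sign-flipping the trace.
#'
#' @param trace a `raw_trace` (see [synthesize_raw_trace]) or a list with
#'   `samples` and `sampling_rate`.
#' @param threshold detection threshold in amplitude units (positive;
#'   applied after polarity adjustment).
#' @param polarity `"negative"` or `"positive"`.
#' @param dead_time minimum separation between detections (s).
#' @return numeric vector of spike times (s).
#' @export
detect_spikes <- function(trace, threshold,
                          polarity = c("negative", "positive"),
                          dead_time = 5e-4) {
  polarity <- match.arg(polarity)
  x <- trace$samples
  if (any(!is.finite(x))) stop("trace contains non-finite samples")
  fs <- trace$sampling_rate
  x <- x - median(x)
  if (polarity == "negative") x <- -x
  above <- x >= threshold
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(crossings)) return(numeric(0))
  times <- (crossings - 1L) / fs
  .enforce_refractory(times, dead_time)
}

#' Split detected spikes into simple and complex spikes
#'
#' Computes, for each spike, the trace variance over the `variance_window`
#' (default 3 ms) following the spike; complex spikes carry an
#' afterdischarge and form a high-variance population. Since detection
#' timestamps the threshold crossing, the window starts `variance_offset`
#' (default 1 ms) after it, skipping the stereotyped spike waveform that is
#' common to both classes. The two populations are separated automatically
#' with a 2-class Otsu threshold on the log variances (a reproducible
#' stand-in for the manual plot-and-click split), or with a
#' `manual_threshold` on the raw variance when given. If the distribution
#' shows no usable bimodality (class means closer than 3 pooled
#' within-class SDs), all spikes are labeled SIMPLE with a warning.
#'
#' @param trace a `raw_trace`.
#' @param spike_times detected spike times (s), at least 2.
#' @param variance_window seconds of trace entering each variance.
#' @param variance_offset seconds skipped after the threshold crossing.
#' @param manual_threshold optional variance threshold; spikes with
#'   variance above it are COMPLEX.
#' @return an object of class `spike_labels`: `spike_times`, `label`
#'   (`"SIMPLE"`/`"COMPLEX"`), `post_spike_variance`, `threshold`.
#' @export
split_simple_complex <- function(trace, spike_times,
                                 variance_window = 0.003,
                                 variance_offset = 0.001,
                                 manual_threshold = NULL) {
  if (length(spike_times) < 2L) stop("need at least 2 spikes to split")
  fs <- trace$sampling_rate
  x <- trace$samples
  n <- length(x)
  v <- vapply(spike_times, function(t0) {
    i0 <- round((t0 + variance_offset) * fs) + 1L
    i1 <- min(round((t0 + variance_offset + variance_window) * fs), n)
    if (i1 <= i0) return(0)
    var(x[i0:i1])
  }, 0)
  if (!is.null(manual_threshold)) {
    lab <- ifelse(v > manual_threshold, "COMPLEX", "SIMPLE")
    thr <- manual_threshold
  } else {
    lv <- log(pmax(v, .Machine$double.xmin))
    thr_lv <- .otsu(lv)
    g1 <- lv[lv <= thr_lv]; g2 <- lv[lv > thr_lv]
    pooled <- sqrt(mean(c(var(g1), var(g2)), na.rm = TRUE))
    sep <- mean(g2) - mean(g1)
    if (!length(g1) || !length(g2) || !is.finite(pooled) ||
        !is.finite(sep) || sep <= 3 * pooled) {
      warning("post-spike variance distribution not bimodal; ",
              "labeling all spikes SIMPLE")
      lab <- rep("SIMPLE", length(v))
      thr <- Inf
    } else {
      lab <- ifelse(lv > thr_lv, "COMPLEX", "SIMPLE")
      thr <- exp(thr_lv)
    }
  }
  structure(list(spike_times = spike_times, label = lab,
                 post_spike_variance = v, threshold = thr),
            class = "spike_labels")
}

# 1-D 2-class Otsu threshold (maximizes between-class variance)
.otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Derive role-labeled spike trains from labeled PC spikes
#'
#' Splits labeled Purkinje cell events into a simple-spike and a
#' complex-spike train. Spikelets within a complex spike are assumed
#' already collapsed into a single event by the detector's dead time.
#'
#' @param labels a [split_simple_complex] result.
#' @param duration recording duration (s).
#' @param unit_id base unit id; the trains get suffixes `"s"` and `"c"`.
#' @param refractory refractory floor for validation (s).
#' @return list with `simple` and `complex` [spike_train]s.
#' @export
derive_trains <- function(labels, duration, unit_id = "PC1",
                          refractory = 5e-4) {
  simple <- labels$spike_times[labels$label == "SIMPLE"]
  cx <- labels$spike_times[labels$label == "COMPLEX"]
  list(simple = spike_train(simple, duration, "PC_SIMPLE",
                            paste0(unit_id, "s"), refractory),
       complex = spike_train(cx, duration, "PC_COMPLEX",
                             paste0(unit_id, "c"), refractory))
}
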
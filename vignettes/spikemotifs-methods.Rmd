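---
title: "Inferring cerebellar microcircuit motifs from paired spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cerebellar microcircuit motifs from paired spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spikemotifs)
```

## The problem

Molecular layer interneurons (INs) of the cerebellar cortex inhibit
Purkinje cells (PCs) and each other, and are themselves recruited by
granule-cell input and by glutamate spilling over from climbing-fiber (CF)
synapses. Paired loose-patch recordings of an IN and a PC (or of two INs)
yield simultaneous spike trains — IN spikes, PC simple spikes, and PC
complex spikes (the CF readout) — from which functional connectivity must
be inferred statistically: a monosynaptic IN→PC connection shows up as a
transient deficit of PC simple spikes just after IN spikes, CF→IN
spillover as a slow-rising IN excitation after complex spikes, electrical
coupling between INs as sharp symmetric correlogram peaks at ±1 ms.

`spikemotifs` implements that inference pipeline — cross-correlograms with
a block-shuffle surrogate null and per-bin Z-scores, cumulative-sum net
spike change, a shuffled-ISI test for triggered spikes, stimulus-locked
latency and response decomposition, motif classification with soma
geometry — together with a ground-truth point-process simulator used to
validate every stage.

## The statistical core

### Correlogram and surrogate null

For trigger spikes $\{t_i\}$ and a target train, the cross-correlogram
(CCG) is the mean target spike count per lag bin per trigger over ±100 ms,
with half-open bins $[l, l+\Delta)$ so lag 0 belongs to the first
post-trigger bin. Edge triggers whose window is truncated by the recording
bounds are dropped (and counted); the bins are normalized by the mean
count over a baseline window (−100..−80 ms for IN-triggered, −100..0 ms
for complex-spike-triggered correlograms).

The null preserves slow rate structure while destroying short-lag
coupling: the recording is cut into 5 s segments, the segment order is
permuted uniformly (the final partial segment participates carrying its
own length; dropping it is available via configuration), and 500 shuffled
CCGs are computed. Per bin,

$$ z = \frac{\mathrm{norm}_{\mathrm{orig}} - \overline{\mathrm{norm}}_{\mathrm{shuf}}}
          {\mathrm{SD}_{\mathrm{shuf}}^{\mathrm{raw}} / r_{\mathrm{base}}^{\mathrm{orig}}} $$

i.e. original and shuffled CCGs are each normalized to their own baseline
rate, while the shuffle SD (taken on raw count-per-trigger CCGs) is
normalized to the original's baseline rate. $|z| > 3$ is significant.
Bins with zero shuffle SD yield `NA` and are excluded from classification
(reported in `undefined_bins`); a zero baseline rate flags the whole CCG
"not assessable".

### Motif calls

* **IN→PC inhibition**: $z < -3$ in the 0–10 ms bin (IN triggers, complex
  spikes within the preceding 25 ms excluded as triggers);
  **co-activation**: $z > 3$ in the −10–0 ms bin.
* **CF→IN excitation**: $z > 3$ in the 0–10 or 10–20 ms bin after the
  complex spike; **inhibition**: $z < -3$ in 10–20 or 20–30 ms;
  **combined** requires both with the excitation threshold crossed
  earlier.
* **IN–IN** (5 ms bins): co-activation $z > 3$, inhibition $z < -3$
  within ±10 ms lag; direction assigned so the presynaptic unit's spikes
  precede the deficit; if both directions are significant the call is
  bidirectional (the in vivo dataset reported only unidirectional cases).
* **Gap-junction synchrony** (0.5 ms bins): significant peaks at both
  +1 ms and −1 ms lag. We additionally require each peak to be *locally
  prominent* (normalized count ≥ 1.5× the mean at 2–6 ms flanking lags):
  without this clause, strong slow common-input co-modulation — which
  elevates every fine bin about equally — can push both ±1 ms bins past
  $z = 3$ without there being any peak. A "peak" that does not exceed its
  flanks is not a peak.

### Net spike change

The pooled cumulative count of target spikes at lags −100..+100 ms around
the events, minus a line fitted to the −100..−80 ms baseline segment and
extrapolated across the window, divided by the number of events: the
average number of spikes added or omitted per event as a function of lag.

Two read-outs are provided. The default scalar is the signed extremum of
the residual over 0..+100 ms (the published account reports a single
number without defining the lag). However, the residual inherits the
baseline-fit extrapolation error — a rate estimated from a 20 ms segment
and extrapolated over 200 ms has SD ≈ 0.1 spikes/event for a 10-minute
recording — so the extremum is noise-dominated per session and its mean
shrinks under sign-flips. `scalar_mode = "at_lag"` instead reads the
residual at a fixed lag (default +20 ms, just past the monosynaptic
window); it is unbiased for effects completed by that lag and is what the
package's own validation uses when comparing against the closed form
$-(1-g)\, r_{PC}\, w$ for a box gain $g$ of width $w$.

When measuring that closed form we also use all IN spikes as events rather
than the CCG's post-CS-excluded triggers: the exclusion conditions the
pre-trigger epoch on being free of complex-spike pauses and biases the
cumulative read by about +0.01 spikes/event.

### Shuffled-ISI test

For electrically triggered IN spikes, the effect on the PC is quantified
on the inter-spike interval containing each event (events landing exactly
on a spike time go to the following interval; events outside the train are
skipped and counted). The real median ISI is compared with 1000 medians
from uniformly placed hypothetical event times, matched in number. Because
random times are interval-length biased exactly like the real events, the
test is calibrated under independence (p uniform; verified by KS over 200
seeds). $z$ is the standard score against the shuffle distribution and
the two-sided empirical p uses the +1 correction, so $p \in (0, 1]$.

### Sensory analysis

Trials span −200..+300 ms around each airpuff onset. Labels: a trial has
a *fast IN response* if an IN spike falls in 0–20 ms (the granule-cell
window), and an *evoked complex spike* if one falls in 0–100 ms. The
cumulative spike change uses the −200..0 ms baseline; the fast amplitude
is the maximum mean spike change in 0–20 ms and the delayed amplitude the
maximum in 50–120 ms minus the fast amplitude.

First-spike latency histograms (2 ms bins; 0.5 ms for fine timing) are
summarized by the center of the maximal bin; a peak is "clear" when the
maximal count is ≥ 4 SDs above the mean of the bin counts. Two caveats we
quantified: (i) the 4-SD criterion calibrates only when bins hold ≳8
expected counts — in sparse histograms Poisson tails give it a 10–60%
false-positive rate, so peak claims from few trials should not be trusted;
(ii) the raw 0.5 ms-bin mode is noisy at 100 trials, so the PC-before-IN
ordering analysis smooths the histogram with a 2.5 ms boxcar
(`smooth_bins = 5`, ≈2.5× the 1 ms latency jitter) before the argmax; the
4-SD criterion always uses raw counts. First-spike selection plus 2 ms
binning also pulls a 14 ms component's peak into the [12,14) bin — a
−1 ms bias inherent to the read-out, not the generator.

## The synthetic ground truth

`simulate_session()` draws every train from an explicit conditional
intensity by exact (Ogata) thinning, with an absolute refractory period
(0.5 ms): the baseline is a gamma renewal hazard — Poisson for INs and
complex spikes; shape 4 for PC simple spikes, mimicking regular PC firing
— multiplied by the active coupling kernels, plus additive stimulus
kernels, times an optional shared log-rate modulation. Kernels:

* `BOX_GAIN` — hazard × gain for lags in [onset, onset+width); gain < 1
  is inhibition (0 = hard veto). Default IN→PC inhibition: gain 0.7 for
  10 ms, reproducing the ~30% published drop.
* `ALPHA` — hazard × (1 + (gain−1)·α(lag)), an alpha function peaking at
  onset+τ; CF→IN spillover uses onset 2 ms, peak ~15 ms.
* `ADD_GAUSS` — an added Gaussian rate bump of fixed area (spikes/event);
  used for stimulus-locked components (PC 13 ms, IN 14 ms, 1 ms jitter).

Defaults are the published population means: IN 8.0 Hz, PC simple 26.4 Hz,
complex spikes 1.2 Hz; a complex spike vetoes simple spikes for 15 ms (the
post-complex-spike pause). Gap-junction coupling injects a partner spike
at ±1 ms (0.2 ms jitter) with probability p per source spike. Common
input is a shared Ornstein–Uhlenbeck log-rate (default SD 0.5, correlation
time 20 ms — long against the ±1 ms gap-junction scale, short against the
5 s shuffle blocks, so it co-activates without faking electrical
coupling), mean-corrected to preserve rates. Sensory sessions use 1–2 s
inter-stimulus intervals; evoked complex spikes occur per trial with
probability 0.4 at 30 ± 10 ms, and the delayed (CF-linked) IN component is
sourced on the evoked complex spikes themselves, making its
CS-conditionality causal.

Everything is plain data (`write_ground_truth()`), and a session is
byte-reproducible from truth + seed.

### What a green test does and does not establish

The generator realizes the coupling structures the analyses assume —
multiplicative short-lag inhibition, slow-rising spillover excitation,
coincidence injection, stimulus-locked additive drive — under stationary
baselines. It does not model bursting, slow drift beyond the optional OU
term, dendritic nonlinearities, recording artifacts, or spike-sorting
errors. Recovery of a motif here validates the statistical machinery, not
the biological interpretation of any in vivo dataset.

Two generator-vs-theory facts worth knowing:

* A *renewal* target compensates a transient hazard drop (suppressed
  spikes age the process, raising the hazard): the measured 0–10 ms dip
  under a 0.7 gain is ≈ 0.75 for the gamma(4) PC but 0.70 for a Poisson
  PC. Closed-form validations therefore run on the Poisson-target world
  they describe.
* Concentrated additive bumps lose a few percent of their area to the
  refractory floor (a 0.3-spike bump with 1 ms jitter peaks at ~120 Hz
  instantaneous rate), so recovered amplitudes sit ~3–5% below nominal.

## Numerical and design choices

* Half-open bins; lag 0 in the first post-trigger bin. Edge triggers
  dropped, not partially counted (unbiased per-bin means).
* "Spontaneous" spikes in stimulated sessions exclude [onset,
  onset+300 ms) — the published analyses never define this boundary; we
  use the evoked-trace span.
* The automatic simple/complex split uses a 2-class Otsu threshold on
  log post-spike variance (manual override available). The variance
  window starts 1 ms after the threshold crossing, skipping the
  stereotyped spike waveform common to both classes; without the offset
  the shared waveform energy blurs the split. A separation below 3 pooled
  within-class SDs is declared unimodal (all SIMPLE, with a warning).
* Kruskal-Wallis follow-up comparisons are Tukey-Kramer on rank means
  with tie correction (the published tool's default; no method is named).
* Bootstrap prevalence SDs use 1000 resamples of pairs; distance bins
  default to 25 μm. Both are unstated in the source analyses.
* Fisher's exact test sums hypergeometric probabilities ≤ the observed
  table's (relative tie tolerance 1e-7) — the "summing small p values"
  two-sided convention, verified against `fisher.test` for all tables
  with N ≤ 40.
* CLI configuration is JSON (ground truth files, manifests); the
  environment provides no YAML parser and JSON round-trips the same
  structures.

## Known limitations

* Only block-shuffle surrogates are provided (no jitter/dither nulls).
* The onset-latency estimator (first threshold crossing of the binned Z)
  is a reconstruction; the source analyses report sub-bin latencies
  without describing their estimator, so absolute latency values are
  comparable only qualitatively (ordering, not milliseconds).
* Per-session net-spike-change and delayed sensory amplitudes are
  noise-dominated at realistic session lengths (see above); both should
  be averaged across sessions before quantitative comparison.
* The motif classifier assumes one IN-PC (or IN-IN) pair per session;
  population analyses loop over sessions.
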
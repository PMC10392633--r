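---
title: "Quantal analysis of amperometric recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal analysis of amperometric recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoquant)
```

## The measurement problem

Single-cell amperometry (SCA) places a carbon-fibre disk electrode
against a secretory cell; every exocytotic event releases catecholamine
that is oxidised at the electrode surface, producing a transient current
spike. Intracellular vesicle impact electrochemical cytometry (IVIEC)
inserts a nanotip electrode into the cytoplasm, where vesicles adsorb
and rupture so that each spike reports the *total* content of one
vesicle. Comparing the two measurements for a population of cells gives
the *fraction of vesicular release* — the share of a vesicle's content
actually released per event, the key observable of partial (sub-quantal)
exocytosis.

`exoquant` implements the complete analysis chain for such recordings:
filtering, spike detection, per-event quantification, per-cell
aggregation, nonparametric group comparison, and Fura-2 ratiometric
Ca^2+^ trace averaging. Because raw electrochemical recordings are
rarely shared, the package also contains a synthetic-recording generator
with a ground-truth event ledger, so that every stage of the pipeline is
testable end to end with known answers.

## From charge to molecules

A spike's charge is the trapezoidal integral of the baseline-corrected
current over the event extent, with negative excursions clipped at the
baseline first: only the oxidation current carries chemical information.
With current in pA and time in s, 1 pA·s = 10^3^ fC.

Faraday's law, $Q = nNF$, converts the charge $Q$ to $N$ moles of
analyte, where $n$ is the number of electrons transferred per molecule
and $F = 96{,}485$ C/mol. Results are reported as molecule counts,
$N_\mathrm{molec} = \frac{Q}{nF} N_A$. The default $n = 2$ is the
standard assumption for catechol oxidation (two electrons per
catecholamine); it is configurable through `faraday_constants()` for
other analytes. As a worked check, 1 pC at $n = 2$ corresponds to
$3.121 \times 10^6$ molecules.

## Filtering and detection

**Binomial smoothing.** Traces are smoothed by iterated convolution with
the normalised binomial kernel $(\tfrac14, \tfrac12, \tfrac14)$, whose
single-pass frequency response is $H_1(f) = \cos^2(\pi f/f_s)$. For a
requested cutoff $f_c$ the pass count is the smallest integer $p$ with

$$p \;\ge\; \frac{\ln 2}{4\,\ln\!\left(1/\cos(\pi f_c/f_s)\right)},$$

which places the filter's −3 dB point ($|H| = 1/\sqrt2$) at or below
$f_c$. At the standard 5 kHz digitisation a 1 kHz cutoff needs exactly
one pass. Edges are handled by reflection, so DC gain is exactly 1 and
the trace length is preserved.

**Noise floor.** The detection threshold is defined in units of the
baseline noise SD. Because quiescent windows may still contain the odd
spike, the estimator is deliberately robust: 1.4826 × the median
absolute deviation of the running-median-detrended current in the
quiescent window (the pre-stimulation segment for SCA, the first 10 % of
the trace for IVIEC, or any explicit window). The 25 ms detrending
window removes slow drift without eating millisecond-scale spikes.

**Threshold detection.** Local maxima of the baseline-corrected filtered
current exceeding 5 × noise SD (the conventional threshold for
amperometric peak picking) are accepted as peaks; each is extended to
the nearest crossings of baseline + 1 × noise SD to define its extent.
Three rules resolve composite regions:

* *Ripple absorption* — a secondary maximum whose separating valley is
  shallower than (threshold − boundary) × noise SD is treated as noise
  riding on the larger event, at any distance. Without this rule the
  decaying tail of a large spike regularly spawns spurious candidates
  and, worse, truncates the parent event's extent at the ripple valley.
* *Close peaks* — two maxima closer than 3 ms count as one event unless
  the valley between them drops below half of the smaller peak, in which
  case they are two events split at the valley minimum.
* *Gap bridging* — a dip below the boundary level shorter than 1 ms does
  not terminate an extent; with ~0.2 pA noise the tail of a genuine
  event crosses the boundary many times before it truly ends.

Published workflows follow automated peak picking with manual inspection
to remove false positives. As a deterministic surrogate, candidates are
rejected when narrower than 1 ms, carrying less than 1 fC, or rising
over fewer than 3 samples. All of these are parameters of
`detection_config()`.

Event extents at region edges include one sample beyond the boundary
crossing on each side, so that the sub-threshold sliver of the rising
edge and tail is bracketed by the trapezoidal integral; omitting it
costs ≈1 % of charge systematically.

Whether only stimulation-locked events should be counted in SCA is a
judgement call in real experiments; it is exposed as the `stim_only`
option rather than hard-coded.

**Baseline.** The per-sample baseline is a 200 ms running median with
each detected event extent replaced by linear interpolation between its
flanks (a plain running median is dragged upward inside wide events).
If events cover the entire trace, the fallback is the straight line
between the endpoints.

Indices are 1-based and event windows inclusive, the native R
convention; all exported tables also carry times in seconds, which are
convention-free.

## Spike shape parameters

Each event is characterised on the filtered trace (consistently with
detection, since the published parameters are measured on smoothed
traces) by:

* `i_max` — peak baseline-corrected current, pA;
* `t_half` — width at 50 % of `i_max`, first upward to last downward
  crossing;
* `t_rise` — 25 % → 75 % duration on the rising limb (fusion-pore
  opening);
* `t_fall` — 75 % → 25 % duration on the falling limb (pore closing).

All crossings are sub-sample by linear interpolation; on noisy events
the first crossing is used on the rising limb and the last on the
falling limb. Events too short to bracket a crossing are flagged and
excluded from kinetic summaries while their charge still counts — a
deliberate asymmetry, since charge is robust to truncation but crossing
times are not.

## Statistics

The statistical unit is the cell: per-cell means feed all group
comparisons, so a hypersecreting cell cannot dominate a condition. A
pooled-event mode (`aggregation = "pooled"`) is provided because
published event-level comparisons are sometimes run on pooled spikes;
both modes are first-class and give the same qualitative answers on
simulated data.

Group location differences use the unpaired two-sided Mann–Whitney
rank-sum test, the standard choice for strongly right-skewed
amperometric quantities. $U$ is computed from midranks; the p-value is
exact (null distribution of $U$) when there are no ties and
$n_1 n_2 \le 400$, otherwise the normal approximation with tie
correction and a 0.5 continuity correction is used, and the method is
recorded in the result. P-values are reported unadjusted, matching
standard practice for pairwise amperometric comparisons. Summaries are
mean ± SEM.

The fraction of release is the ratio of group means — released (SCA)
over stored (IVIEC) — not a mean of per-cell ratios: the two modes
measure *different cells*, so no pairing exists. It is reported both
unrounded and to the nearest integer percent (the conventional
presentation). Since the ratio has no closed-form small-sample error, a
percentile bootstrap CI with independent cell-level resampling of both
groups is provided (`fraction_bootstrap_ci()`, deterministic given its
seed).

## Calcium traces

Fura-2 imaging yields per-ROI intensity series at 340 and 380 nm
excitation; the background-corrected ratio
$r(t) = (F_{340} - b_{340})/(F_{380} - b_{380})$ tracks cytosolic free
Ca^2+^ independently of dye loading. Frames where the corrected 380 nm
signal is not positive are dropped rather than imputed. Traces are
resampled onto a common grid by linear interpolation and averaged
across cells into a mean ± SEM response curve. Baseline normalisation
(subtracting each cell's mean over the first 5 s, the conventional
pre-stimulation baseline) is available but off by default, since
absolute ratios are the conventional display. Conversion to absolute
Ca^2+^ concentration via the Fura-2 K~d~ is out of scope.

## The synthetic-data generator

Real spike generative models are not part of the published record, so
every distributional choice in the simulator is a package design
decision, documented here and exercised by the tests.

* **Spike template** — difference of exponentials,
  $i(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$, scaled so the integral
  equals the event's charge. It is the simplest strictly positive pulse
  with independent rise and decay control; any pulse reproducing
  `i_max`/`t_half`/`t_rise`/`t_fall` would serve, since the analysis
  side never assumes the functional form. Defaults
  $\tau_r = 0.5$ ms, $\tau_d = 3$ ms give millisecond-scale spikes
  typical of dense-core vesicle release.
* **Quantal sizes** — log-normal with configurable mean and CV 0.8;
  amperometric quantal-size distributions are strongly right-skewed.
* **Event timing** — homogeneous Poisson, inside the 5 s stimulation
  window for SCA and over the whole trace for IVIEC (vesicle rupture at
  a nanotip is not stimulus-locked). Default per-condition SCA rates are
  the published events-per-cell divided by the 5 s window: control
  15/5 s, OGDR 36/5 s, zinc 8/5 s, zinc + OGDR 18/5 s. The IVIEC rate
  (1.5 events/s) is a simulator choice.
* **Noise and drift** — additive white Gaussian noise (default 0.3 pA,
  a low-noise carbon-fibre recording after analogue filtering) plus a
  slow sinusoid (default 2 pA amplitude, period twice the trace length)
  to exercise baseline correction without dominating it. The noise
  default matters quantitatively: since the detection threshold scales
  with the noise floor, a noisier design censors the small-event tail of
  the log-normal and biases recovered means upward; at 0.3 pA the
  censored charge share is below 1 %.
* **Seeds** — every stochastic element derives from the configuration
  seed; per-cell seeds are `seed + cell index`, so any single cell can
  be regenerated in isolation, and the caller's RNG state is never
  touched.
* **Fura-2** — the 340/380 ratio rises linearly over the 5 s
  stimulation to the configured amplitude and relaxes exponentially
  (15 s time constant) over a 90 s recording at 10 frames/s, with a
  common additive background on both channels and 1 % multiplicative
  per-frame noise.

What the simulator does *not* emulate: pre-spike feet, flickering
fusion pores, overlapping-event deconvolution beyond valley splitting,
electrode fouling, or line interference. Passing tests therefore
demonstrate correctness of the analysis chain under a clean generative
model, not robustness to every artefact of bench data.

## End-to-end validation and problem sizes

The test suite validates the full chain — simulate, filter, detect,
quantify, aggregate, compare — against the simulator's ledger and
against the published worked examples: the four condition means
(released 105k/208k/103k/116k molecules; stored 176k/299k/126k/205k)
must reproduce release fractions of 60/70/82/57 %.

Detection fidelity is measured on 500 simulated SCA traces (recall and
precision ≥ 0.95 for events with SNR ≥ 8 at ≤ 5 events/s, isolated-event
charge within 5 %). The end-to-end fraction recovery uses 20 cells per
condition and mode — matching the published n > 16 — and averages the
recovered fractions over 16 replicate simulated experiments. A single
replicate is deliberately not asserted against the ±3-point band: with
the published event rates (down to 8 events per cell for zinc) and a
log-normal CV of 0.8, the sampling SD of a single recovered fraction is
4–8 percentage points, so a one-shot comparison would test luck rather
than correctness; averaging replicates estimates the pipeline's
*expected* recovery, which is the quantity the ±3-point band can
meaningfully constrain. The same analysis explains why per-condition
bootstrap CIs on the fraction are wide (±6–10 points) at realistic cell
counts.

## Known limitations

* No overlap deconvolution: coincident events within one extent are
  merged unless separated by a clear valley, slightly inflating mean
  quantal size at high event rates (≈2 % at 3 events/s).
* Charge is systematically underestimated by ≈2 % because the extent
  truncates the exponential tail at the boundary level; this cancels in
  the released/stored ratio.
* The exact Mann–Whitney p-value is only available for tie-free samples
  with $n_1 n_2 \le 400$; beyond that the corrected normal
  approximation is used (and flagged in the result).
* Trace I/O is CSV with a JSON metadata sidecar; instrument-vendor
  formats are out of scope.
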
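---
title: "Methods: evoked calcium-transient quantification and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked calcium-transient quantification and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

## The measurement model

A recording is a uniform grid of fluorescence frames under a three-event
protocol: a receptor stimulus (ATP, KCl or DHPG) at `tStimulus`, the
ionophore ionomycin at `tIonomycin`, and the chelator EGTA at `tEgta`
(defaults 20 s, 200 s, 400 s over a 500 s recording at 1 s per frame). The
defaults in `StimulusProtocol()` are the single source of timing truth;
every window below is derived from them.

Per cell, the pipeline computes a background-subtracted, baseline-normalized
fold series

$$ F_{\mathrm{fold}}(t) \;=\; \frac{\max(F(t) - B,\, 0)}{F_0},
   \qquad F_0 = \frac{1}{3}\sum_{k=1}^{3} \max(F(t_k) - B,\, 0), $$

with $B$ a scalar (or per-frame) background. The baseline frames are, by
default, the first `nBaselineFrames = 3` frames of the recording. The phrase
"the first three images before delivering the stimulus" is ambiguous between
frames $\{0,1,2\}$ and the three frames immediately preceding the stimulus;
the two readings coincide for flat baselines, and the alternative is
available as `normalizeTraces(anchor = "prestimulus")`. By construction the
baseline-window mean of $F_{\mathrm{fold}}$ is exactly 1 (tested to
$10^{-12}$), and normalization is invariant to rescaling the raw counts.

Windows are half-open so every frame belongs to exactly one phase: baseline
frames, receptor-mediated response (RMR) on $[t_{\mathrm{stim}},
t_{\mathrm{iono}})$, ionomycin on $[t_{\mathrm{iono}}, t_{\mathrm{EGTA}})$,
EGTA tail afterwards. The stimulus frame itself belongs to the RMR window,
so a peak can never precede its stimulus. Per-cell features are window
maxima with first-occurrence tie-breaking:

* `max_rmr_fold`, `time_to_max_rmr` (s from stimulus delivery),
* `max_iono_fold`, `time_to_max_iono` (s from ionomycin addition),
* `responder`: `max_rmr_fold >= 2`, boundary inclusive.

Two deliberate choices here. First, "rate of rise" is reported as the time
from stimulus to the window maximum, in seconds, because that is the unit in
which the study reports it; a 10–90% rise slope (fold/s) is available as a
secondary metric (`AnalysisConfig(includeRiseSlope = TRUE)`) but off by
default, since a slope estimated from noisy single frames is far less
stable. Second, ionomycin metrics are computed on the same normalized trace
without re-baselining at the ionomycin frame, matching a single-F0
description of the measurement. The EGTA tail is retained in the data but
contributes no metric.

No smoothing, detrending or bleach correction is applied before feature
extraction: any smoothing kernel biases the time-to-max, and the analysis
this package reproduces describes none.

## Group statistics

Cells from all lines of a group are pooled (two ASD lines into one ASD
sample, two control lines into one control sample). Group means include
non-responders: a reported condition pairing a grand mean of 1.58 fold with
13.6% doubling is only coherent if all imaged cells enter the mean.
Comparisons use the two-tailed Mann–Whitney U test with midranks,
`U = min(U1, U2)`, an exact tail for `n1 + n2 <= 20` without ties, and
otherwise the normal approximation with tie-corrected variance and
continuity correction. The exact branch is verified against brute-force
enumeration of all rank splits, and the approximate branch holds its size:
its type-I error at α = 0.05 over 10⁴ Gaussian null simulations at
n = 20/20 is tested to lie in [0.040, 0.060].

The sampling unit is configurable. Amplitude and time metrics default to
cell-level testing: published p-values at or below 10⁻⁴ are unreachable by
a rank test on three replicates per group, so cells are the only reading
consistent with the reported statistics, and the unit is surfaced in the
report metadata rather than asserted silently. Percent-doubling is
summarized and tested at replicate level (replicates = line × run), where a
fraction is the natural observation. SEMs follow the same units
(`AnalysisConfig(amplitudeSemUnit=, fractionSemUnit=)`); a single replicate
leaves a replicate-level SEM undefined and is reported as `NA` with a
warning. No multiple-testing correction is applied by default, matching the
per-comparison reporting it reproduces; `adjustComparisons()` adds BH
q-values for reuse.

## The synthetic generator

No raw recordings are public, so validation is parameter recovery: encode
each published condition as generative parameters, simulate, run the full
pipeline, and check the published statistics come back. The shipped presets
(`studyPresets()`, from `inst/extdata/presets/study_conditions.yaml`) carry
one entry per (stage, stimulus, group).

**Waveform.** The study reports peaks and times-to-peak but no functional
form, so a cell's noise-free fold profile is built from alpha-function
pulses, chosen because peak amplitude and peak time are independent,
interpretable parameters: $g(\tau) = (\tau/\tau_p)\,e^{1 - \tau/\tau_p}$
rises to 1 at $\tau_p$. After the peak the pulse relaxes along the rescaled
alpha tail so that it reaches the partial plateau $1 + 0.35\,(A - 1)$
exactly at the window end; without that rescaling a slow cell (large
$\tau_p$) would carry most of its receptor response into the ionomycin
window and corrupt the ionomycin maximum. The ionomycin pulse rises from
the receptor plateau to its own drawn peak, and the EGTA phase decays
exponentially toward baseline with a 30 s time constant. Raw counts are
`background + f0 * fold * exp(-bleachRate * t) + N(0, noiseSd)`, clipped at
zero.

**Grid snapping.** Per-cell times-to-peak are snapped to the frame grid
before rendering, so each drawn amplitude is realized exactly at a sampled
frame. An off-grid alpha peak is never sampled, which would make exact
amplitude closure impossible; with snapping, the noise-free
generate→extract loop recovers drawn amplitudes to $10^{-6}$ and times to
within one frame (tested), and extracted maxima increase strictly with the
drawn amplitude.

**Mixtures.** Conditions reporting both a grand mean and a doubling
percentage are two-component mixtures: non-responders at
Normal(1.3, 0.15) fold truncated to [1, 2), responders at the mean solved in
closed form by `calibrateMixture()` so the mixture mean equals the published
grand mean exactly (identity tested to $10^{-12}$). Means inconsistent with
the reported fraction at the fixed non-responder mean raise an
infeasible-preset error rather than generating silently. Published "± x"
values are treated as SEMs over pooled cells at unstated n, which cannot fix
the cell-level variance; per-cell spreads therefore default to SD 0.6 fold
for amplitudes and 30% of the mean for times-to-peak, values typical of
single-cell Fluo-4 work, and recovery targets are means, not spreads.

**What is emulated, and what is not.** The generator reproduces per-cell
amplitude heterogeneity, responder/non-responder structure, timing spread,
shared optics (baseline 1000 counts, 1% additive noise, 50-count background,
optional photobleaching — default off, since no bleach correction is
modeled), and the line/replicate layout (2 lines × 3 replicates per group;
cell counts per replicate are not published and default to 50, large enough
for CLT-based tolerances while keeping every validation run in seconds). It
does not model spontaneous transients or oscillations, mechanistic calcium
handling, spatial structure within cells, motion, or correlated noise —
so green validation tests certify the *pipeline arithmetic* under the
assumed statistical structure, not robustness to every pathology of real
microscopy data. Two unpublished quantities (the 1-week KCl ionomycin
response and the iPSC-stage ionomycin time-to-peak) were fixed once at
values typical of the neighbouring conditions (2.85 fold / 40 s, and 50 s);
they are not recovery targets.

**Degenerate inputs.** Backgrounds at or above the whole trace, non-positive
F0, peaks placed beyond their window, empty response windows, empty
cohorts, and all-tied samples all raise typed errors (or, for the tied
Mann–Whitney case, return U = n₁n₂/2 and p = 1 with a warning) rather than
propagating NaNs.

## Stage screen

The transcriptomic screen consumes an externally produced DEG table
(gene, stage, log2FC, Q) over the four differentiation stages (iPSC, NI,
NSP, Diff) — the differential-expression model itself is out of scope — and
(1) tallies significant DEGs per stage at Q ≤ 0.05, splitting by sign
(log2FC = 0 at significance counts in neither direction, with a warning);
(2) tests calcium-annotation over-representation with the upper-tail
hypergeometric probability `phyper(k-1, K, N-K, n, lower.tail = FALSE)`,
verified against exact binomial-coefficient sums for N ≤ 30 and against
Monte-Carlo draws; (3) adjusts across stages with Benjamini–Hochberg; and
(4) ranks stages by annotated-DEG count, breaking ties by smaller p and
then by stage name. The universe defaults to all genes in the table, since
the original background is unstated; the annotation set is user-supplied
(the bundled list is a synthetic demo, not a licensed GO/KEGG export), and
only one-sided over-representation is tested.

## Problem sizes and tolerances

Validation runs use 300 cells per cohort (600 for the mixture-fraction
check), 10⁴ cells for Monte-Carlo responder-fraction checks, 10⁴ null
simulations for test calibration, and 100 seeded null runs for the
false-positive sweep of `compareConditions()`; the full suite completes in
well under a minute per file on one CPU. Recovery tolerances are
max(5% of the published value, 2 × its published SEM) — the published
sampling noise itself — and ±3 percentage points for the replicate-level
doubling fraction.

## Known limitations

* The waveform is phenomenological; kinetic parameters recovered from real
  data should be interpreted through the extraction definitions, not as
  biophysical constants.
* Time-to-max on noisy plateaus has frame-level jitter: with a slow, flat
  peak the argmax wanders among near-maximal frames, which mildly widens
  (and for asymmetric decays, slightly shifts) recovered time-to-peak
  distributions.
* The Mann–Whitney implementation does not replicate any specific vendor
  tool's exact-with-ties behaviour bit-for-bit; midranks with tie-corrected
  normal approximation are used instead.
* ROI extraction averages mask pixels per frame; there is no motion
  correction, segmentation, or dual-dye ratioing.
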
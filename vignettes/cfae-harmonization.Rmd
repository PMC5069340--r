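---
title: "Methods: CFAE detection, synthetic electrograms, and threshold revision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CFAE detection, synthetic electrograms, and threshold revision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfaer)
```

## The problem

Two commercial electroanatomical mapping systems classify complex
fractionated atrial electrograms (CFAEs) with different algorithms: one
quantifies the mean interval between detected negative deflections
(CFE-Mean, with CFE-SD as a complementary index), the other counts
"complex intervals" between voltage extrema confined to a narrow amplitude
window (ICL, with ACI and SCI as complementary indices). Applied to the
same bipolar atrial electrogram (AEG), the two default rules frequently
disagree. This package implements both detectors from their published
descriptions, and the resampling pipeline that revises each system's
cutoffs using the *other* system's classification as the reference, so the
two rule sets classify concordantly.

Because the clinical recordings behind the original analysis are
proprietary exports, the package ships a synthetic AEG generator with
planted ground truth; every pipeline stage is exercised and tested against
it.

## Detector models and their interpretation choices

### Negative-deflection detector (CFE-Mean / CFE-SD)

The published criteria say *what* qualifies a deflection, not *how* to
locate one. The operator used here:

- A candidate is a local minimum of the first difference — the instant of
  steepest negative slope (−dV/dt). Window-edge slopes count as candidates
  so a deflection clipped at the boundary is still markable.
- The surrounding deflection is delimited by the nearest preceding local
  maximum and nearest following local minimum of the voltage (window edges
  as fallback). Peak-to-peak amplitude is their difference; duration their
  separation.
- Criteria: amplitude ≥ `pp_sensitivity_mv` (default 0.05 mV, the
  operator's stand-in for baseline noise; an optional adaptive mode takes
  `max(threshold, k × MAD)`), duration < `max_deflection_ms` (default
  10 ms, rejecting broad ventricular far-field deflections), and a greedy
  chronological refractory of `refractory_ms` (default 30 ms): the earliest
  qualifying deflection always wins, as an online device would behave.
- The mark time is the steepest-slope instant. The published description
  measures FI "between consecutive negative deflections" without fixing an
  anchor point; anchoring at the slope extremum makes interval statistics
  insensitive to the (constant) offset between slope extremum and trough.

CFE-Mean is the arithmetic mean of the fractionated intervals (successive
mark-time differences), CFE-SD their *sample* standard deviation (n−1; the
source description does not specify the denominator; 0 when there is
exactly one interval). With fewer than two marks both are undefined and the
AEG classifies non-CFAE. Classification bounds (default 30–120 ms) are
inclusive at both ends.

### Complex-interval detector (ICL / ACI / SCI)

- An extremum qualifies when its **absolute deviation from the zero
  baseline** lies inside the voltage window (default 0.05–0.15 mV,
  inclusive). Band-passed bipolar AEGs have mean ≈ 0, which makes this the
  natural reading of "exceed a lower voltage threshold"; an optional
  `peak_to_peak` mode measures each extremum against the preceding opposite
  extremum instead. The default is asserted throughout the tests.
- Successive qualifying extrema bound a complex interval when their
  separation lies in the interval window (default 50–110 ms, inclusive).
  Extrema need not alternate polarity, intervals chain (shared endpoints),
  and there is no refractory — none is described for this system.
- ICL = interval count; ACI / SCI = mean / minimum duration over the
  *qualifying* intervals only (undefined at ICL = 0). Band labels use the
  conventional cutpoints (<4 low, 4–6 moderate, ≥7 high). ICL
  classification is refused for windows other than 2.5 s unless explicitly
  overridden, since no validated threshold exists for longer windows.

## The revision pipeline

1. A cohort of 797 AEGs is split 30 times into 679 training / 118
   validation members, uniformly without replacement; per-iteration seeds
   derive from one master seed. (The source material states both 697 and
   679 for the training size; 679 + 118 = 797 is internally consistent, so
   679 is the default and both sizes are plain config values.)
2. On each training set: ROC of ICL scores against the NavX default
   classification (high-is-positive), and ROC of CFE-Mean scores against
   the CARTO default classification (low-is-positive). Thresholds sit at
   midpoints between consecutive distinct scores plus ±∞ sentinels, so
   every achievable confusion matrix is a curve point and integer ICL gives
   stepped curves. The revised cutoff is the point minimising the distance
   to (0, 1); ties break toward higher sensitivity (missing CFAE is the
   costlier clinical error), then higher specificity, then threshold order.
3. Complementary indices are calibrated the same way against the label
   "both revised primary rules agree the AEG is CFAE" (all
   low-is-positive).
4. Validation applies the default rules and the combined revised rules
   (NavX: CFE-Mean ∧ CFE-SD; CARTO: ICL ∧ ACI ∧ SCI, conjunctive, undefined
   index ⇒ non-CFAE) to the 118 held-out AEGs and reports proportions and
   Cohen's κ per iteration; any overlap between a validation and training
   set is a hard error, asserted structurally.

Undefined indices get worst-case surrogate scores for ranking — the window
length in ms (2500 at 2.5 s) for CFE-Mean, CFE-SD, ACI and SCI. For
interval statistics bounded above by the interval window (≤ 110 ms) this is
an infinity-equivalent; it keeps ROC input total without a separate missing
category.

Iterations whose reference labels collapse to a single class are excluded
from the summaries with a warning and reported in the study object. The
revised ICL cutoff is real-valued (a mean of midpoint thresholds, e.g.
between 3 and 4 → 3.5); with integer ICL a cutoff of 3.5 classifies as
≥ 4. On synthetic cohorts where the low-ICL archetype still shows
occasional intervals the optimum can fall below 1 (e.g. 0.5 ⇒ ≥ 1); the
pipeline reports whatever the ROC optimum is rather than clamping it.
The across-iteration κ comparison uses a paired Wilcoxon test (the original
analysis does not name its test); κ is reported on the validation subsets,
with the full-cohort default κ reported separately.

## The synthetic generator

Activations follow a renewal process: complex onsets start at 0 with
truncated-normal intervals (floored at the width of one whole complex so
complexes never overlap; draws below the floor are redrawn). An optional
two-component mixture interleaves long gaps (`p_long`, `long_gap_ms`) to
model bursty activity. Each deflection is a biphasic wavelet — difference
of two Gaussians, positive lobe leading, lobe separation width/2, lobe SD
width/6, normalised to the drawn peak-to-peak amplitude on the sample grid.
The `neg_fraction` parameter (default 0.7) sets the share of the
peak-to-peak carried by the negative lobe, as bipolar AEG deflections are
predominantly negative-going; it also determines *which* lobes fall inside
the 0.05–0.15 mV voltage window, and the archetypes below rely on that.
Gaussian noise is band-limited to 30–300 Hz and scaled to `noise_rms_mv`
*before* being added, so the rendered deflection amplitudes stay exact and
zero-noise signals close the loop with the detectors sample-accurately.

Four archetypes (all 2.5 s, 1.2 kHz, noise 0.01 mV RMS) populate the
agreement quadrants; the published amplitude/interval distributions do not
exist, so these are engineering choices, fixed once:

| archetype | intervals (ms) | structure | p-p amplitude (mV) | intent |
|---|---|---|---|---|
| concordant CFAE | 70 ± 10 | doublets 15 ms apart | 0.12 ± 0.015 | CFE-Mean ≈ 70; negative lobes (≈ 0.084 mV) in-window ⇒ high ICL |
| concordant organized | 180 ± 20 | single | 0.32 ± 0.04, neg. lobe 85 % | CFE-Mean > 120; both lobes outside the window ⇒ ICL 0 |
| NavX-only | 112 ± 12 | single | 0.30 ± 0.04, neg. lobe 85 % | CFE-Mean < 120 but amplitudes straddle the window top ⇒ ICL < 4 |
| CARTO-only | 70 ± 8 with 25 % gaps 500 ± 50 | single | 0.12 ± 0.015 | in-window bursts ⇒ ICL ≥ 7, gap-dominated mean ⇒ CFE-Mean > 120 |

Default mixture weights follow the observed quadrant occupancy
(273 : 230 : 282 : 12 of 797), with the CARTO-only pattern deliberately
rare. All per-AEG seeds derive from the cohort master seed, so cohorts are
reproducible item-by-item.

What the generator does **not** emulate: wavefront propagation and
collision, ventricular far-field deflections, non-stationary rhythm
changes within a window, electrode contact artefacts, and the true (heavier
tailed, patient-clustered) clinical amplitude/interval distributions.
Passing tests therefore demonstrate correctness of the algorithms and the
pipeline machinery and the *direction* of the concordance improvement — not
that clinical data would reproduce any particular revised cutoff. The
original cutoffs (CFE-Mean ≤ 84.1 ms, ICL ≥ 3.8, …) are not reproducible
without the clinical recordings, and the package does not attempt to tune
toward them; on the cleanly separable synthetic archetypes the revised
rules agree far more strongly than clinical data would allow.

## Numerical choices

- **Filters.** Preprocessing is optional (clinical signals arrive already
  band-passed; the generator emits band-limited signals by construction).
  The band-pass is a zero-phase (forward–backward) Butterworth, order 4,
  30–300 Hz — zero-phase so deflection times are not shifted. The 50 Hz
  notch is a second-order IIR biquad with quality factor 30, applied
  zero-phase, and is never applied automatically: the acquisition-time rule
  ("when signal-to-noise required it") has no published criterion, so the
  notch is an explicit user decision. Both filters use odd-reflection edge
  padding (250 ms) so start-up transients decay outside the signal.
- **Conventions.** Times in ms from window start; sample indices 0-based;
  segments half-open [start, end); a slope mark sits at the midpoint of its
  sample pair. Plateau extrema are represented by their first sample.
- **Degenerate inputs.** < 2 marks ⇒ undefined NavX indices, non-CFAE,
  surrogate score; ICL 0 ⇒ undefined ACI/SCI; single-class ROC labels ⇒
  error (excluded iteration); κ ≡ 0 when chance agreement is 1; constant
  vectors are an error for Spearman.
- **Statistics.** The Friedman statistic uses the tie-corrected rank form
  (the base-R implementation, tie-free, is the cross-check in the tests);
  Dunn's follow-up uses mean-rank z-tests with Bonferroni scaling over all
  k(k−1)/2 pairs, as "Dunn's correction" is not further specified.
  Mann–Whitney uses exact enumeration for tie-free samples up to n = 20 and
  the tie-corrected normal approximation otherwise. AUROC is trapezoidal
  and equals the rank statistic exactly; both implementations exist and the
  tests compare them to 1e-12.

## Problem sizes

The shipped analyses and tests use the cohort sizes the design prescribes:
797 AEGs with 30 × (679/118) splits for the study and the
parameter-recovery checks, 20 replicate studies for the concordance
improvement property, 200 seeded 0.5 s signals for brute-force detector
equivalence, and a 60-AEG 8 s cohort for the window sweep. A full study
runs in a few seconds on one core.

## Known limitations

- The detectors follow the *published descriptions* of the commercial
  algorithms; proprietary firmware details (display averaging,
  multi-channel gating) are out of scope, as are 3-D geometry, anatomical
  regions, and map rendering.
- Surrogate scoring of undefined indices is a ranking device, not an
  estimate; output tables flag definedness separately.
- The FI anchor point and the amplitude-criterion baseline are documented
  interpretation choices; alternative readings (onset anchoring,
  peak-to-peak qualification) would shift indices by small systematic
  amounts. The peak-to-peak mode is available for sensitivity analyses.
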
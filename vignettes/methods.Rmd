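---
title: "Validating stroke-volume monitors: agreement, trending and error-grid methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating stroke-volume monitors: agreement, trending and error-grid methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svagree)
```

## The problem

Early haemorrhage is hard to detect from blood pressure alone; stroke volume
(SV) falls earlier and more reliably. Non-invasive SV monitors — thoracic
electrical bioimpedance (TEB), suprasternal Doppler (SSD) — are candidates
for this role, but before they can guide transfusion decisions their
readings must be compared against a reference standard (trans-thoracic
echocardiography, TTE) over a clinically relevant range of hypovolaemia.
Lower body negative pressure (LBNP) produces that range safely in healthy
volunteers: stepped suction pools blood in the pelvis and legs, lowering
venous return and hence SV, and releasing the suction restores it.

`svagree` implements the full statistical chain for such a validation study:

1. **absolute agreement** — Bland-Altman analysis adapted for repeated
   measurements per subject, with percentage error;
2. **trend agreement** — percent changes from baseline compared on a
   four-quadrant plot with a central exclusion zone, plus Pearson
   correlation;
3. **clinical relevance** — an error grid built from expert opinion that
   classifies each measurement error by its potential for patient harm;
4. **synthetic data** — an LBNP cohort simulator and an expert-questionnaire
   simulator so that the whole chain is testable without volunteer data.

## The cohort simulator

`simulate_cohort()` is phenomenological: it makes no attempt to model
baroreflexes, heart rate or blood pressure, only the SV trajectory the
protocol is designed to impose and the error structure of the instruments.

Per subject $i$ with baseline $b_i \sim N(\mu_b, \sigma_b)$, at protocol
step $s$ with fractional target $t_s$:

$$\mathrm{SV}^{true}_{is} = b_i\, t_s\,(1 + \varepsilon_{is}), \quad
  \varepsilon_{is} \sim N(0, \mathrm{cv}_{step})$$

$$\mathrm{SV}^{ref}_{is} = \mathrm{SV}^{true}_{is}(1 + \eta_{is}), \quad
  \eta_{is} \sim N(0, \mathrm{cv}_{ref})$$

$$\mathrm{SV}^{dev}_{is} = \alpha\, \mathrm{SV}^{true}_{is}(1 + \nu_{is})
  + \beta + e_{is}, \quad \nu_{is} \sim N(0, \mathrm{cv}_{dev}),\;
  e_{is} \sim N(0, \sigma_{dev})$$

All readings are truncated below at 1 ml so that downstream percent-change
arithmetic stays defined.

Defaults and why:

* **Step targets** `c(1.00, 0.92, 0.85, 0.80, 0.675, 0.595, 1.00)`. The
  protocol fixes two initial suction levels (−10 and −20 mmHg) and then
  titrates to SV targets of 80%, 65–70% and 55–64% of baseline, ending in
  recovery. The titrated bands are represented by their midpoints (0.675,
  0.595); `band_draw = TRUE` draws uniformly within the band instead. No SV
  fraction is defined by the protocol for the two fixed-pressure steps, so
  0.92 and 0.85 are package defaults chosen to continue the graded monotone
  fall; both are configurable.
* **Baseline** 100 ± 15 ml: a typical supine healthy-adult LVOT-derived SV
  with realistic between-subject spread.
* **`within_step_cv` = 0.05**: titration to a target SV is imprecise at
  roughly this level.
* **`ref_cv` = 0.10**: echocardiographic VTi-based SV has inter-measurement
  variability of about 10%. This matters more than it looks: in a
  Bland-Altman difference-vs-mean regression, *whichever* instrument is
  noisier drags the slope away from zero even without true proportional
  bias, so the ratio of device to reference noise controls the false-alarm
  rate of the proportional-bias test.
* **Device models**. The TEB-like default (`device_teb()`: gain 0.5, offset
  5 ml, additive SD 6 ml, proportional SD 0.05) reads roughly half the true
  SV, so its bias grows strongly with SV — the signature that makes limits
  of agreement meaningless for it — while its *percent changes* track the
  truth well, because a pure gain cancels in ratios. The SSD-like default
  (`device_ssd()`: gain 1, offset 0, proportional SD 0.10, additive SD
  4 ml) is unbiased but wide. Its error is deliberately split into a
  dominant proportional part and a small additive part: with mostly
  proportional noise of the same order as the reference noise, the
  difference-vs-mean slope stays near zero, as it should for a device with
  no systematic gain error. (A large purely additive error of the same
  total magnitude would produce a spurious positive slope — a regression
  artefact, not a property of the device being emulated.) These settings
  reproduce the qualitative published pattern — large negative
  SV-dependent TEB bias; near-zero SSD bias with percentage error around
  the 30% acceptability limit; trend correlation around 0.6–0.7 and
  concordance near 90% — they are not fitted values, as no raw study data
  are available.
* **Strands**. Tourniquet and non-tourniquet sessions are simulated
  identically apart from the strand label and separate random draws,
  because the study arms behaved near-identically.
* Noise is independent across steps within a subject; the within-subject
  correlation of instrument error is unknown and not modelled.

Device noise streams are seeded per device name, so adding or removing a
device never changes another device's simulated readings.

## Repeated-measures Bland-Altman

Each subject contributes several reference/device pairs over a *range* of
induced stroke volumes, so the plain SD of all differences is not a valid
basis for limits of agreement. `bland_altman_repeated()` implements the
multiple-observations-per-individual method for a varying measurand: a
one-way variance-component decomposition of the differences by subject,

$$\widehat{\sigma}^2_d = \mathrm{MSW} +
  \max\!\left(0, \frac{\mathrm{MSB} - \mathrm{MSW}}{n_0}\right), \qquad
  n_0 = \frac{N^2 - \sum_i n_i^2}{N\,(k-1)},$$

with limits of agreement at $\bar d \pm 1.96\,\widehat{\sigma}_d$ and
percentage error $100 \times 1.96\,\widehat{\sigma}_d / \overline{SV}_{ref}$
(30% is the conventional acceptability limit). When every subject has one
pair the estimator reduces exactly to the plain SD, and `pooled_naive` is
available as an explicit alternative. The grand mean of the reference
readings, with equal weight per pair, is used as the denominator.

Proportional bias is assessed by the least-squares slope of differences on
pair means; `suppress_loa_if_proportional()` marks the limits and the
percentage error not-reportable when the slope's two-sided p-value falls
below 0.05 (configurable). The original analysis made the equivalent call
by inspection; a p-value threshold makes it reproducible.

Degenerate inputs: a constant mean (no SV range) leaves the slope
undefined (`NA`, never suppressed); identical readings give slope 0 with an
undefined p-value; a lone subject falls back to the pooled estimator with a
structured warning code.

## Four-quadrant trend analysis

`compute_deltas()` computes percent changes against each signal's *own*
baseline (the baseline-step reading), which is why a miscalibrated but
linear device can trend well. `four_quadrant()` excludes pairs in a central
square (default half-width 15%, the convention for SV trend analysis;
`"or"` and reference-only exclusion variants are provided because the
literature varies), counts a pair concordant when both deltas share a
strict sign, and removes zero-direction pairs outside the square from the
denominator, since sign agreement is undefined at zero. Pearson r is
reported over all pairs without exclusion, since correlation and
concordance answer different questions.

## The expert-opinion error grid

The error grid asks a different question from Bland-Altman: *how much would
this particular measurement error matter to the patient?* Its construction:

1. Experts state the percent fall in SV at which action is *indicated* and
   at which it is *essential*, then rate the potential harm of every
   (actual fall, measured fall) combination on a 0–60% grid as
   None / Mild / Moderate / Severe.
2. Ratings are weighted None 0, Mild 2, Moderate 5, Severe 10 and **summed**
   across respondents per cell (`build_harm_grid()`), giving 0 to
   $10 \times n$ (150 for 15 respondents), also expressed as a percentage.
3. Cells are banded by thresholding the percentage score and merged into
   rectilinear risk-zone polygons (`derive_zones()`). The default
   thresholds (13.3, 35, 75) place the band edges below a uniformly-Mild
   panel score (13.3%), midway between uniformly-Mild and uniformly-Moderate
   (35%), and at a Severe-dominant score (75%): a consensus panel therefore
   maps each pure rating back to its own band. The original grid was drawn
   by eye over a colour gradient, so *any* programmatic banding is a
   design decision; thresholds are exposed, and hand-drawn polygons can be
   loaded from JSON (`read_zones_json()`) instead.
4. `classify_points()` converts delta pairs to reduction coordinates
   (actual on x, measured on y), clamps out-of-domain points to the domain
   edge (they represent real measurements and must be counted), and assigns
   zones by point-in-polygon test, testing severe first so that boundary
   points take the **higher-harm** zone — the clinically conservative
   tie-break.
5. `zone_summary()` reports counts, integer-rounded percentages, and the
   one-decimal combined severe-harm rate across two pooled strands,
   matching the display conventions of published error-grid results.

The grid is intentionally not symmetric: under-reading a fall that demands
essential action (treatment withheld) is rated Moderate even where the
mirror-image over-read (unnecessary treatment) is Mild.

The questionnaire simulator generates each respondent's ratings
deterministically from their two thresholds via this category-mismatch
rule — same action category: None; one category apart: Mild, except
Moderate when an essential-action fall is under-read; two apart: Severe —
and then applies ±1-category jitter with a configurable probability
(default 0.05 in the pipeline, representing mild inter-rater
inconsistency). Diagonal cells are always None.

One display convention worth noting: because rectilinear zones tile the
plane, a point falling *exactly* on a cell corner (e.g. an exact 15%
reduction on the identity line, between 10%- and 20%-cells) touches the
neighbouring off-diagonal cells, and the conservative tie-break will label
it with their band if they are harmful. This is the tie-break working as
specified; with smoothed hand-drawn zones the diagonal corridor is strictly
interior to the no-risk zone and the case does not arise.

## Pipeline and numerical choices

`run_pipeline()` chains the stages per device × strand, isolates failures
per combination, and writes deterministic CSV/JSON outputs (no timestamps),
so identical configurations reproduce byte-identical files. All stage seeds
derive from the single master seed; keep it below $2^{31}$.

Problem sizes used in the test-suite simulations mirror the study design —
21 subjects × 7 steps × 2 strands — with 200-replicate Monte-Carlo loops
for parameter-recovery checks and 1000 random instances for the
brute-force concordance oracle.

## What passing tests do and do not show

The simulator reproduces the *statistical shape* of an LBNP validation
study: graded targeted SV reduction, instrument noise of realistic
magnitude, and device error structures chosen to span the two qualitative
regimes (proportional miscalibration vs unbiased imprecision). It does not
reproduce physiological dynamics (baroreflex compensation, pre-syncope,
heart-rate or blood-pressure trajectories), inter-step correlation of
device error, operator-dependent signal-quality failures, or the exact
numerical results of any particular volunteer cohort. Passing tests
therefore demonstrate that the *analysis chain* is correct and
reproducible, not that any specific device is safe; published empirical
values (biases, percentage errors, concordance rates) are checked for sign
and order of magnitude only, because the underlying raw measurements are
not public.
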
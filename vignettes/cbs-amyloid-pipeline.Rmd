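---
title: "Predicting amyloid status in corticobasal syndrome: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting amyloid status in corticobasal syndrome: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbspredict)
```

## The problem

Corticobasal syndrome (CBS) is defined clinically, but its underlying
pathology is heterogeneous: frontotemporal lobar degeneration (FTLD)
tauopathies such as corticobasal degeneration and progressive supranuclear
palsy dominate, while roughly a quarter of patients have Alzheimer's disease
(AD). Amyloid PET with Pittsburgh compound B (PIB) is the accepted in vivo
surrogate for AD pathology, but it is not widely accessible. The pipeline in
this package operationalizes the question: how well do bedside and
routinely-available measures — structured clinical criteria, and the
regional pattern of FDG-PET hypometabolism — predict a patient's PIB
status?

Group-level studies show that CBS-AD patients tend toward
temporoparietal-predominant degeneration with memory/visuospatial-weighted
cognitive deficits, whereas CBS-FTLD patients show frontal-predominant
changes with executive, behavioural and motor-speech deficits. The pipeline
turns that contrast into per-patient classifiers and scores each one
against amyloid status.

## The clinical rule engine

`check_core()` implements the core screen: a progressive course, at least
three of five core features (parkinsonism, dystonia, myoclonus, impaired
voluntary limb control, cortical sensory deficit), and the absence of all
six exclusion features (visual hallucinations, REM-sleep behaviour
disorder, cerebellar ataxia, prominent autonomic dysfunction, fluctuating
alertness, prominent rest tremor). Each criterion is a chart-coded boolean;
a record missing any field is rejected rather than imputed, because a
silent default would change a patient's eligibility invisibly.

`evaluate_variants()` counts the frontal-variant features (non-fluent or
motor speech deficit; apathy/disinhibition/loss of empathy; lower-extremity
apraxia; executive dysfunction greater than memory/visuospatial impairment)
and temporoparietal-variant features (logopenic aphasia; Gerstmann or
Balint elements; memory/visuospatial impairment greater than executive
dysfunction). Meeting a variant requires at least one of its features. The
two cognitive-profile criteria are mutually exclusive by construction —
both cannot be "greater than" the other — and conflicting input is a hard
error at load time.

### Adjudicating both-variant patients

In practice many core-eligible patients meet features of both variants, and
the original chart-review procedure resolved them by the rater's overall
impression — which cannot be reproduced deterministically. `adjudicate()`
replaces it with a fixed precedence:

1. **single_variant** — only one variant met: no ambiguity.
2. **cognitive_dominance** — both met and exactly one cognitive-profile
   criterion present: follow it. This criterion is given priority because
   the relative pattern of cognitive impairment (executive-worse predicting
   non-AD, memory/visuospatial-worse predicting AD) is the one individual
   criterion with demonstrated predictive value for amyloid status.
3. **count_majority** — both met, neither cognitive criterion: the variant
   with more features present.
4. **default** — still tied: frontal variant at equivocal confidence,
   because non-AD pathology is the prior majority (~75%) in CBS.

Confidence is mapped deterministically onto the conventional 5-point scale
(1 = highest-confidence fvCBS … 5 = highest-confidence tpvCBS):
single_variant → 1/5, cognitive_dominance and count_majority → 2/4,
default → 3. This preserves two invariants the scale implies: an FV call
always has confidence ≤ 3 and a TPV call ≥ 3.

The engine is deterministic and total: the test suite enumerates every
variant-feature combination exhaustively, checks it against an
independently written restatement of the rule table, and verifies
monotonicity (adding a supporting feature never flips an established
label).

## Quantitative PET measures

**SUVR.** Regional FDG uptake is normalized to mean pons activity
(`compute_suvr()`), the standard reference for FDG in neurodegeneration
because the pons is relatively spared.

**Z-scores.** Each patient ROI SUVR is expressed in control standard
deviation units (`compute_z()`); hypometabolism is negative. ROIs are
frontal, temporoparietal and "common" (peri-rolandic regions affected
across CBS variants), each left/right and as the bilateral (hemispheric
mean) composite. Scoring the control cohort against its own sample
statistics returns mean 0, SD 1 per ROI — a self-normalization identity the
tests assert to numerical tolerance.

**Classification.** `classify_fdg_quant()` labels a patient by the lowest
bilateral Z: temporoparietal-variant if the temporoparietal Z is below the
frontal Z, frontal-variant otherwise. Two design choices are deliberate:

* only the bilateral frontal and temporoparietal composites enter the
  decision — the "common" ROI is by definition shared across variants and
  carries no discriminative signal, and hemisphere-specific comparison
  conventions were left unstated in the source material;
* an exact tie goes to FV, mirroring the rule engine's default. Ties have
  measure zero on continuous data; the rule exists so the classifier is
  total.

The Z-difference `z_frontal − z_temporoparietal` is reported alongside
(positive = temporoparietal-predominant hypometabolism). Classification is
invariant to any common rescaling of uptakes and control statistics, since
SUVR units cancel in the Z-scores; a property test asserts this.

**Lateralization index.** Implemented as `|right/left − 1| × 100`. The
formula as conventionally printed ("abs((right/left)) − 1 × 100") is
ambiguous about parenthesization and would yield negative values whenever
the right side is smaller; taking the absolute value of the ratio-minus-one
keeps the index non-negative, consistent with strictly positive published
group values. The orientation matters: `LI(r, l) ≠ LI(l, r)` in general
(10 vs ≈9.09 for a 1.1:1 ratio), and the test suite asserts the asymmetry
rather than hiding it.

## Logan graphical DVR

`logan_dvr()` estimates the distribution volume ratio of a reversible
tracer from a target and a reference-tissue time–activity curve by
ordinary least squares on the Logan transform: the slope of
`∫₀ᵀ C_t dt / C_t(T)` against `∫₀ᵀ C_ref dt / C_t(T)` over late frames.
Numerical choices:

* cumulative trapezoidal integration from time zero with an implicit (0, 0)
  point before the first frame (activity is zero before injection);
* fit window `t* = 35` min by default, overridable — late enough for the
  transform to be linear for PIB-like kinetics within a 90-min scan;
* the pure reference-ratio form with no k2′ correction term; the source
  procedure cites reference-tissue Logan analysis without k2′ details, and
  for the validation model below the transform is exactly linear without
  one;
* at least three fit frames are required, and non-positive target activity
  in the fit window is an error rather than a silent drop.

### Validation model

`generate_tac_pair()` builds a reference curve as a bi-exponential decay
(fast delivery component plus slow washout: amplitudes 6 and 3, rate
constants 0.25 and 0.012 min⁻¹) and a target as the exact solution of a
one-tissue compartment model driven by the reference,
`dC_t/dt = DVR·k₂·C_ref − k₂·C_t` with `k₂ = 0.15 min⁻¹`. For this model
the Logan plot is exactly linear with slope DVR and intercept `−1/k₂`, so
recovery error isolates the integration and windowing error of the
implementation. Frames use a quadratically spaced 30-frame, 90-min grid
(finer early frames, as in dynamic PET protocols). Tests check recovery
within 2% at DVR ∈ {1.0, 1.5, 2.0, 2.5} noise-free, cross-check the
generated curve against an independent `deSolve` ODE integration, and check
unbiasedness over 100 noisy replicates at an additive noise SD of 0.09
(about 1% of peak activity — realistic for large-ROI TACs, where Logan's
noise-induced negative bias is negligible).

A global PIB DVR is dichotomized by `classify_pib_quant()` at the
conventional threshold 1.20, inclusive at the boundary.

## Diagnostic performance statistics

`build_contingency()` cross-tabulates named, aligned binary calls (positive
prediction = temporoparietal-variant or marker present; reference positive
= PIB+); id mismatches are errors listing the offending patients, and
patients missing a modality must be dropped pairwise upstream
(`run_report()` does this and logs every drop — per-modality totals then
drift exactly as real cohorts do).

For proportions, the default 95% interval is **Clopper–Pearson exact**,
computed by the beta-quantile form. The choice matters at the denominators
involved here (10–14 patients per group): the exact interval is
conservative but never undercovers, whereas the Wald interval collapses
badly near 0 and 1. Wald is available behind `ci_method = "wald"` for
comparison. A statistic whose denominator is empty is returned as
undefined (`NA`), never as zero. Coverage of the exact interval is verified
empirically in the tests over n ∈ {10, 25, 50}, p ∈ {0.1, …, 0.9} with
2000 replicates per cell.

Odds ratios use the sample cross-product with a Woolf log-normal interval
and the Haldane–Anscombe +0.5 correction when any cell is zero (flagged,
and guaranteeing finiteness). Fisher's exact test uses the conditional
hypergeometric distribution with the probability-mass two-sided convention
— the sum of probabilities of all tables no more probable than the one
observed — stated explicitly because several two-sided conventions exist;
the tests verify it against an exhaustive enumeration for every 2×2 table
with total ≤ 30. The chi-square test is the uncorrected Pearson statistic
on 1 df, undefined on a zero margin. Cohen's kappa follows the standard
`(p_o − p_e)/(1 − p_e)` definition and is cross-checked against an
independent implementation.

Report-time rounding follows the conventions of the field's tables:
half-up to whole percents for sensitivity/specificity, two decimals for
accuracy and kappa (`round_half_up()`; base R rounds half to even). All
statistics are carried at full precision internally.

## The synthetic cohort generator

`cohort_spec()` defaults encode the reference study conditions: 11
amyloid-positive patients, 14 amyloid-negative, 26 controls, and the
published group means ± SDs of the bilateral ROI Z-scores (PIB+: frontal
−1.26 ± 0.91, temporoparietal −2.76 ± 1.65, common −1.89 ± 0.81; PIB−:
frontal −1.06 ± 1.61, temporoparietal −0.93 ± 1.65, common −1.69 ± 1.37)
and lateralization indices. Generation works backwards from how the data
are summarized: patient Z-scores are drawn directly in control-SD units and
inverted to uptakes through the *generated* control sample statistics, so
that re-deriving Z against the generated control reference returns exactly
the drawn values (a round-trip the tests assert). This avoids committing to
an unobserved raw-SUVR scale; the control base (SUVR ≈ 1.4–1.5 ± 0.12 per
ROI over a pons of 1.0 ± 0.05, arbitrary units) only anchors positivity of
uptakes.

Choices a user should know about:

* **ROI independence.** Z draws are independent across ROIs; between-ROI
  correlations are not published, and any covariance structure would be a
  modelling invention. This makes closed-form predictions possible (below)
  but understates the spatial smoothness of real hypometabolism.
* **Clinical prevalences are not published.** The per-criterion prevalence
  defaults are package choices, documented as such: the
  memory/visuospatial-worse criterion is enriched in the amyloid-positive
  group (0.60 vs 0.15) and the executive-worse criterion in the
  amyloid-negative group (0.60 vs 0.15), so the engine's discriminative
  pathway is exercised. A patient drawn with no variant feature at all is
  given the group-typical cognitive criterion, keeping every synthetic
  patient classifiable — real cohorts can contain unclassifiable patients.
* **Asymmetry** is injected by splitting each bilateral uptake into
  hemispheres at the drawn lateralization magnitude, with the hypometabolic
  side chosen at random; when the right side is the lower one, the realized
  `|R/L − 1|` index is slightly below the drawn magnitude (the formula's
  orientation asymmetry again).
* **Determinism.** The generator seeds its own RNG stream and restores the
  caller's, so identical spec + seed give byte-identical tables.

Because ROI draws are independent Gaussians, the quantitative classifier's
expected sensitivity has a closed form,
`Φ((μ_f − μ_tp) / √(σ_f² + σ_tp²))` over the amyloid-positive parameters,
and the acceptance tests check the simulated sensitivity at 500 patients
per group against it within three Monte-Carlo standard errors. Passing
these tests shows the pipeline is internally consistent with its stated
distributions — not that real CBS cohorts follow them: visual-rating
behaviour, inter-ROI correlation, scanner effects and rater drift are all
outside what the generator emulates.

## Reference fixtures

The only patient-level information released with the original cohort is a
set of printed summaries, shipped here as fixed inputs:
`reference_modality_counts()` (per-modality confusion counts against PIB
status), `apoe_reference_table()` (APOE ε4 carriage 6/10 vs 1/10), and
`pathology_cases()` (the eight autopsy/biopsy cases, as a plain-text table
under `inst/extdata`). `reference_modality_calls()` expands the counts into
per-patient calls with an arbitrary but deterministic id assignment — any
assignment with the same cell counts yields identical 2×2 tables, which is
all the statistics consume. Quantities that depend on the unreleased
patient-level data (the both-variant overlap split, intra-rater kappas,
combined-predictor odds ratios) are deliberately not pinned to published
values; they are covered by the property-based checks above instead. One
printed inconsistency is preserved rather than papered over: the
quantitative-FDG confusion counts give a sensitivity of 9/10 = 90%, while
the accompanying text rounds it with the visual reads to 91%; this package
reproduces the counts.

## Problem sizes and runtime envelope

Validation runs at deliberately modest sizes chosen to make sampling error
negligible relative to each tolerance: exhaustive enumeration over all 2⁷
variant-feature combinations and all 2×2 tables with total ≤ 30; 2000
replicates per coverage cell; 100 noisy Logan replicates; 500 patients per
group for the end-to-end closed-form comparison. The complete suite runs in
a few minutes on a single core.

## Known limitations

* The adjudication precedence is a documented replacement for clinician
  impression, not a reconstruction of it; the original cohort's 12
  both-variant patients cannot be re-derived.
* The lateralization formula's orientation (right over left) is a
  convention; swapping hemispheres changes the index.
* The generator draws ROIs independently and features independently within
  groups; real data are correlated in both.
* MRI and visual-read ratings enter only as label columns — the package
  computes nothing from images.
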
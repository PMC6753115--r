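---
title: "Patch-based probability grading on synthetic phantoms: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based probability grading on synthetic phantoms: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`patchgrade` implements a complete, desk-scale analogue of a patch-based
MRI grading study of the Alzheimer's disease (AD) clinical continuum:
five clinical groups — cognitively healthy controls (CH), subjective
cognitive decline (SCD), early and late mild cognitive impairment
(eMCI, lMCI), and AD dementia — compared on grading scores and atrophy
measures of the hippocampus (HPC) and entorhinal cortex (EC), expressed
as covariate-adjusted normative Z-scores. Because real multi-site
clinical MRI is gated, the package ships a synthetic phantom generator
that plays the role of the scanner and of the participants; every
downstream stage is exercised end to end against known ground truth.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic design can and
cannot show.

## The grading model

For a voxel $v$ of a subject volume in template space, the engine
extracts the cubic intensity patch $P_s(v)$ of half-width $r$ (default
$r = 3$, a $7\times7\times7$ patch) and compares it with every template
patch $P_t(u)$ centred within a search window of half-width $w$ around
the same template-space location, across all templates $t$ of a labeled
library. The comparison is the plain sum of squared differences
$d_{t,u} = \lVert P_s(v) - P_t(u)\rVert_2^2$, turned into a nonlocal
weight

$$ w_{t,u} = \exp(-d_{t,u} / h^2), \qquad
   h^2 = \min_{t,u} d_{t,u} + \varepsilon, $$

with $\varepsilon$ = `bandwidth_eps` ($10^{-8}$) per patch voxel. Tying
$h^2$ to the smallest candidate distance makes the weights adaptive: a
subject that appears in the library receives an essentially degenerate
weight on its own patch (the "subject in library" limit grades exactly
at that template's tag), and a common rescaling of all intensities
leaves the fused labels unchanged.

Two quantities are fused from the same weights:

* **Label**: each candidate votes for the structure label at its centre
  voxel; the label with the maximum summed weight wins (ties go to the
  lowest code, deterministically). This yields the segmentation.
* **Grading**: the weighted mean of the template group tags, 1 for
  healthy-control templates and 2 for AD templates. Grading is a convex
  combination of $\{1, 2\}$, so it always lies in $[1, 2]$; higher
  means more AD-like.

The regional grading score is the unweighted mean of the per-voxel
gradings over the voxels the fusion itself assigns to the structure.
Whether the original method averages over a fixed anatomical mask or
over the fused segmentation is not specified by its published
description; the fused-segmentation choice keeps segmentation and
grading self-consistent and is the package default (a fixed mask can be
emulated by grading an explicit voxel set with `grade_voxels()`).

**Preselection.** Candidates whose patch mean or variance differ from
the subject patch by more than a factor `1/presel_thresh` (default 2,
i.e. threshold 0.5) are skipped before any distance is computed — the
standard patch-preselection device. If no candidate survives, the
engine silently falls back to the exhaustive candidate set and flags
the voxel, so the weight set is never empty. With preselection off the
optimized engine is bit-compatible (to $10^{-10}$ relative) with a
plain-R exhaustive loop (`brute_force_grade()`), which the test suite
uses as its oracle. On phantoms at the default threshold, preselection
changes the fused label only at a sub-percent rate at structure
boundaries; region scores agree to well under the score resolution.

**Borders.** Patches crossing the volume border use replicate padding;
candidate centres outside the grid are simply not candidates.

## The phantom cohort

The generator is the package's definition of the study conditions, not
a tuning device. A phantom is a "brain" ellipsoid of tissue intensity
100 on background 0, containing four bilateral structures (HPC and EC
as ellipsoids with grid-proportional centres and semi-axes), all
mirror-symmetric about the midsagittal plane. An atrophy severity
$s \in [0,1]$ drives two effects at once:

* semi-axes shrink by $(1 - s\,\cdot\,$`volume_loss_max`$)^{1/3}$
  (default maximal loss 30 %), so enclosed volume falls linearly in
  $s$; and
* the rim shell (normalized ellipsoid radius 0.75–1) shifts by
  $s\,\cdot\,$`intensity_shift_max` (default −25 units), pulling the
  boundary toward tissue intensity — grading is sensitive to boundary
  texture, not only to size.

Template libraries draw healthy templates at $s \sim U[0, 0.1]$ and AD
templates at $s \sim U[0.8, 1]$, tagged 1 and 2. Subject volumes
additionally receive, in order: a small random rigid pose (up to 3
voxels translation and 3° rotation by default), a random low-order
polynomial multiplicative bias field (peak-to-trough 10 %, order 2,
unit mean over the brain), and additive Gaussian noise (SD 2 % of
tissue intensity). Noise is Gaussian rather than Rician: the
downstream operators are intensity-generic, and at the phantom's
contrast the distinction is immaterial.

The five-group severity profile defaults to CH 0.05, SCD 0.15, eMCI
0.40, lMCI 0.60, AD 0.85, with per-subject jitter SD 0.05. The
published study reports no SCD–CH atrophy difference, so no empirical
magnitude exists for the SCD level; it is a free design parameter, set
just above CH so that the generated mean ordering is resolvable at the
default cohort size without making SCD clinically abnormal. Cohort
sizes default to the published composition (CH 29, SCD 66, eMCI 22,
lMCI 8, AD 12; 137 in all). Covariates are drawn with the published
per-group means and SDs (age, MoCA, GAI, GDS, delayed recall, sex
ratios), and the cognitive variables are drawn inside the group's
classification region so records round-trip through the classifier.
Anatomy scales mildly with age (−0.2 %/year) and sex (+2 % for males)
so the normative adjustment has real structure to remove; intracranial
volume is the brain-mask volume, which exists precisely so that the
volumetric adjustment can exercise that covariate.

What the phantoms do **not** model: real neuroanatomy and its
between-subject topological variability, partial-volume mixtures,
multi-tissue contrast, scanner-specific artifacts, or Rician noise
statistics. Passing tests therefore demonstrate the correctness and
internal calibration of the pipeline — monotone severity recovery,
segmentation overlap against truth, null-cohort false-positive control
— not clinical performance on real MRI.

## Preprocessing stand-ins

Each preprocessing stage honours the contract of its clinical
counterpart at desk scale; none claims to re-implement the original
algorithm.

* **Denoising** is a nonlocal-means filter (patch half-width 1, search
  half-width 3 by default) with bandwidth $h^2 = 2\hat\sigma^2$, where
  $\hat\sigma$ is the pseudo-residual MAD estimate of the noise SD. The
  published description names an optimized nonlocal-means filter
  without parameters; these defaults follow common practice.
* **Bias correction** fits a polynomial (order 2 by default) to log
  intensities over a mask, with two trimmed refits (residuals within 2
  MADs) so bright structures embedded in the dominant tissue class do
  not bend the field; the exponentiated fit is normalized to unit mean
  over the mask. This is a deliberate simplification of
  histogram-sharpening inhomogeneity correctors: same contract (remove
  a smooth multiplicative field), verifiable against the generator's
  known field (relative RMSE below 5 % at the default amplitude).
* **Registration** is rigid (6 parameters), maximizing normalized
  correlation by Nelder–Mead over a three-level coarse-to-fine pyramid
  (down-sampling 4×, 2×, 1×; iteration caps 400/200/120). Normalized
  correlation rather than mutual information because phantom contrasts
  are consistent and NC has a smooth optimum. Recovery error for poses
  within the generator's range is well under half a voxel on clean
  phantoms.
* **Intensity normalization** is the least-squares affine map of
  subject onto template intensities over the brain mask, with a
  positive-gain guard. Normalization happens before brain extraction
  (library intensities are template-normalized); the ordering of these
  two stages is not specified by the published description and is
  recorded here.
* **Brain extraction** reuses the label-fusion engine with brain /
  non-brain labels from the library's content masks, at small radii,
  plus an intensity veto: deep inside the candidate region every
  template patch is brain, so fusion alone cannot reject a content-free
  subject; voxels darker than a quarter of the background-to-tissue
  interval are vetoed. The multiscale cascade of the clinical method is
  collapsed to one pass — phantom backgrounds are simple.

All stages are deterministic given their inputs. Running the chain
twice changes the volume less than running it once (an empirical
contraction checked in the tests).

## Normative Z-scores, QC, composites

Raw measures are structure volumes (voxel count × voxel volume from
the fused label field) and raw grading scores. A normative model —
ordinary least squares per measure, trained on generated
cognitively-healthy subjects only (≥ 20 required; the pipeline default
is 50, the calibration tests use 200) — predicts each measure from age
and sex (grading) or age, sex and intracranial volume (volumes). Then
$Z = (\text{raw} - \text{predicted}) / \hat\sigma_{\text{resid}}$ with
the degrees-of-freedom-corrected residual SD (the alternative, total
SD, is not used; the choice is recorded here). Grading Z-scores are
sign-flipped so that **negative always means more AD-like**, matching
the convention that the zero line is normality; raw gradings are
retained alongside.

Quality control follows the voxel-discrepancy rule: a structure whose
estimated and reference label fields disagree on 100 or more voxels
(symmetric difference) is excluded; 99 is retained — the threshold is
strict and oracle-checked.

Composites: (a) the mean of all region Z-scores of one modality,
(b) the mean of the four bilateral grading Z-scores, (c) the mean of
the atrophy composite and the grading composite. Excluded regions are
refused, not silently dropped.

## Statistics

Group comparisons use classical one-way ANOVA (equal-variance; the
heteroscedasticity-robust variant is deliberately not the default,
matching the named method) with Tukey HSD post-hocs — the Tukey–Kramer
form, required by the unbalanced group sizes — plus Cohen's d with the
$(n-1)$-weighted pooled SD, Pearson chi-square for categorical
characteristics, and Benjamini–Hochberg FDR for region batteries. The
moderation analysis regresses a biomarker Z on complaint group, symptom
score, and their interaction; its type-I error and power are verified
by simulation at the published group sizes. Classical machinery is
delegated to base R (`oneway.test`, `TukeyHSD`, `p.adjust`,
`chisq.test`, `lm`); the package owns the contracts, guards and the
report layer, and every statistic is additionally checked against a
hand-written textbook-formula oracle in the tests.

The report generator follows the study's split: Tukey pairwise tests
for the main HPC/EC outcomes and composites, FDR across regions for
whole-battery scans. Adjusted pairwise p-values are reported
untruncated.

## Classification rules

Groups are assigned CDR-first: CDR 1.0 with a memory complaint, MoCA
13–25 and education-stratified impaired Logical Memory is AD; CDR 0.5
splits into lMCI (impaired LM, MoCA 20–25) and eMCI (borderline LM,
MoCA 20–26); CDR 0 with MoCA ≥ 26 and intact LM is SCD when the
complaint is worried and CH otherwise; everything else is
UNCLASSIFIED. The LM cutoffs overlap between the borderline and intact
bands by construction (e.g. 9–11 versus ≥ 9 at ≥ 16 years of
education); CDR disambiguates every overlap, which an exhaustive scan
over the discrete record grid confirms: no record satisfies two group
rules, and MoCA 26 with CDR 0.5 and borderline LM is eMCI, not SCD.

## Problem sizes and numerical choices

The heavy checks run at sizes chosen once for a single-CPU desk run:

* severity-monotonicity sweep: 5 levels × 10 phantoms at 64³, 5+5
  template library, search half-width 1;
* default cohort runs: 137 subjects + 50 normative controls at 64³,
  10+10 library, search half-width 1, preselection on; the
  cohort-gradient checks generate subjects already aligned (no pose or
  bias) and grade directly, while the full preprocessing chain is
  exercised separately on its own recovery checks — registration and
  bias recovery are properties of the preprocessing operators, not of
  the group statistics;
* null-cohort calibration: 50 seeds × (5 × 10) subjects at 32³ with a
  patch half-width of 2, a 3+3 library and a fixed normative model —
  the compact grid keeps 50 independent cohorts affordable, and the
  property under test (false-positive control of the adjusted group
  battery when all severities are equal) does not depend on grid size;
* engine-oracle equivalence: ≥ 1000 random voxel draws on 16³ volumes
  against the plain-R exhaustive loop.

Tie-breaks and degenerate inputs are all deterministic: argmax label
ties take the lowest code; zero-distance candidates dominate through
the adaptive bandwidth; empty fusion results, empty masks, zero pooled
SDs, constant symptom scores, rank-deficient normative designs and
missing reference groups raise flagged errors rather than propagating
silently.

## Known limitations

* Ellipsoidal anatomy gives the patch engine an easier matching problem
  than convoluted cortex; Dice targets here do not transfer to real
  segmentation accuracy.
* The normative model is trained on the same generative family it
  adjusts, so its calibration checks verify the machinery, not
  transportability across scanners or sites (site and scanner
  covariates are accepted by the model interface but the phantom
  cohort is single-site).
* Rigid-only registration is adequate for the generator's pose range;
  real pipelines need affine or nonlinear components.
* The grading sign convention (raw: higher = more AD-like; Z: lower =
  worse) is applied at the adjustment stage and logged in the run
  manifest; mixing raw and adjusted directions is the main foot-gun
  when extending the report layer.
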
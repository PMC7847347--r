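---
title: "Predicting IDH1 genotype from VASARI scores and ADC radiomics: methods and design"
author: "RadioGliomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting IDH1 genotype from VASARI scores and ADC radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RadioGliomics)
```

## The problem

Diffuse lower-grade gliomas (WHO grade II–III) split into prognostically
distinct entities by IDH1 mutation status, and a preoperative, imaging-based
prediction of that genotype informs treatment planning. Two kinds of MRI
evidence carry signal: qualitative VASARI trait scores read by radiologists
from conventional sequences, and quantitative radiomics features computed
from the apparent diffusion coefficient (ADC) map inside the tumor volume of
interest (VOI). `RadioGliomics` implements the full analysis chain —
56-feature ADC radiomics extraction, 23-trait VASARI encoding, two-step
feature selection (mRMR then 0.632+ bootstrap AUC), random-forest model-order
sweeps, and decision-level fusion of the two models at weight 0.5 — together
with a seeded synthetic cohort generator so that every stage can be exercised
and falsified without access to patient data.

## The pipeline

For a cohort of subjects with an ADC volume, a co-registered binary tumor
mask, a VASARI record and an IDH1 label each:

1. **Split** the cohort into training and validation sides, stratified by
   label (default fraction 67/102).
2. **Extract** the 56 radiomics features per subject and normalize each
   feature to [0, 1] using *training-cohort* bounds; validation values are
   mapped with those same bounds and clipped.
3. **Encode** VASARI records to integer codes (ordinal traits by rank).
4. **Select** features on the training side only: an mRMR candidate pool,
   then single-feature 0.632+ bootstrap AUC ranking; top 5 VASARI and top 10
   radiomics features are kept, each with its AUC.
5. **Sweep model order**: for k = 1..5 (VASARI) and 1..10 (radiomics), train
   a random forest on the top-k features and score it with the 0.632+
   bootstrap AUC on training data; the optimal order maximizes that AUC
   (ties go to the smaller order).
6. **Evaluate** the two optimal models on the validation cohort; metrics are
   reported as mean ± sd over repeated trainings with distinct seeds.
7. **Fuse** the two models' wildtype probabilities as
   `0.5 p_VASARI + 0.5 p_radiomics` and evaluate the fusion; optionally
   repeat with age and gender appended to the radiomics arm.
8. **Report** the cross-type Pearson correlation (the empirical argument
   that the two feature families are complementary) and the cohort balance
   table (chi-square / Fisher / Student t).

The whole run derives from one master seed; identical configuration and seed
reproduce every stage output byte for byte.

## The radiomics registry

The 56 features are 3 shape + 13 first-order histogram + 9 GLCM + 13 GLRLM +
13 GLSZM + 5 NGTDM features (`featureRegistry()` lists the names). The
conventions that fix their values:

* **Discretization** — fixed bin *count*, Ng = 32, uniform between the
  in-mask minimum and maximum (minimum maps to level 1, maximum to level Ng).
  A fixed count keeps the texture matrices comparable across subjects, which
  between-subject modelling requires; a constant VOI is flagged degenerate.
* **Directions** — the 13 unique 3-D offsets at Chebyshev distance 1. GLCM
  and GLRLM are accumulated over all 13 and merged before features are
  computed, giving one rotation-robust value per feature per subject.
  Direction-restricted matrices remain available for analysis and testing.
* **Mask restriction** — voxels outside the VOI break runs and zones and are
  excluded from co-occurrence pairs and NGTDM neighbourhoods. NGTDM averages
  over the *available* in-mask 26-neighbours; isolated voxels are excluded;
  ε = 1e-12 guards zero denominators (a zero-difference field caps
  coarseness at 1/ε).
* **Run/zone percentages** — the run percentage divides the run count by the
  total run mass `sum(j·r(i,j))` (in-mask voxels × directions), so the value
  stays in (0, 1] for any direction set; the zone percentage divides by the
  in-mask voxel count.
* **First-order entropy/uniformity** use a 64-bin fixed-width in-mask
  histogram; energy is the raw sum of squares; variance uses n−1.
* **Shape** — eccentricity is `sqrt(1 − λ_min/λ_max)` from the covariance of
  in-mask voxel coordinates in mm; volume is voxel count × voxel volume;
  surface area is face-counted. Eccentricity is the shape descriptor this
  analysis centres on; volume and surface-to-volume ratio are its standard
  companions, and the registry is an editable data frame.

Every texture feature is pinned, at tolerance 1e-9, to brute-force
pair/run/zone/neighbourhood enumeration oracles that live in the test suite
and share no code with the compiled implementation.

## Feature selection

*Mutual information* is the plug-in contingency-table estimate in bits.
Features with more than 6 distinct values are discretized at mean ± sd into
3 levels first; encoded categorical traits enter as-is. The mRMR ranking is
greedy with the difference criterion `I(f; y) − mean I(f; s)` over the
selected set. Ties are resolved deterministically: higher score, then
*smaller redundancy term*, then higher relevance, then feature name. The
redundancy-ascending rule matters: when a candidate duplicates an
already-selected feature that perfectly predicts the labels, its score ties
with fresh noise at exactly zero, and preferring the less redundant candidate
is the resolution consistent with mRMR's purpose.

The *0.632+ bootstrap AUC* of a model draws B = 100 n-with-replacement
resamples, trains on each, and scores the out-of-bag subjects; replicates
whose resample or out-of-bag set lacks a class are skipped and counted. With
apparent AUC `a` (train and score on everything) and mean out-of-bag AUC `o`,
the relative overfitting rate is `R = (a − o)/(a − 0.5)` — 0.5 being the
no-information AUC — clipped to [0, 1] and set to 0 when `a ≤ 0.5`; the
weight is `w = 0.632/(1 − 0.368 R)` and the estimate `(1 − w) a + w o`.
Ranking uses single-feature models, consistent with reporting one AUC per
selected feature.

## Modelling choices

* Random forests with 500 trees, unlimited depth, minimum node size 1,
  `mtry = floor(sqrt(p))`, all seeded (the acceptance script uses 200 trees
  at its cohort scale). When a training resample has *no* varying predictor —
  possible for sparse binary traits under bootstrap — a tree cannot split,
  and the underlying C implementation does not terminate; the fit falls back
  to predicting the training wildtype prevalence.
* The reported probability always refers to the **wildtype** class; the
  operating threshold for sensitivity/specificity/accuracy is probability
  ≥ 0.5 (wildtype on ties).
* The "±" on validation metrics is the sd over 10 repeated trainings with
  distinct seeds on fixed data — the reading of repeat-variability we adopt;
  the ROC curve uses the repeat-averaged scores.
* AUC is the Mann–Whitney pair statistic with ties counted ½, computed from
  mid-ranks; the ROC is a threshold sweep over unique scores. The test suite
  cross-checks it against an independent implementation (pROC).
* The fusion weight is fixed at 0.5, not learned — at ~100 subjects a learned
  weight mostly fits noise.
* Cohort balance uses chi-square *without* continuity correction (the
  uncorrected statistic is appropriate at these margins, and Fisher's exact
  test takes over whenever an expected cell drops below 5), and the
  classical equal-variance t-test for continuous variables.

## The synthetic cohort generator

The generator's default conditions are a realistic LGG cohort: 102 subjects at a 50:52
mutant:wildtype balance, one ADC tumor volume (10⁻³ mm²/s), one VASARI
record, and age/gender per subject. A tumor is a randomly rotated ellipsoid
(radius 6–10 mm by default) in a 32³ voxel grid at 1 mm isotropic spacing;
in-mask ADC is Gaussian, mean 1.2 and sd 0.15, on top of normal-appearing
tissue around 0.8 — a plausible lower-grade-glioma diffusion range, chosen
here because no distributional parameters of the real maps are published.
Necrosis-like foci (ADC ~ N(0.6, 0.1²), radius 1.5–2.5 mm, Poisson counts)
and hard clipping at 0 complete the intensity model.

Texture is a **Gaussian copula**: white noise is smoothed with a Gaussian
kernel whose width is the correlation length (subject-level jitter sd 0.25
voxels models biological heterogeneity), then rank-mapped onto exact normal
scores. The rank-mapping is what makes the four class-effect knobs act on
separate feature families — without it, a shorter correlation length
mechanically deepens the field minimum and the texture knob leaks into the
histogram family:

| knob | default | acts on |
|---|---|---|
| `minShift` | −0.04 | wildtype per-subject minimum ADC voxel (histogram minimum) |
| `necrosisRate` | +0.3 foci | extra wildtype necrosis foci (low-gray-level emphasis family) |
| `textureShift` | +0.2 voxels | mutant correlation length (run/zone length, GLCM correlation) |
| `eccentricityShift` | +0.07 | wildtype mask elongation (shape) |

Setting every effect to zero (`zeroSignalConfig()`) makes the two class
distributions identical — the null used to check that no selection optimism
leaks into validation metrics.

One coupling is unavoidable: because quantization spans the in-mask min–max
range, anything that moves the per-subject minimum (the shift itself, or
necrosis foci) also stretches the bins and shifts every texture matrix. The
planted-recovery experiment therefore designates one *sentinel feature* per
effect family — the family's strongest single-feature readout as measured on
the generator (histogram minimum; long-run low-gray emphasis for necrosis;
short-run emphasis for roughness) — and asks the two-step selection to
recover all three into its top 10.

**Calibration.** Defaults were fixed once, by Monte-Carlo, so that the
strongest planted single-feature AUCs sit in the range reported for
selected features in published LGG radiogenomics analyses (top radiomics
features in the low 0.7s, histogram minimum and eccentricity in the
0.63–0.68 band). The five informative VASARI traits
(enhancement quality, deep white matter invasion, tumor location, proportion
of necrosis, T1/FLAIR ratio) got class-conditional category probabilities
whose closed-form ordinal AUCs are 0.752, 0.740, 0.685, 0.683 and 0.634; the
other 18 traits are class-independent. `perturbMask()` produces a
second-rater surrogate by flipping voxels with probability
`(1 − e^{−severity}) · e^{−d/severity}` (d = voxel distance to the mask
boundary), and `calibratePerturbation()` bisects the severity to a target
mean Dice coefficient, e.g. the 0.879 interobserver regime.

What the generator does **not** emulate: T1W/T2W/FLAIR contrast and
enhancement physics (VASARI records are sampled from conditionals, not
rendered from images), DWI acquisition and registration error, non-ellipsoidal
infiltrative margins, and intra-tumor heterogeneity beyond foci + stationary
texture. Passing tests therefore demonstrate that the *machinery* —
extraction, selection, estimation, fusion — behaves correctly on data with
known planted truth; they do not validate the clinical effect sizes
themselves.

## Problem sizes in the test suite

The suite verifies texture features against enumeration oracles on 100
random 6×6×6 volumes; planted-feature recovery on 25 cohorts of 100 subjects
(28³ grids); null calibration of the full pipeline on 50 cohorts of 60
subjects (20³); and fusion complementarity on 25 cohorts of 80 subjects
(24³) — sizes chosen so Monte-Carlo standard errors stay well inside the
asserted margins while a desktop run of the whole suite remains short.
Bootstrap and forest sizes are scaled accordingly (B = 8–20, 60–100 trees)
in the simulation tests; closed-form and oracle tests are exact.

## Known limitations

* The order sweep's 0.632+ AUC barely penalizes appended pure-noise features
  under a strong random forest, so the "optimal order" concentrates on small
  orders rather than identifying the single informative feature every time;
  the tests assert the median-parsimony and expectation forms of that
  property.
* NIfTI round trips store intensities as the format's floating point; masks
  and spacings are exact, intensities agree to ~1e-6.
* The pipeline recomputes all stages on each run (no stage cache); stage
  outputs are plain CSV/JSON files, so external tools can resume from them.
* Nominal VASARI traits are single integer-coded columns, adequate for tree
  splits but not for linear models; one-hot encoding is deliberately out of
  scope.
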
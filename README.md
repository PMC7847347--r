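# RadioGliomics

Predicting IDH1 genotype in lower-grade glioma (LGG) from two complementary
kinds of MRI evidence: qualitative **VASARI** trait scores (23 standardized
radiologist readings) and quantitative **ADC radiomics** (56 shape,
histogram and texture features computed inside the tumor volume of
interest on the apparent-diffusion-coefficient map). The package is aimed
at radiogenomics researchers who want the full analysis chain as tested,
reusable R functions rather than a one-off script.

## The method

For a cohort with per-subject ADC volume + tumor mask (NIfTI), VASARI
record and binary IDH1 label:

1. **Radiomics extraction** — 56 features: 3 shape, 13 first-order
   histogram, 9 GLCM, 13 GLRLM, 13 GLSZM, 5 NGTDM. Volumes are quantized
   to Ng = 32 gray levels between the in-mask min and max; GLCM/GLRLM are
   merged over the 13 unique 3-D directions; runs and zones break at the
   mask; features are normalized to [0, 1] with training-cohort bounds.
2. **VASARI encoding** — lexicon-validated records map to integer codes
   (ordinal traits by rank order).
3. **Two-step selection** (training side only) — greedy mRMR
   (difference criterion, `I(f;y) − mean I(f;s)`) forms a candidate pool;
   each pooled feature is then ranked by its single-feature **0.632+
   bootstrap AUC**: with apparent AUC `a` and out-of-bag AUC `o`,
   `R = (a − o)/(a − 0.5)` clipped to [0,1], `w = 0.632/(1 − 0.368 R)`,
   estimate `(1 − w) a + w o`. Top 5 VASARI and top 10 radiomics features
   are kept.
4. **Model-order sweep** — random forests on the top-k features
   (k = 1..5 / 1..10), optimal order = argmax training bootstrap AUC.
5. **Fusion** — the final probability is the weighted average
   `0.5 p_VASARI + 0.5 p_radiomics`; sensitivity/specificity/accuracy are
   read at probability ≥ 0.5, AUC is the Mann–Whitney pair statistic.

Because the patient data behind this design are not public, the package
ships a seeded **synthetic cohort generator** (`syntheticConfig()`,
`generateCohort()`) whose default conditions are a realistic LGG cohort — 102 subjects at a
50:52 mutant:wildtype balance, ellipsoidal tumors with Gaussian-copula ADC
texture, class effects planted per feature family, class-conditional
VASARI records, and rater-style mask perturbation calibrated to a target
Dice coefficient. Every stage is testable against known planted truth; see
the methods vignette (`vignettes/radiogenomic-fusion-modelling.Rmd`).

## Worked example

```r
library(RadioGliomics)

cfg <- pipelineConfig(
  synthetic = syntheticConfig(nSubjects = 40, volumeShape = c(24, 24, 24),
                              tumorRadiusRange = c(4.5, 8)),
  B = 20, model = modelConfig(nTree = 100, repeats = 3), seed = 42)
res <- runPipeline(cfg)
cat(renderReport(res), sep = "\n")
```

```
IDH1 genotype prediction — run summary
==========================================
seed 42, 40 subjects (26 train / 14 validation)

Selected vasari features (top 5):
  VASARI tumor_location                         0.763
  VASARI t1_flair_ratio                         0.717
  VASARI enhancement_quality                    0.712
  VASARI side_of_lesion_center                  0.673
  VASARI eloquent_brain                         0.656
  order sweep 1..5: optimal 3 (bootstrap AUC 0.859)

Selected radiomics features (top 10):
  GLRLM low gray-level run emphasis             0.855
  GLRLM long run low gray-level emphasis        0.818
  GLCM autocorrelation                          0.809
  Eccentricity                                  0.809
  Volume                                        0.802
  GLRLM short run low gray-level emphasis       0.799
  GLSZM gray-level nonuniformity                0.758
  Histogram maximum                             0.750
  GLRLM run-length nonuniformity                0.748
  GLRLM short run high gray-level emphasis      0.735
  order sweep 1..10: optimal 8 (bootstrap AUC 0.908)

Validation performance:
  vasari         AUC 0.823+/-0.024 sens 1.000 spec 0.571 acc 0.786
    ROC series 1: 12 points
  radiomics      AUC 0.755+/-0.020 sens 0.714 spec 0.571 acc 0.643
    ROC series 2: 14 points
  fused          AUC 0.912+/-0.031 sens 0.905 spec 0.619 acc 0.762
    ROC series 3: 15 points
  fusedClinical  AUC 0.946+/-0.024 sens 1.000 spec 0.619 acc 0.810
ROC series rendered: 3
Cross-type correlation: mean |r| = 0.106
```

Reading the output: the per-feature numbers are single-feature 0.632+
bootstrap AUCs on the training side (the shape of a selected-feature
table); the validation block gives mean ± sd over repeated trainings; the
fused model combines the two optimal models at weight 0.5 and here beats
either alone, while the low cross-type correlation is what makes the two
evidence types complementary.

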
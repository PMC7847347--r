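# Synthetic cohort generator: seeded determinism, planted-effect
# semantics, VASARI conditionals and mask perturbation.

test_that("config validation names the offending field", {
  expect_error(syntheticConfig(nSubjects = 2), "nSubjects")
  expect_error(syntheticConfig(mutantFraction = 1.2), "mutantFraction")
  expect_error(syntheticConfig(adcBackgroundSd = -1), "adcBackgroundSd")
  bad <- vasariLexicon()
  cond <- RadioGliomics:::.defaultVasariConditionals()
  cond$enhancement_quality["mutant", ] <- c(0.5, 0.4, 0.2) # sums to 1.1
  expect_error(syntheticConfig(vasariConditionals = cond),
               "enhancement_quality")
})

test_that("label allocation hits the configured class balance exactly", {
  cfg <- syntheticConfig(nSubjects = 102, mutantFraction = 50 / 102,
                         volumeShape = c(16, 16, 16),
                         tumorRadiusRange = c(3, 5), seed = 7)
  co <- generateCohort(cfg)
  tab <- table(cohortLabels(co))
  expect_equal(unname(tab[["mutant"]]), 50)
  expect_equal(unname(tab[["wildtype"]]), 52)
  ids <- vapply(co@subjects, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("identical seeds reproduce cohorts exactly; different seeds differ", {
  cfg <- smallConfig(nSubjects = 5, seed = 3)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(c1@subjects, c2@subjects)
  c3 <- generateCohort(smallConfig(nSubjects = 5, seed = 4))
  expect_false(identical(c1@subjects[[1]]$volume@intensities,
                         c3@subjects[[1]]$volume@intensities))
})

test_that("zero effect sizes give the same voxel distribution per class", {
  cfg <- zeroSignalConfig(smallConfig(seed = 9))
  withr::with_seed(1, {
    vm <- unlist(lapply(1:4, function(i) {
      v <- generateTumorVolume("mutant", cfg, 900 + i)
      intensities(v)[tumorMask(v)]
    }))
    vw <- unlist(lapply(1:4, function(i) {
      v <- generateTumorVolume("wildtype", cfg, 950 + i)
      intensities(v)[tumorMask(v)]
    }))
  })
  expect_gt(suppressWarnings(ks.test(vm, vw)$p.value), 0.01)
})

test_that("the minimum-ADC shift moves the wildtype minimum by its size", {
  cfg <- smallConfig(classEffects = list(minShift = -0.3, necrosisRate = 0,
                                         textureShift = 0,
                                         eccentricityShift = 0))
  withr::with_seed(2, {
    d <- vapply(1:60, function(i) {
      s <- sample.int(1e6, 1)
      vm <- generateTumorVolume("mutant", cfg, s)
      vw <- generateTumorVolume("wildtype", cfg, s + 1)
      min(intensities(vw)[tumorMask(vw)]) - min(intensities(vm)[tumorMask(vm)])
    }, numeric(1))
  })
  expect_lt(abs(mean(d) - (-0.3)), 3 * sd(d) / sqrt(length(d)))
})

test_that("degenerate radius with no eccentricity target gives a sphere", {
  cfg <- smallConfig(tumorRadiusRange = c(7, 7), baseEccentricity = 0,
                     eccentricitySd = 0,
                     classEffects = list(minShift = 0, necrosisRate = 0,
                                         textureShift = 0,
                                         eccentricityShift = 0))
  v <- generateTumorVolume("mutant", cfg, 77)
  # sqrt(1 - l_min/l_max) magnifies voxelization anisotropy: 0.2 means the
  # principal axes agree within 4%
  expect_lt(shapeFeatures(v)[["Eccentricity"]], 0.2)
})

test_that("oversized tumors are rejected with a generation error", {
  cfg <- syntheticConfig(nSubjects = 4, volumeShape = c(10, 10, 10),
                         tumorRadiusRange = c(8, 9))
  expect_error(generateTumorVolume("mutant", cfg, 1), "larger than")
})

test_that("VASARI records follow their class conditionals", {
  lex <- vasariLexicon()
  cond <- RadioGliomics:::.defaultVasariConditionals()
  cond$enhancement_quality <- rbind(mutant = c(0.7, 0.2, 0.1),
                                    wildtype = c(0.1, 0.2, 0.7))
  cfg <- smallConfig(vasariConditionals = cond)
  recs <- lapply(1:200, function(i)
    generateVasariRecord(if (i <= 100) "mutant" else "wildtype", cfg,
                         1000 + i))
  df <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(as.list(r), check.names = FALSE)))
  expect_equal(nrow(validateVasariRecords(df)), 0)
  enc <- encodeVasariRecords(df, rep(c("mutant", "wildtype"), each = 100))
  auc <- rocAuc(featureValues(enc)[, "VASARI enhancement_quality"],
                subjectLabels(enc))$auc
  expect_gt(auc, 0.7)

  # identical conditionals: no signal
  cfg0 <- zeroSignalConfig(cfg)
  recs0 <- lapply(1:200, function(i)
    generateVasariRecord(if (i <= 100) "mutant" else "wildtype", cfg0,
                         2000 + i))
  df0 <- do.call(rbind, lapply(recs0, function(r)
    as.data.frame(as.list(r), check.names = FALSE)))
  enc0 <- encodeVasariRecords(df0, rep(c("mutant", "wildtype"), each = 100))
  auc0 <- rocAuc(featureValues(enc0)[, "VASARI enhancement_quality"],
                 subjectLabels(enc0))$auc
  expect_lt(abs(auc0 - 0.5), 0.12)

  # degenerate one-hot conditional is a point mass
  cond1 <- RadioGliomics:::.defaultVasariConditionals()
  cond1$t1_flair_ratio <- rbind(mutant = c(0, 1, 0), wildtype = c(0, 1, 0))
  cfg1 <- smallConfig(vasariConditionals = cond1)
  r1 <- vapply(1:20, function(i)
    generateVasariRecord("mutant", cfg1, 3000 + i)[["t1_flair_ratio"]],
    character(1))
  expect_true(all(r1 == "mixed"))
})

test_that("a missing trait distribution is a configuration error", {
  cfg <- smallConfig()
  cfg@vasariConditionals$tumor_location <- NULL
  expect_error(generateVasariRecord("mutant", cfg, 1), "tumor_location")
})

test_that("mask perturbation spans identity to disjointness with severity", {
  cfg <- smallConfig(seed = 12)
  m <- tumorMask(generateTumorVolume("mutant", cfg, 55))
  expect_identical(perturbMask(m, 0), m)
  expect_equal(diceCoefficient(m, perturbMask(m, 0))$dsc, 1)
  dHigh <- diceCoefficient(m, perturbMask(m, 50, seed = 8))$dsc
  expect_lt(dHigh, 0.2)
  expect_error(perturbMask(array(FALSE, c(3, 3, 3)), 1), "empty")
  expect_error(perturbMask(m, -1), "severity")
})

test_that("calibrated perturbation lands in the interobserver Dice regime", {
  cfg <- smallConfig(seed = 13)
  masks <- lapply(1:30, function(i)
    tumorMask(generateTumorVolume(if (i %% 2) "mutant" else "wildtype",
                                  cfg, 5000 + i)))
  cal <- calibratePerturbation(masks, targetDsc = 0.879, seed = 6)
  dsc <- vapply(seq_along(masks), function(i)
    diceCoefficient(masks[[i]],
                    perturbMask(masks[[i]], cal$severity, 7000 + i))$dsc,
    numeric(1))
  expect_gt(mean(dsc), 0.85)
  expect_lt(mean(dsc), 0.91)
})

test_that("perturbation severity degrades Dice monotonically in expectation", {
  cfg <- smallConfig(seed = 14)
  masks <- lapply(1:8, function(i)
    tumorMask(generateTumorVolume("mutant", cfg, 6000 + i)))
  meanDsc <- function(sev) mean(vapply(seq_along(masks), function(i)
    diceCoefficient(masks[[i]], perturbMask(masks[[i]], sev, 800 + i))$dsc,
    numeric(1)))
  expect_gt(meanDsc(0.2), meanDsc(1))
  expect_gt(meanDsc(1), meanDsc(3))
})
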
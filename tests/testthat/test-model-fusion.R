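# Cohort split, random-forest training, ROC/AUC, evaluation, fusion,
# correlation and clinical covariates.

test_that("stratified split reproduces the 67/35 design", {
  ids <- sprintf("S%03d", 1:102)
  labels <- rep(c("mutant", "wildtype"), c(50, 52))
  sp <- splitCohort(ids, labels, trainFraction = 67 / 102, seed = 1)
  expect_length(sp$train, 67)
  expect_length(sp$validation, 35)
  expect_setequal(c(sp$train, sp$validation), ids)
  for (side in list(sp$train, sp$validation))
    expect_length(unique(sp$labels[side]), 2)

  sp2 <- splitCohort(ids, labels, trainFraction = 67 / 102, seed = 1)
  expect_identical(sp, sp2)
  expect_error(splitCohort(ids, labels, trainFraction = 1), "degenerate")
  expect_error(splitCohort(ids[1:3], c("mutant", "mutant", "wildtype"),
                           0.5), "2 subjects")
})

test_that("training memorizes separable data and is seed-reproducible", {
  ft <- normalizeFeatures(separableTable(n = 24))
  m1 <- trainModel(ft, "signal", modelConfig(nTree = 100), seed = 4)
  expect_equal(rocAuc(predictProbability(m1, ft), subjectLabels(ft))$auc, 1)
  p1 <- predictProbability(m1, ft)
  m2 <- trainModel(ft, "signal", modelConfig(nTree = 100), seed = 4)
  expect_identical(p1, predictProbability(m2, ft))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(trainModel(ft, "nonexistent", modelConfig()), "unknown")
})

test_that("validation scoring of shuffled labels hovers at chance", {
  withr::with_seed(13, {
    aucs <- vapply(1:25, function(i) {
      n <- 60
      labels <- sample(rep(c("mutant", "wildtype"), n / 2))
      X <- matrix(rnorm(n * 4), n, 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
      ft <- normalizeFeatures(FeatureTable(X, labels))
      tr <- seq_len(40); va <- 41:60
      m <- trainModel(ft[, tr], paste0("f", 1:4),
                      modelConfig(nTree = 60), seed = i)
      rocAuc(predictProbability(m, ft[, va]), subjectLabels(ft)[va])$auc
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("AUC is the Mann-Whitney pair statistic with ties at one half", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.2),
                      c("wildtype", "wildtype", "mutant", "mutant"))$auc, 1)
  expect_equal(rocAuc(c(0.9, 0.3, 0.5, 0.2),
                      c("wildtype", "wildtype", "mutant", "mutant"))$auc,
               0.75)
  expect_equal(rocAuc(rep(0.4, 6),
                      rep(c("wildtype", "mutant"), 3))$auc, 0.5)
  expect_error(rocAuc(1:3, rep("mutant", 3)), "class")
})

test_that("ROC curves are monotone and AUC is rank-invariant", {
  withr::with_seed(19, {
    for (i in 1:10) {
      sc <- rnorm(30)
      labels <- sample(rep(c("mutant", "wildtype"), 15))
      ra <- rocAuc(sc, labels)
      expect_false(is.unsorted(ra$roc$fpr))
      expect_false(is.unsorted(ra$roc$tpr))
      expect_equal(ra$roc[1, ], data.frame(fpr = 0, tpr = 0))
      expect_equal(unlist(ra$roc[nrow(ra$roc), ]), c(fpr = 1, tpr = 1))
      # strictly increasing transform leaves the pair statistic alone
      expect_equal(rocAuc(exp(2 * sc), labels)$auc, ra$auc)
      # cross-check against an independent implementation
      expect_equal(ra$auc,
                   as.numeric(suppressMessages(pROC::auc(
                     pROC::roc(labels, sc, levels = c("mutant", "wildtype"),
                               direction = "<")))))
    }
  })
})

test_that("threshold metrics follow the >= rule and hand-built confusions", {
  sc <- c(1, 0, 1, 0); lb <- c("wildtype", "mutant", "wildtype", "mutant")
  m <- evaluateScores(sc, lb)$metrics
  expect_equal(unname(m[c("sensitivity", "specificity", "accuracy")]),
               c(1, 1, 1))

  # probability 0.5 everywhere predicts wildtype under the >= rule
  m2 <- evaluateScores(rep(0.5, 10),
                       rep(c("wildtype", "mutant"), c(6, 4)))$metrics
  expect_equal(unname(m2["accuracy"]), 0.6)

  # TP 29, FN 11, TN 30, FP 9
  sc3 <- c(rep(0.9, 29), rep(0.1, 11), rep(0.1, 30), rep(0.9, 9))
  lb3 <- rep(c("wildtype", "mutant"), c(40, 39))
  m3 <- evaluateScores(sc3, lb3)$metrics
  expect_equal(unname(m3["sensitivity"]), 29 / 40)
  expect_equal(unname(m3["specificity"]), 30 / 39)
  expect_equal(unname(m3["accuracy"]), 59 / 79)
})

test_that("repeated-training evaluation reports mean, sd and a valid ROC", {
  ft <- normalizeFeatures(separableTable(n = 40))
  rep1 <- evaluateModel(ft[, 1:24], ft[, 25:40], "signal",
                        modelConfig(nTree = 60, repeats = 4), seed = 2)
  m <- reportMetrics(rep1)
  expect_setequal(m$metric, c("auc", "sensitivity", "specificity", "accuracy"))
  expect_true(all(m$mean >= 0 & m$mean <= 1))
  expect_true(all(m$sd >= 0))
  expect_equal(rep1@repeats, 4L)
  roc <- reportRoc(rep1)
  expect_false(is.unsorted(roc$fpr))
})

test_that("model order sweep favors parsimony when only one feature carries signal", {
  withr::with_seed(29, {
    res <- vapply(1:12, function(i) {
      n <- 60
      labels <- rep(c("mutant", "wildtype"), n / 2)
      X <- cbind(planted = ifelse(labels == "wildtype", 1, 0) + rnorm(n, 0, 0.25),
                 matrix(rnorm(n * 4), n, 4,
                        dimnames = list(NULL, paste0("noise", 1:4))))
      ft <- normalizeFeatures(FeatureTable(X, labels))
      sw <- sweepModelOrder(c("planted", paste0("noise", 1:4)), ft,
                            modelConfig(nTree = 100), B = 20, seed = i)
      c(sw@optimalOrder, sw@auc[1], sw@auc[5])
    }, numeric(3))
  })
  expect_lte(median(res[1, ]), 2)
  # appending pure noise never helps in expectation
  expect_gte(mean(res[2, ] - res[3, ]), -0.02)

  ft1 <- normalizeFeatures(separableTable(n = 20))
  sw1 <- sweepModelOrder("signal", ft1, modelConfig(nTree = 40), B = 5,
                         seed = 1)
  expect_equal(sw1@optimalOrder, 1L)
  expect_equal(sw1@orders, 1L)
})

test_that("order sweep rewards additional independent signal in expectation", {
  withr::with_seed(30, {
    gain <- vapply(1:8, function(i) {
      n <- 60
      labels <- rep(c("mutant", "wildtype"), n / 2)
      X <- sapply(1:5, function(j)
        0.8 * (labels == "wildtype") + rnorm(n))
      colnames(X) <- paste0("sig", 1:5)
      ft <- normalizeFeatures(FeatureTable(X, labels))
      sw <- sweepModelOrder(paste0("sig", 1:5), ft,
                            modelConfig(nTree = 100), B = 20, seed = i)
      sw@auc[5] - sw@auc[1]
    }, numeric(1))
  })
  expect_gte(mean(gain), 0)
})

test_that("single-feature forests are monotone in a monotone feature", {
  withr::with_seed(37, {
    x <- seq(0, 1, length.out = 40)
    labels <- ifelse(x > 0.5, "wildtype", "mutant")
    ft <- normalizeFeatures(FeatureTable(cbind(mono = x), labels))
    m <- trainModel(ft, "mono", modelConfig(nTree = 200), seed = 3)
    grid <- FeatureTable(cbind(mono = seq(0, 1, by = 0.05)),
                         rep(c("mutant", "wildtype"), length.out = 21))
    p <- predictProbability(m, normalizeFeatures(grid, normBounds(ft)))
    expect_true(all(diff(p) > -0.02))
  })
})

test_that("probability fusion is the weighted average with guarded inputs", {
  expect_equal(fuseProbabilities(0.6, 0.8, 0.5), 0.7)
  expect_equal(fuseProbabilities(0.3, 0.9, 1), 0.3) # weight 1: VASARI only
  expect_equal(fuseProbabilities(0.3, 0.9, 0), 0.9)
  expect_equal(fuseProbabilities(c(0.2, 0.4), c(0.6, 0.8), 0.25),
               c(0.5, 0.7))
  expect_error(fuseProbabilities(1.2, 0.5), "0, 1")
  expect_error(fuseProbabilities(0.5, 0.5, 2), "weight")
})

test_that("cross-type Pearson correlation flags degeneracy and anchors", {
  withr::with_seed(41, {
    labels <- rep(c("mutant", "wildtype"), 50)
    a <- rnorm(100); b <- rnorm(100)
    x <- FeatureTable(cbind(v1 = a, v2 = rnorm(100), v3 = rep(2, 100)),
                      labels)
    y <- FeatureTable(cbind(r1 = a, r2 = -a, r3 = rnorm(100)), labels)
    r <- featureCorrelation(x, y)
    expect_equal(unname(r["v1", "r1"]), 1)
    expect_equal(unname(r["v1", "r2"]), -1)
    expect_true(all(r >= -1 & r <= 1))
    expect_equal(unname(r["v3", ]), c(0, 0, 0)) # constant column
    expect_true("v3" %in% attr(r, "degenerate"))

    # independent columns: |r| mostly below 0.3 at n = 100
    xi <- FeatureTable(matrix(rnorm(100 * 10), 100,
                              dimnames = list(NULL, paste0("a", 1:10))),
                       labels)
    yi <- FeatureTable(matrix(rnorm(100 * 10), 100,
                              dimnames = list(NULL, paste0("b", 1:10))),
                       labels)
    ri <- featureCorrelation(xi, yi)
    expect_gte(mean(abs(ri) < 0.3), 0.95)
  })
  expect_error(featureCorrelation(
    FeatureTable(cbind(x = 1:4), rep(c("mutant", "wildtype"), 2)),
    FeatureTable(cbind(x = 1:5), rep(c("mutant", "wildtype"), c(2, 3)))),
    "subject")
})

test_that("clinical covariates append, normalize, flag and round-trip", {
  labels <- rep(c("mutant", "wildtype"), 5)
  ft <- normalizeFeatures(FeatureTable(
    cbind(f1 = rnorm(10)), labels,
    covariates = data.frame(age = seq(30, 66, by = 4),
                            gender = rep(c("M", "F"), 5))))
  aug <- augmentWithClinical(ft)
  expect_setequal(rownames(aug), c("f1", "Age", "Gender"))
  expect_true(all(featureValues(aug)[, "Age"] >= 0 &
                  featureValues(aug)[, "Age"] <= 1))
  # dropping the clinical rows recovers the original table
  expect_equal(featureValues(aug)[, "f1", drop = FALSE],
               featureValues(ft)[, "f1", drop = FALSE])

  cft <- normalizeFeatures(FeatureTable(
    cbind(f1 = rnorm(10)), labels,
    covariates = data.frame(age = rep(50, 10), gender = rep("M", 10))))
  caug <- augmentWithClinical(cft)
  expect_true(all(featureValues(caug)[, "Age"] == 0)) # constant -> 0
  b <- normBounds(caug)
  expect_true(b$degenerate[b$feature == "Age"])

  noAge <- FeatureTable(cbind(f1 = rnorm(4)),
                        rep(c("mutant", "wildtype"), 2))
  expect_error(augmentWithClinical(noAge), "age")
})
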
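# Random-forest modelling: stratified cohort split, model-order sweep over
# ranked features, evaluation with repeat variability, decision-level
# probability fusion of the qualitative and quantitative models, and the
# cross-type Pearson correlation. The reported probability always refers
# to the wildtype class.

#' Random-forest model configuration
#'
#' @param nTree trees per forest (default 500).
#' @param nodeSize minimum terminal-node size (default 1).
#' @param mtry variables per split; `NULL` = `floor(sqrt(p))`.
#' @param repeats repeated trainings for mean +/- sd reporting (default 10).
#' @param threshold operating probability threshold for
#'   sensitivity/specificity/accuracy (default 0.5; a score >= threshold
#'   predicts wildtype).
#' @return list of settings consumed by the training functions.
#' @export
modelConfig <- function(nTree = 500L, nodeSize = 1L, mtry = NULL,
                        repeats = 10L, threshold = 0.5) {
  if (nTree < 1L) stop("nTree must be >= 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  list(nTree = as.integer(nTree), nodeSize = as.integer(nodeSize),
       mtry = mtry, repeats = as.integer(repeats), threshold = threshold)
}

#' @noRd
.fitForest <- function(X, y, config, seed) {
  # a tree cannot split when no predictor varies (possible in bootstrap
  # resamples of sparse binary traits): fall back to the class prevalence
  if (all(apply(X, 2, function(col) max(col) == min(col))))
    return(structure(list(p = mean(y == "wildtype")),
                     class = "prevalenceModel"))
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(ncol(X)))) else config$mtry
  .withSeed(seed,
    randomForest::randomForest(x = as.data.frame(X), y = y,
                               ntree = config$nTree, mtry = mtry,
                               nodesize = config$nodeSize))
}

#' @noRd
.forestProb <- function(fit, X) {
  if (inherits(fit, "prevalenceModel")) return(rep(fit$p, nrow(X)))
  unname(predict(fit, newdata = as.data.frame(X), type = "prob")[, "wildtype"])
}

#' Stratified random cohort split
#'
#' Splits subjects into training and validation sets at the given
#' fraction, stratified by class so both labels appear on both sides
#' (the near-balanced design the modelling relies on). Sizes match the
#' fraction within per-class rounding.
#'
#' @param ids subject identifiers.
#' @param labels class labels (`"mutant"`/`"wildtype"`), same length.
#' @param trainFraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @return list with `train`, `validation` (ids) and `labels` (named).
#' @examples
#' s <- splitCohort(sprintf("S%03d", 1:102),
#'                  rep(c("mutant", "wildtype"), c(50, 52)),
#'                  trainFraction = 67 / 102, seed = 1)
#' lengths(s[c("train", "validation")])  # 67, 35
#' @export
splitCohort <- function(ids, labels, trainFraction = 67 / 102, seed = 1L) {
  labels <- .assertLabels(labels)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly in (0, 1): degenerate split",
         call. = FALSE)
  if (any(table(labels) < 2L))
    stop("need at least 2 subjects per class", call. = FALSE)
  train <- character(0)
  .withSeed(.deriveSeed(seed, 0L, 10L), {
    for (cls in levels(labels)) {
      clsIds <- ids[labels == cls]
      nTrain <- round(length(clsIds) * trainFraction)
      nTrain <- min(max(nTrain, 1L), length(clsIds) - 1L)
      train <- c(train, sample(clsIds, nTrain))
    }
  })
  validation <- setdiff(ids, train)
  list(train = ids[ids %in% train], validation = validation,
       labels = setNames(as.character(labels), ids))
}

#' Train a random-forest classifier on a feature subset
#'
#' @param table a [FeatureTable-class] (training cohort, normalized).
#' @param features feature subset to use.
#' @param config configuration from [modelConfig()].
#' @param seed training seed; refitting with the same seed reproduces
#'   the ensemble and its predictions exactly.
#' @return A [TrainedModel-class] carrying the feature subset and the
#'   table's normalization bounds for later cohorts.
#' @export
trainModel <- function(table, features, config = modelConfig(), seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  y <- subjectLabels(table)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in training labels", call. = FALSE)
  X <- featureValues(subsetFeatures(table, features))
  fit <- .fitForest(X, y, config, seed)
  b <- metadata(table)$bounds
  bounds <- if (is.null(b)) data.frame() else
    b[b$feature %in% features, , drop = FALSE]
  new("TrainedModel", fit = fit, features = features, bounds = bounds,
      config = config, seed = as.integer(seed))
}

#' Predict the wildtype probability for a cohort
#'
#' Applies the model to a feature table. A table that has not been
#' normalized is first mapped with the model's stored training bounds,
#' honouring the train-only normalization contract.
#'
#' @param model a [TrainedModel-class].
#' @param table a [FeatureTable-class] containing the model's features.
#' @return Numeric vector of wildtype probabilities in [0, 1].
#' @export
predictProbability <- function(model, table) {
  stopifnot(is(model, "TrainedModel"), is(table, "FeatureTable"))
  if (!isTRUE(metadata(table)$normalized) && nrow(model@bounds) > 0)
    table <- normalizeFeatures(table, model@bounds)
  X <- featureValues(subsetFeatures(table, model@features))
  .forestProb(model@fit, X)
}

#' Mann-Whitney AUC and ROC curve
#'
#' The AUC is the pair statistic: the fraction of (wildtype, mutant)
#' score pairs ranked correctly, ties counted 1/2 — computed via mid
#' ranks. ROC points come from a threshold sweep over the unique scores
#' (predict wildtype when score >= threshold), from (0, 0) to (1, 1).
#'
#' @param scores numeric scores (higher = more wildtype-like).
#' @param labels class labels, both classes present.
#' @return list with `auc` and `roc` (data.frame of fpr, tpr).
#' @examples
#' rocAuc(c(0.9, 0.3, 0.5, 0.2),
#'        c("wildtype", "wildtype", "mutant", "mutant"))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- .assertLabels(labels)
  pos <- labels == "wildtype"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores) # mid ranks: ties count 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & pos) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !pos) / n0, numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  roc <- roc[order(roc$fpr, roc$tpr), ]
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  rownames(roc) <- NULL
  list(auc = auc, roc = roc)
}

#' Classification metrics of a score vector at a threshold
#'
#' Predicts wildtype when `score >= threshold` (the documented tie
#' rule) and reports AUC, sensitivity (wildtype recall), specificity
#' (mutant recall) and accuracy.
#'
#' @param scores wildtype probabilities.
#' @param labels class labels.
#' @param threshold operating threshold (default 0.5).
#' @return list with `metrics` (named numeric) and `roc`.
#' @export
evaluateScores <- function(scores, labels, threshold = 0.5) {
  labels <- .assertLabels(labels)
  ra <- rocAuc(scores, labels)
  predPos <- scores >= threshold
  pos <- labels == "wildtype"
  metrics <- c(auc = ra$auc,
               sensitivity = sum(predPos & pos) / sum(pos),
               specificity = sum(!predPos & !pos) / sum(!pos),
               accuracy = mean(predPos == pos))
  list(metrics = metrics, roc = ra$roc)
}

#' Evaluate a feature subset with repeated trainings
#'
#' Trains `config$repeats` forests with distinct seeds on the training
#' table, scores each on the evaluation table, and reports each metric
#' as mean +/- sd over the repeats (the repeat-variability convention
#' for validation metrics). The ROC curve uses the repeat-averaged
#' scores.
#'
#' @param trainTable training [FeatureTable-class] (normalized).
#' @param testTable evaluation [FeatureTable-class] (same feature space).
#' @param features feature subset to model.
#' @param config configuration from [modelConfig()].
#' @param seed base seed; repeat `i` uses a seed derived from it.
#' @return An [EvaluationReport-class].
#' @export
evaluateModel <- function(trainTable, testTable, features,
                          config = modelConfig(), seed = 1L) {
  reps <- config$repeats
  scoreMat <- matrix(NA_real_, ncol(testTable), reps)
  labs <- subjectLabels(testTable)
  perRep <- matrix(NA_real_, reps, 4,
                   dimnames = list(NULL, c("auc", "sensitivity",
                                           "specificity", "accuracy")))
  for (i in seq_len(reps)) {
    model <- trainModel(trainTable, features, config,
                        .deriveSeed(seed, i, 11L))
    sc <- predictProbability(model, testTable)
    scoreMat[, i] <- sc
    perRep[i, ] <- evaluateScores(sc, labs, config$threshold)$metrics
  }
  avg <- rowMeans(scoreMat)
  metrics <- data.frame(metric = colnames(perRep),
                        mean = colMeans(perRep),
                        sd = apply(perRep, 2, sd), row.names = NULL)
  new("EvaluationReport", metrics = metrics,
      roc = rocAuc(avg, labs)$roc, repeats = as.integer(reps),
      threshold = config$threshold)
}

#' Sweep model order over a ranked feature set
#'
#' For each order `k`, models the top-`k` ranked features and estimates
#' the training-cohort 0.632+ bootstrap AUC; the optimal order is the
#' argmax (ties: the smaller, more parsimonious order).
#'
#' @param selection a [SelectionResult-class] (or character vector of
#'   ranked features).
#' @param table training [FeatureTable-class].
#' @param config configuration from [modelConfig()].
#' @param B bootstrap replicates per order.
#' @param seed integer seed.
#' @return An [OrderSweepResult-class].
#' @export
sweepModelOrder <- function(selection, table, config = modelConfig(),
                            B = 100L, seed = 1L) {
  features <- if (is(selection, "SelectionResult"))
    selectedFeatures(selection) else as.character(selection)
  if (length(features) < 1L) stop("empty selection", call. = FALSE)
  ests <- lapply(seq_along(features), function(k)
    boot632Auc(table, features[seq_len(k)], config, B,
               .deriveSeed(seed, k, 12L)))
  auc <- vapply(ests, combinedAuc, numeric(1))
  new("OrderSweepResult", orders = seq_along(features), auc = auc,
      estimates = ests, optimalOrder = as.integer(which.max(auc)),
      features = features)
}

#' Decision-level probability fusion
#'
#' Weighted average of the qualitative (VASARI) and quantitative
#' (radiomics) model probabilities:
#' `w * pVasari + (1 - w) * pRadiomics`, default weight 0.5 (plain
#' average).
#'
#' @param pVasari,pRadiomics probabilities in [0, 1] (vectors of equal
#'   length).
#' @param weight fusion weight on the VASARI model, in [0, 1].
#' @return Fused probabilities.
#' @examples
#' fuseProbabilities(0.6, 0.8)  # 0.7
#' @export
fuseProbabilities <- function(pVasari, pRadiomics, weight = 0.5) {
  if (any(pVasari < 0 | pVasari > 1) || any(pRadiomics < 0 | pRadiomics > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (weight < 0 || weight > 1)
    stop("weight must lie in [0, 1]", call. = FALSE)
  weight * pVasari + (1 - weight) * pRadiomics
}

#' Pearson correlation between two feature sets
#'
#' Correlates every (VASARI feature, radiomics feature) pair over the
#' same subjects. A constant column yields r = 0 for its pairs, flagged
#' in the `degenerate` attribute.
#'
#' @param x,y [FeatureTable-class] objects over identical subjects
#'   (e.g. encoded VASARI and radiomics).
#' @return Matrix of Pearson r (rows = features of `x`), with a
#'   `degenerate` attribute naming constant features.
#' @export
featureCorrelation <- function(x, y) {
  if (!identical(colnames(x), colnames(y)))
    stop("subject ids (and order) must match", call. = FALSE)
  mx <- featureValues(x); my <- featureValues(y)
  degx <- colnames(mx)[apply(mx, 2, function(v) max(v) == min(v))]
  degy <- colnames(my)[apply(my, 2, function(v) max(v) == min(v))]
  r <- suppressWarnings(stats::cor(mx, my))
  r[is.na(r)] <- 0
  attr(r, "degenerate") <- c(degx, degy)
  r
}
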
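# Two-step feature selection: greedy minimum-redundancy maximum-relevance
# (mRMR, difference form) candidate ranking on discretized features,
# followed by single-feature 0.632+ bootstrap AUC ranking with a random
# forest, yielding ranked features with one AUC per feature.

#' Plug-in mutual information between two discrete sequences
#'
#' Estimated from the joint contingency table with base-2 logarithms
#' (`0 log 0 = 0`), in bits. `mutualInformation(x, x)` equals the
#' plug-in entropy of `x`.
#'
#' @param x,y equal-length vectors interpreted as categorical.
#' @return Mutual information in bits (>= 0).
#' @examples
#' mutualInformation(rep(0:1, 5), rep(0:1, 5))  # 1 bit
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  tab <- table(x, y)
  pxy <- tab / sum(tab)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  ind <- outer(px, py)
  keep <- pxy > 0
  sum(pxy[keep] * log2(pxy[keep] / ind[keep]))
}

# mRMR input discretization: features with few distinct values (encoded
# categorical traits, binary covariates) enter as-is; continuous features
# are cut at mean +/- sd into 3 levels.
#' @noRd
.discretizeForMi <- function(x, maxDiscrete = 6L) {
  ux <- unique(x)
  if (length(ux) <= maxDiscrete) return(match(x, sort(ux)))
  mu <- mean(x); s <- sd(x)
  findInterval(x, c(mu - s, mu + s)) + 1L
}

#' Greedy mRMR feature ranking
#'
#' Ranks features by the difference criterion: the first pick maximizes
#' relevance `I(f; y)`; each later pick maximizes
#' `I(f; y) - mean(I(f; s))` over the already-selected set `S`.
#' Continuous features are discretized at mean +/- sd into 3 levels for
#' the mutual-information estimates. Ties resolve deterministically:
#' higher score, then smaller redundancy term, then higher relevance,
#' then feature name.
#'
#' @param table a [FeatureTable-class] with both classes present.
#' @param poolSize number of features to rank (default: all).
#' @return Character vector of ranked feature names.
#' @export
mrmrRank <- function(table, poolSize = nrow(table)) {
  stopifnot(is(table, "FeatureTable"))
  y <- subjectLabels(table)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (nrow(table) < 2L && poolSize > 1L)
    stop("need at least 2 features", call. = FALSE)
  poolSize <- min(poolSize, nrow(table))
  vals <- featureValues(table)
  disc <- apply(vals, 2, .discretizeForMi)
  feats <- colnames(vals)
  rel <- vapply(feats, function(f) mutualInformation(disc[, f], y), numeric(1))

  redCache <- matrix(NA_real_, length(feats), length(feats),
                     dimnames = list(feats, feats))
  red <- function(a, b) {
    if (is.na(redCache[a, b])) {
      v <- mutualInformation(disc[, a], disc[, b])
      redCache[a, b] <<- v
      redCache[b, a] <<- v
    }
    redCache[a, b]
  }

  selected <- character(0)
  remaining <- feats
  for (step in seq_len(poolSize)) {
    if (length(selected) == 0L) {
      redTerm <- setNames(rep(0, length(remaining)), remaining)
    } else {
      redTerm <- vapply(remaining, function(f)
        mean(vapply(selected, function(s) red(f, s), numeric(1))), numeric(1))
    }
    score <- rel[remaining] - redTerm
    ord <- order(-score, redTerm, -rel[remaining], remaining)
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

#' Combine apparent and out-of-bag AUC with the 0.632+ rule
#'
#' The relative overfitting rate is
#' `R = (apparent - oob) / (apparent - 0.5)`, clipped to [0, 1] and set
#' to 0 when the apparent AUC is at or below the 0.5 no-information
#' level; the weight is `w = 0.632 / (1 - 0.368 R)` and the combined
#' estimate `(1 - w) * apparent + w * oob`.
#'
#' @param apparent apparent (resubstitution) AUC.
#' @param oob mean out-of-bag AUC.
#' @return list with `R`, `w` and `combined`.
#' @examples
#' combine632(0.9, 0.7)  # R = 0.5, w = 0.632/0.816
#' @export
combine632 <- function(apparent, oob) {
  R <- if (apparent <= 0.5) 0 else (apparent - oob) / (apparent - 0.5)
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  list(R = R, w = w, combined = (1 - w) * apparent + w * oob)
}

#' 0.632+ bootstrap AUC of a random-forest model
#'
#' For each of `B` bootstrap replicates, trains the classifier on an
#' n-with-replacement resample and scores the out-of-bag subjects; the
#' out-of-bag AUC is the mean over replicates whose out-of-bag set (and
#' resample) contain both classes — others are skipped and counted.
#' The apparent AUC comes from training on and scoring the full set,
#' and the two are blended with [combine632()].
#'
#' @param table a [FeatureTable-class].
#' @param features feature subset to model.
#' @param config model configuration from [modelConfig()].
#' @param B bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @return A [Boot632Estimate-class].
#' @export
boot632Auc <- function(table, features, config = modelConfig(), B = 100L,
                       seed = 1L) {
  stopifnot(is(table, "FeatureTable"))
  if (B < 2L) stop("B must be >= 2", call. = FALSE)
  y <- subjectLabels(table)
  if (length(unique(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  X <- featureValues(subsetFeatures(table, features))
  n <- nrow(X)

  apparentFit <- .fitForest(X, y, config, .deriveSeed(seed, 0L, 6L))
  apparent <- rocAuc(.forestProb(apparentFit, X), y)$auc

  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- .withSeed(.deriveSeed(seed, b, 7L), sample.int(n, n, replace = TRUE))
    oobIdx <- setdiff(seq_len(n), idx)
    if (length(unique(y[idx])) < 2L || length(unique(y[oobIdx])) < 2L)
      next
    fit <- .fitForest(X[idx, , drop = FALSE], y[idx], config,
                      .deriveSeed(seed, b, 8L))
    reps[b] <- rocAuc(.forestProb(fit, X[oobIdx, , drop = FALSE]),
                      y[oobIdx])$auc
  }
  nSkipped <- sum(is.na(reps))
  if (nSkipped == B)
    stop("all ", B, " bootstrap replicates had a single-class out-of-bag set",
         call. = FALSE)
  oob <- mean(reps, na.rm = TRUE)
  cmb <- combine632(apparent, oob)
  new("Boot632Estimate", apparent = apparent, oob = oob,
      overfitRate = cmb$R, weight = cmb$w, combined = cmb$combined,
      replicates = reps, nSkipped = as.integer(nSkipped))
}

#' Two-step feature selection (mRMR pool, then bootstrap AUC ranking)
#'
#' Runs [mrmrRank()] to form a candidate pool, estimates each pool
#' feature's single-feature 0.632+ bootstrap AUC with [boot632Auc()],
#' and returns the top `k` by AUC (ties: feature name), each with its
#' AUC attached — the shape of a selected-feature table.
#'
#' @param table a [FeatureTable-class] (training cohort).
#' @param k features to keep (<= `poolSize`).
#' @param poolSize mRMR candidate pool size.
#' @param B bootstrap replicates per feature.
#' @param config model configuration from [modelConfig()].
#' @param seed integer seed.
#' @return A [SelectionResult-class].
#' @export
selectTopFeatures <- function(table, k, poolSize = min(30L, nrow(table)),
                              B = 100L, config = modelConfig(), seed = 1L) {
  poolSize <- min(poolSize, nrow(table))
  if (k > poolSize)
    stop("k must not exceed poolSize", call. = FALSE)
  pool <- mrmrRank(table, poolSize)
  ests <- lapply(seq_along(pool), function(i)
    boot632Auc(table, pool[i], config, B, .deriveSeed(seed, i, 9L)))
  auc <- vapply(ests, combinedAuc, numeric(1))
  ord <- order(-auc, pool)[seq_len(k)]
  new("SelectionResult", feature = pool[ord], auc = auc[ord],
      estimates = ests[ord], pool = pool, B = as.integer(B),
      seed = as.integer(seed))
}
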
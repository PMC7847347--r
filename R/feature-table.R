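# FeatureTable operations: [0,1] normalization with training-cohort bounds,
# and clinical covariate augmentation.

#' Normalize feature columns to [0, 1]
#'
#' Affine per-feature rescaling `x' = (x - min) / (max - min)`. When
#' `bounds` is `NULL` the bounds are computed from the table itself (the
#' training cohort) and stored in its metadata; passing a training
#' table's bounds maps a validation cohort onto the training scale, with
#' out-of-bounds values clipped to [0, 1]. A constant column maps to 0
#' and is flagged in the stored bounds.
#'
#' @param table a [FeatureTable-class].
#' @param bounds optional data.frame with columns `feature`, `min`,
#'   `max` (as produced by a previous normalization; see [normBounds()]).
#' @return A normalized [FeatureTable-class] carrying its bounds.
#' @examples
#' ft <- FeatureTable(cbind(f1 = c(2, 4, 6), f2 = c(1, 1, 1)),
#'                    labels = c("mutant", "wildtype", "mutant"))
#' featureValues(normalizeFeatures(ft))[, "f1"]  # 0, 0.5, 1
#' @export
normalizeFeatures <- function(table, bounds = NULL) {
  stopifnot(is(table, "FeatureTable"))
  m <- assay(table) # features x subjects
  if (is.null(bounds)) {
    bounds <- data.frame(feature = rownames(m),
                         min = apply(m, 1, min),
                         max = apply(m, 1, max),
                         degenerate = apply(m, 1, function(r)
                           max(r) == min(r)),
                         row.names = NULL)
  } else {
    missing <- setdiff(rownames(m), bounds$feature)
    if (length(missing))
      stop("bounds lack feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    bounds <- bounds[match(rownames(m), bounds$feature), , drop = FALSE]
    if (is.null(bounds$degenerate)) bounds$degenerate <- bounds$max == bounds$min
  }
  rng <- bounds$max - bounds$min
  scaled <- (m - bounds$min) / ifelse(rng > 0, rng, 1)
  scaled[bounds$degenerate | rng <= 0, ] <- 0
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  out <- table
  SummarizedExperiment::assay(out) <- scaled
  metadata(out)$bounds <- bounds
  metadata(out)$normalized <- TRUE
  out
}

#' Append age and gender as model features
#'
#' Adds an `Age` column (years) and a binary `Gender` column (male = 1)
#' to the feature table; when the table is normalized the new columns
#' are rescaled the same way. Dropping the two columns again recovers
#' the original table.
#'
#' @param table a [FeatureTable-class].
#' @param age numeric vector of ages; defaults to the `age` covariate
#'   carried in `colData`.
#' @param gender `"M"`/`"F"` (or 0/1) vector; defaults to the `gender`
#'   covariate.
#' @param bounds optional bounds for the two new columns (from a
#'   training table), with the same shape as [normBounds()].
#' @return A [FeatureTable-class] with two extra features.
#' @export
augmentWithClinical <- function(table, age = NULL, gender = NULL,
                                bounds = NULL) {
  stopifnot(is(table, "FeatureTable"))
  cd <- colData(table)
  if (is.null(age)) age <- cd$age
  if (is.null(gender)) gender <- cd$gender
  if (is.null(age) || anyNA(age))
    stop("missing covariate: age", call. = FALSE)
  if (is.null(gender) || anyNA(gender))
    stop("missing covariate: gender", call. = FALSE)
  if (length(age) != ncol(table) || length(gender) != ncol(table))
    stop("covariate length must match subject count", call. = FALSE)
  g <- if (is.character(gender) || is.factor(gender))
    as.numeric(as.character(gender) == "M") else as.numeric(gender)
  extra <- rbind(Age = as.numeric(age), Gender = g)
  colnames(extra) <- colnames(table)

  normalized <- isTRUE(metadata(table)$normalized)
  if (normalized) {
    if (is.null(bounds)) {
      bounds <- data.frame(feature = c("Age", "Gender"),
                           min = apply(extra, 1, min),
                           max = apply(extra, 1, max),
                           degenerate = apply(extra, 1, function(r)
                             max(r) == min(r)),
                           row.names = NULL)
    }
    b <- bounds[match(rownames(extra), bounds$feature), , drop = FALSE]
    rng <- b$max - b$min
    extra <- (extra - b$min) / ifelse(rng > 0, rng, 1)
    extra[b$degenerate | rng <= 0, ] <- 0
    extra[extra < 0] <- 0
    extra[extra > 1] <- 1
  }
  m <- rbind(assay(table), extra)
  out <- FeatureTable(t(m), labels = subjectLabels(table),
                      subjectIds = colnames(table))
  metadata(out) <- metadata(table)
  if (normalized)
    metadata(out)$bounds <- rbind(
      metadata(table)$bounds,
      bounds[match(rownames(extra), bounds$feature), , drop = FALSE])
  out
}

#' Subset a FeatureTable to named features
#'
#' @param table a [FeatureTable-class].
#' @param features character vector of feature names to keep.
#' @return A [FeatureTable-class] restricted to those rows.
#' @export
subsetFeatures <- function(table, features) {
  missing <- setdiff(features, rownames(table))
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  table[features, ]
}

#' Combine two FeatureTables over the same subjects
#'
#' Row-binds the feature sets of two tables (e.g. encoded VASARI and
#' radiomics) after checking subject order and labels agree.
#'
#' @param x,y [FeatureTable-class] objects over identical subjects.
#' @return A [FeatureTable-class] with both feature sets.
#' @export
combineFeatures <- function(x, y) {
  if (!identical(colnames(x), colnames(y)))
    stop("subject ids differ between tables", call. = FALSE)
  if (!identical(as.character(subjectLabels(x)),
                 as.character(subjectLabels(y))))
    stop("labels differ between tables", call. = FALSE)
  out <- FeatureTable(cbind(featureValues(x), featureValues(y)),
                      labels = subjectLabels(x), subjectIds = colnames(x))
  metadata(out) <- metadata(x)
  out
}
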
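#' MaskedVolume: a 3-D ADC map with its tumor mask
#'
#' Container for one subject's apparent-diffusion-coefficient volume
#' (units 10^-3 mm^2/s), the co-registered binary volume of interest,
#' and the voxel spacing in mm. All feature extraction operates on the
#' in-mask voxels only.
#'
#' @slot intensities 3-D numeric array of ADC values.
#' @slot mask 3-D logical array of the same dimensions; `TRUE` = tumor.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @export
setClass("MaskedVolume",
  representation(intensities = "array", mask = "array", spacing = "numeric"))

setValidity("MaskedVolume", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3-D array")
  if (!identical(dim(object@intensities), dim(object@mask)))
    msg <- c(msg, "mask and intensities must have identical dimensions")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (sum(object@mask) < 1L)
    msg <- c(msg, "mask must contain at least one foreground voxel")
  if (!all(is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a MaskedVolume
#'
#' @param intensities 3-D numeric array of ADC values (10^-3 mm^2/s).
#' @param mask 3-D logical (or 0/1) array of the same shape.
#' @param spacing voxel spacing in mm, length 3.
#' @return A [MaskedVolume-class] object.
#' @examples
#' vol <- MaskedVolume(array(rnorm(27, 1.2, 0.1), c(3, 3, 3)),
#'                     array(TRUE, c(3, 3, 3)), c(1, 1, 1))
#' @export
MaskedVolume <- function(intensities, mask, spacing = c(1, 1, 1)) {
  storage.mode(intensities) <- "double"
  if (!is.logical(mask)) {
    mask <- array(mask != 0, dim = dim(mask))
  }
  new("MaskedVolume", intensities = intensities, mask = mask,
      spacing = as.numeric(spacing))
}

setMethod("show", "MaskedVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("MaskedVolume %dx%dx%d, spacing %s mm, %d mask voxels\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              sum(object@mask)))
  v <- object@intensities[object@mask]
  cat(sprintf("  in-mask ADC: %.3f - %.3f (median %.3f)\n",
              min(v), max(v), median(v)))
})

#' GrayLevelVolume: quantized masked volume
#'
#' @slot levels 3-D integer array; 1..nLevels inside the mask, 0 outside.
#' @slot nLevels number of gray levels used for quantization.
#' @slot range numeric length-2, the in-mask (min, max) the bins span.
#' @slot degenerate logical; `TRUE` when the in-mask intensity was constant.
#' @export
setClass("GrayLevelVolume",
  representation(levels = "array", nLevels = "integer", range = "numeric",
                 degenerate = "logical"))

setValidity("GrayLevelVolume", function(object) {
  v <- object@levels[object@levels > 0L]
  if (object@nLevels < 2L) return("nLevels must be >= 2")
  if (length(v) && (min(v) < 1L || max(v) > object@nLevels))
    return("in-mask levels must lie in [1, nLevels]")
  TRUE
})

setMethod("show", "GrayLevelVolume", function(object) {
  cat(sprintf("GrayLevelVolume: Ng=%d over [%.4g, %.4g]%s\n",
              object@nLevels, object@range[1], object@range[2],
              if (object@degenerate) " (degenerate: constant input)" else ""))
})

#' TextureMatrices: the four gray-level texture matrices of one volume
#'
#' GLCM and GLRLM are accumulated over the 13 unique 3-D directions at
#' Chebyshev distance 1 and merged; the per-direction run matrices are
#' retained so the run-mass conservation can be checked per direction.
#'
#' @slot glcm Ng x Ng symmetric matrix, normalized to sum 1.
#' @slot glrlm Ng x Rmax run-count matrix merged over directions.
#' @slot glrlmByDirection list of the 13 per-direction run-count matrices.
#' @slot glszm Ng x Zmax zone-count matrix (26-connectivity).
#' @slot ngtdm list with `s` (per-level gray-tone difference totals) and
#'   `n` (per-level voxel counts over voxels with >= 1 in-mask neighbour).
#' @slot nVoxels in-mask voxel count.
#' @slot nLevels number of gray levels.
#' @export
setClass("TextureMatrices",
  representation(glcm = "matrix", glrlm = "matrix",
                 glrlmByDirection = "list", glszm = "matrix",
                 ngtdm = "list", nVoxels = "integer", nLevels = "integer"))

setMethod("show", "TextureMatrices", function(object) {
  cat(sprintf(
    "TextureMatrices: Ng=%d, %d voxels; GLRLM %d directions, GLSZM %d zones\n",
    object@nLevels, object@nVoxels, length(object@glrlmByDirection),
    sum(object@glszm)))
})

#' FeatureTable: per-subject feature values with class labels
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment]
#' holding features as rows and subjects as columns, the IDH1 label in
#' `colData`, and (once normalized) the per-feature training bounds in
#' `metadata` so validation data can be mapped with the training scale.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"label" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'label' column")
  else if (!all(as.character(colData(object)$label) %in% .CLASS_LEVELS))
    msg <- c(msg, "labels must be 'mutant' or 'wildtype'")
  if (anyNA(assay(object)))
    msg <- c(msg, "feature matrix must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix of feature values, subjects in rows and
#'   features in columns (the natural analysis orientation; stored
#'   transposed, features x subjects).
#' @param labels character/factor of `"mutant"`/`"wildtype"`, one per subject.
#' @param subjectIds optional subject identifiers (default: rownames).
#' @param covariates optional data.frame of extra per-subject columns
#'   (e.g. age, gender) stored in `colData`.
#' @return A [FeatureTable-class].
#' @examples
#' ft <- FeatureTable(matrix(rnorm(20), 5, 4,
#'                           dimnames = list(NULL, paste0("f", 1:4))),
#'                    labels = c("mutant", "mutant", "wildtype",
#'                               "wildtype", "mutant"))
#' @export
FeatureTable <- function(values, labels, subjectIds = NULL, covariates = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  if (is.null(subjectIds)) {
    subjectIds <- rownames(values)
    if (is.null(subjectIds)) subjectIds <- sprintf("S%03d", seq_len(nrow(values)))
  }
  labels <- .assertLabels(labels)
  stopifnot(length(labels) == nrow(values))
  cd <- DataFrame(label = labels, row.names = subjectIds)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == nrow(values))
    for (nm in colnames(covariates)) cd[[nm]] <- covariates[[nm]]
  }
  se <- SummarizedExperiment(assays = list(features = t(values)), colData = cd)
  new("FeatureTable", se)
}

setMethod("show", "FeatureTable", function(object) {
  tab <- table(subjectLabels(object))
  cat(sprintf("FeatureTable: %d features x %d subjects (%d mutant, %d wildtype)%s\n",
              nrow(object), ncol(object), tab[["mutant"]], tab[["wildtype"]],
              if (isTRUE(metadata(object)$normalized)) ", normalized to [0,1]"
              else ""))
})

#' Boot632Estimate: a 0.632+ bootstrap AUC estimate
#'
#' @slot apparent AUC of the model trained and scored on the full set.
#' @slot oob mean out-of-bag AUC over bootstrap replicates.
#' @slot overfitRate relative overfitting rate R, clipped to [0, 1].
#' @slot weight w = 0.632 / (1 - 0.368 R).
#' @slot combined (1 - w) apparent + w oob.
#' @slot replicates per-replicate out-of-bag AUCs (NA where skipped).
#' @slot nSkipped replicates skipped for a single-class out-of-bag set.
#' @export
setClass("Boot632Estimate",
  representation(apparent = "numeric", oob = "numeric",
                 overfitRate = "numeric", weight = "numeric",
                 combined = "numeric", replicates = "numeric",
                 nSkipped = "integer"))

setValidity("Boot632Estimate", function(object) {
  msg <- character()
  if (object@overfitRate < 0 || object@overfitRate > 1)
    msg <- c(msg, "overfitRate must lie in [0, 1]")
  w0 <- 0.632 / (1 - 0.368 * object@overfitRate)
  if (abs(object@weight - w0) > 1e-9)
    msg <- c(msg, "weight must equal 0.632/(1 - 0.368 R)")
  comb <- (1 - object@weight) * object@apparent + object@weight * object@oob
  if (abs(object@combined - comb) > 1e-9)
    msg <- c(msg, "combined must equal (1-w) apparent + w oob")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Boot632Estimate", function(object) {
  cat(sprintf(
    "0.632+ bootstrap AUC: %.3f (apparent %.3f, oob %.3f +/- %.3f, R %.3f, w %.3f, B=%d, %d skipped)\n",
    object@combined, object@apparent, object@oob,
    sd(object@replicates, na.rm = TRUE), object@overfitRate, object@weight,
    length(object@replicates), object@nSkipped))
})

#' SelectionResult: ranked features with per-feature bootstrap AUCs
#'
#' The canonical selected-feature table shape: feature names
#' sorted by their single-feature 0.632+ bootstrap AUC, with the mRMR
#' candidate pool and bootstrap provenance attached.
#'
#' @slot feature ranked feature names (AUC descending).
#' @slot auc per-feature combined 0.632+ AUC.
#' @slot estimates list of [Boot632Estimate-class], one per feature.
#' @slot pool the mRMR candidate pool the ranking drew from.
#' @slot B bootstrap replicates per feature.
#' @slot seed base seed.
#' @export
setClass("SelectionResult",
  representation(feature = "character", auc = "numeric", estimates = "list",
                 pool = "character", B = "integer", seed = "integer"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@feature) != length(object@auc))
    msg <- c(msg, "feature and auc lengths differ")
  if (any(object@auc < 0 | object@auc > 1))
    msg <- c(msg, "AUCs must lie in [0, 1]")
  if (is.unsorted(rev(object@auc)))
    msg <- c(msg, "ranking must be sorted by AUC, descending")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: top %d of a pool of %d (B=%d)\n",
              length(object@feature), length(object@pool), object@B))
  print(data.frame(feature = object@feature,
                   AUC = round(object@auc, 3)), row.names = FALSE)
})

#' TrainedModel: a fitted random-forest classifier with provenance
#'
#' @slot fit the fitted ensemble (opaque).
#' @slot features feature subset the model uses, in registry order.
#' @slot bounds per-feature normalization bounds carried from training.
#' @slot config model configuration list (see [modelConfig()]).
#' @slot seed training seed.
#' @export
setClass("TrainedModel",
  representation(fit = "ANY", features = "character", bounds = "data.frame",
                 config = "list", seed = "integer"))

setValidity("TrainedModel", function(object) {
  if (length(object@features) < 1L) return("feature subset must be non-empty")
  TRUE
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: random forest (%d trees) on %d feature(s)\n",
              object@config$nTree, length(object@features)))
  cat("  ", paste(object@features, collapse = ", "), "\n")
})

#' EvaluationReport: classification metrics with repeat variability
#'
#' AUC, sensitivity, specificity and accuracy as mean and sd over
#' repeated trainings with distinct seeds, plus the ROC curve of the
#' repeat-averaged scores.
#'
#' @slot metrics data.frame with columns metric, mean, sd.
#' @slot roc data.frame with columns fpr, tpr (threshold sweep).
#' @slot repeats number of repeated trainings.
#' @slot threshold operating threshold for sensitivity/specificity/accuracy.
#' @export
setClass("EvaluationReport",
  representation(metrics = "data.frame", roc = "data.frame",
                 repeats = "integer", threshold = "numeric"))

setValidity("EvaluationReport", function(object) {
  m <- object@metrics
  if (!all(c("metric", "mean", "sd") %in% colnames(m)))
    return("metrics needs columns metric, mean, sd")
  if (any(m$mean < 0 | m$mean > 1)) return("metric means must lie in [0, 1]")
  r <- object@roc
  if (nrow(r) && (is.unsorted(r$fpr) || is.unsorted(r$tpr)))
    return("ROC must be monotone nondecreasing")
  TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (threshold %.2f, %d repeats):\n",
              object@threshold, object@repeats))
  m <- object@metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-11s %.3f +/- %.3f\n", m$metric[i], m$mean[i], m$sd[i]))
})

#' OrderSweepResult: bootstrap AUC across model orders
#'
#' @slot orders model orders evaluated (1..k).
#' @slot auc combined 0.632+ bootstrap AUC per order.
#' @slot estimates list of [Boot632Estimate-class] per order.
#' @slot optimalOrder order maximizing the bootstrap AUC (ties: smaller).
#' @slot features the ranked features the orders prefix.
#' @export
setClass("OrderSweepResult",
  representation(orders = "integer", auc = "numeric", estimates = "list",
                 optimalOrder = "integer", features = "character"))

setMethod("show", "OrderSweepResult", function(object) {
  cat(sprintf("OrderSweepResult: orders 1..%d, optimal %d (AUC %.3f)\n",
              max(object@orders), object@optimalOrder,
              object@auc[object@optimalOrder]))
})

#' SyntheticConfig: parameters of the synthetic cohort generator
#'
#' See [syntheticConfig()] for field semantics and defaults.
#' @export
setClass("SyntheticConfig",
  representation(nSubjects = "integer", mutantFraction = "numeric",
                 volumeShape = "integer", voxelSpacing = "numeric",
                 tumorRadiusRange = "numeric", adcBackgroundMean = "numeric",
                 adcBackgroundSd = "numeric", necrosisMean = "numeric",
                 necrosisSd = "numeric", baseTextureSigma = "numeric",
                 textureSigmaSd = "numeric",
                 baseNecrosisRate = "numeric", baseEccentricity = "numeric",
                 eccentricitySd = "numeric", classEffects = "list",
                 clinicalEffects = "list", vasariConditionals = "list",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 4L)
    msg <- c(msg, "nSubjects: must be >= 4")
  if (object@mutantFraction <= 0 || object@mutantFraction >= 1)
    msg <- c(msg, "mutantFraction: must lie strictly in (0, 1)")
  if (length(object@volumeShape) != 3L || any(object@volumeShape < 4L))
    msg <- c(msg, "volumeShape: three voxel counts >= 4")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing: three positive mm values")
  if (length(object@tumorRadiusRange) != 2L ||
      any(object@tumorRadiusRange <= 0) ||
      diff(object@tumorRadiusRange) < 0)
    msg <- c(msg, "tumorRadiusRange: increasing positive (min, max) mm")
  if (object@adcBackgroundSd < 0) msg <- c(msg, "adcBackgroundSd: must be >= 0")
  if (object@necrosisSd < 0) msg <- c(msg, "necrosisSd: must be >= 0")
  if (object@baseTextureSigma < 0) msg <- c(msg, "baseTextureSigma: must be >= 0")
  if (object@textureSigmaSd < 0) msg <- c(msg, "textureSigmaSd: must be >= 0")
  if (object@baseNecrosisRate < 0) msg <- c(msg, "baseNecrosisRate: must be >= 0")
  needed <- c("minShift", "necrosisRate", "textureShift", "eccentricityShift")
  miss <- setdiff(needed, names(object@classEffects))
  if (length(miss))
    msg <- c(msg, paste0("classEffects: missing ", paste(miss, collapse = ", ")))
  for (trait in names(object@vasariConditionals)) {
    p <- object@vasariConditionals[[trait]]
    if (!is.matrix(p) || nrow(p) != 2L ||
        any(abs(rowSums(p) - 1) > 1e-9) || any(p < 0))
      msg <- c(msg, paste0("vasariConditionals: trait '", trait,
                           "' rows must be probabilities summing to 1"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d subjects (mutant fraction %.3f), volume %s, seed %d\n",
    object@nSubjects, object@mutantFraction,
    paste(object@volumeShape, collapse = "x"), object@seed))
  ce <- object@classEffects
  cat(sprintf("  effects: minShift %.2f, necrosisRate %.2f, textureShift %.2f, eccentricityShift %.2f\n",
              ce$minShift, ce$necrosisRate, ce$textureShift,
              ce$eccentricityShift))
})

#' SyntheticCohort: a generated cohort of subjects
#'
#' @slot subjects list of per-subject lists with elements `id`, `volume`
#'   ([MaskedVolume-class]), `vasari` (named character), `label`, `age`,
#'   `gender`.
#' @slot config the [SyntheticConfig-class] that produced it.
#' @export
setClass("SyntheticCohort",
  representation(subjects = "list", config = "SyntheticConfig"))

setValidity("SyntheticCohort", function(object) {
  ids <- vapply(object@subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) return("subject ids must be unique")
  labs <- vapply(object@subjects, `[[`, character(1), "label")
  if (!all(labs %in% .CLASS_LEVELS)) return("labels must be mutant/wildtype")
  TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  labs <- cohortLabels(object)
  cat(sprintf("SyntheticCohort: %d subjects (%d mutant, %d wildtype), seed %d\n",
              length(object@subjects), sum(labs == "mutant"),
              sum(labs == "wildtype"), object@config@seed))
})
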
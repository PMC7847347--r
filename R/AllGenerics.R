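# Accessor generics. Slot access from user code goes through these.

#' Access the intensity array of a MaskedVolume
#' @param x a [MaskedVolume-class].
#' @return 3-D numeric array.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname intensities
#' @export
setMethod("intensities", "MaskedVolume", function(x) x@intensities)

#' Access the binary tumor mask
#' @param x a [MaskedVolume-class].
#' @return 3-D logical array.
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname tumorMask
#' @export
setMethod("tumorMask", "MaskedVolume", function(x) x@mask)

#' Access voxel spacing (mm)
#' @param x a [MaskedVolume-class].
#' @return numeric length 3.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "MaskedVolume", function(x) x@spacing)

#' Feature values as a subjects-by-features matrix
#' @param x a [FeatureTable-class].
#' @return numeric matrix, subjects in rows.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureTable", function(x) t(assay(x)))

#' Subject class labels
#' @param x a [FeatureTable-class] or [SyntheticCohort-class].
#' @return factor with levels mutant, wildtype.
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))
#' @rdname subjectLabels
#' @export
setMethod("subjectLabels", "FeatureTable", function(x)
  factor(as.character(colData(x)$label), levels = .CLASS_LEVELS))

#' Per-feature normalization bounds
#'
#' `NULL` until [normalizeFeatures()] has been applied; afterwards a
#' data.frame with columns feature, min, max (training-cohort scale).
#' @param x a [FeatureTable-class].
#' @export
setGeneric("normBounds", function(x) standardGeneric("normBounds"))
#' @rdname normBounds
#' @export
setMethod("normBounds", "FeatureTable", function(x) metadata(x)$bounds)

#' Labels of a synthetic cohort
#' @rdname subjectLabels
#' @export
setMethod("subjectLabels", "SyntheticCohort", function(x) cohortLabels(x))

#' Ranked features of a SelectionResult
#' @param x a [SelectionResult-class].
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@feature)

#' Per-feature 0.632+ bootstrap AUCs of a SelectionResult
#' @param x a [SelectionResult-class].
#' @export
setGeneric("featureAuc", function(x) standardGeneric("featureAuc"))
#' @rdname featureAuc
#' @export
setMethod("featureAuc", "SelectionResult", function(x)
  setNames(x@auc, x@feature))

#' Feature subset used by a TrainedModel
#' @param x a [TrainedModel-class].
#' @export
setGeneric("modelFeatures", function(x) standardGeneric("modelFeatures"))
#' @rdname modelFeatures
#' @export
setMethod("modelFeatures", "TrainedModel", function(x) x@features)

#' Metric table of an EvaluationReport
#' @param x an [EvaluationReport-class].
#' @return data.frame with columns metric, mean, sd.
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname reportMetrics
#' @export
setMethod("reportMetrics", "EvaluationReport", function(x) x@metrics)

#' ROC points of an EvaluationReport
#' @param x an [EvaluationReport-class].
#' @return data.frame with columns fpr, tpr.
#' @export
setGeneric("reportRoc", function(x) standardGeneric("reportRoc"))
#' @rdname reportRoc
#' @export
setMethod("reportRoc", "EvaluationReport", function(x) x@roc)

#' Combined 0.632+ AUC of a Boot632Estimate
#' @param x a [Boot632Estimate-class].
#' @export
setGeneric("combinedAuc", function(x) standardGeneric("combinedAuc"))
#' @rdname combinedAuc
#' @export
setMethod("combinedAuc", "Boot632Estimate", function(x) x@combined)
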
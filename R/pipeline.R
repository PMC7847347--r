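# End-to-end workflow: simulate (or ingest) -> extract -> encode -> select
# -> sweep/train -> evaluate -> fuse -> report, with one master seed and a
# provenance manifest. Stage outputs are plain CSV/JSON files.

#' Configure the end-to-end pipeline
#'
#' Defaults encode the analysis design: top-5 VASARI and
#' top-10 radiomics features, model orders swept 1-5 and 1-10 on the
#' training cohort by 0.632+ bootstrap AUC, a 67:35 stratified split
#' and decision fusion at weight 0.5.
#'
#' @param synthetic a [SyntheticConfig-class]; its seed is overridden by
#'   `seed`.
#' @param nLevels gray levels for radiomics quantization.
#' @param kVasari,kRadiomics features kept per type.
#' @param poolVasari,poolRadiomics mRMR pool sizes.
#' @param B bootstrap replicates for selection and order sweeps.
#' @param model a [modelConfig()] list.
#' @param weight fusion weight on the VASARI model.
#' @param trainFraction training fraction of the cohort split.
#' @param includeClinical also evaluate a fusion model whose radiomics
#'   arm carries age and gender.
#' @param seed master seed for the whole run.
#' @return list of validated pipeline settings.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           nLevels = 32L, kVasari = 5L, kRadiomics = 10L,
                           poolVasari = 23L, poolRadiomics = 30L,
                           B = 100L, model = modelConfig(), weight = 0.5,
                           trainFraction = 67 / 102,
                           includeClinical = TRUE, seed = 1L) {
  synthetic@seed <- as.integer(seed)
  validObject(synthetic)
  list(synthetic = synthetic, nLevels = as.integer(nLevels),
       kVasari = as.integer(kVasari), kRadiomics = as.integer(kRadiomics),
       poolVasari = as.integer(poolVasari),
       poolRadiomics = as.integer(poolRadiomics), B = as.integer(B),
       model = model, weight = weight, trainFraction = trainFraction,
       includeClinical = isTRUE(includeClinical), seed = as.integer(seed))
}

# Fusion evaluation: per repeat, train both arms, fuse validation scores.
#' @noRd
.evaluateFusion <- function(trainV, testV, featV, trainR, testR, featR,
                            weight, config, seed) {
  reps <- config$repeats
  labs <- subjectLabels(testV)
  scoreMat <- matrix(NA_real_, ncol(testV), reps)
  perRep <- matrix(NA_real_, reps, 4,
                   dimnames = list(NULL, c("auc", "sensitivity",
                                           "specificity", "accuracy")))
  for (i in seq_len(reps)) {
    mv <- trainModel(trainV, featV, config, .deriveSeed(seed, i, 13L))
    mr <- trainModel(trainR, featR, config, .deriveSeed(seed, i, 14L))
    fused <- fuseProbabilities(predictProbability(mv, testV),
                               predictProbability(mr, testR), weight)
    scoreMat[, i] <- fused
    perRep[i, ] <- evaluateScores(fused, labs, config$threshold)$metrics
  }
  metrics <- data.frame(metric = colnames(perRep), mean = colMeans(perRep),
                        sd = apply(perRep, 2, sd), row.names = NULL)
  new("EvaluationReport", metrics = metrics,
      roc = rocAuc(rowMeans(scoreMat), labs)$roc,
      repeats = as.integer(reps), threshold = config$threshold)
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a cohort, splits it (stratified), extracts and normalizes
#' the 56 radiomics features (validation mapped with training bounds),
#' encodes the VASARI records, selects features on the training side
#' only, sweeps model orders by training bootstrap AUC, evaluates the
#' two optimal models and their weight-0.5 fusion on the validation
#' cohort, and computes the cross-type Pearson correlation and the
#' cohort balance table. With `outDir` set, every stage lands as a
#' plain CSV/JSON file and a manifest records config, seed and output
#' hashes.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir optional output directory for stage files.
#' @return list with elements `cohort`, `split`, `radiomics`, `vasari`
#'   (per-side [FeatureTable-class]s), `selection`, `sweep`, `reports`
#'   (VASARI, radiomics, fused, optionally fusedClinical
#'   [EvaluationReport-class]s), `correlation`, `balance`, `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL) {
  seed <- config$seed
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  cohort <- stage("simulate", generateCohort(config$synthetic))
  ids <- vapply(cohort@subjects, `[[`, character(1), "id")
  labels <- cohortLabels(cohort)

  split <- stage("split",
    splitCohort(ids, labels, config$trainFraction, .deriveSeed(seed, 1L, 15L)))
  trIdx <- match(split$train, ids)
  vaIdx <- match(split$validation, ids)

  radAll <- stage("extract", extractCohortFeatures(cohort, config$nLevels))
  vasRecords <- do.call(rbind, lapply(cohort@subjects, function(s)
    as.data.frame(as.list(s$vasari), check.names = FALSE)))
  vasAll <- stage("encode",
    encodeVasariRecords(vasRecords, labels, subjectIds = ids))

  radTrain <- stage("normalize", normalizeFeatures(radAll[, trIdx]))
  radVal <- normalizeFeatures(radAll[, vaIdx], normBounds(radTrain))
  vasTrain <- normalizeFeatures(vasAll[, trIdx])
  vasVal <- normalizeFeatures(vasAll[, vaIdx], normBounds(vasTrain))

  selV <- stage("select-vasari",
    selectTopFeatures(vasTrain, config$kVasari, config$poolVasari,
                      config$B, config$model, .deriveSeed(seed, 2L, 16L)))
  selR <- stage("select-radiomics",
    selectTopFeatures(radTrain, config$kRadiomics, config$poolRadiomics,
                      config$B, config$model, .deriveSeed(seed, 3L, 17L)))

  swV <- stage("sweep-vasari",
    sweepModelOrder(selV, vasTrain, config$model, config$B,
                    .deriveSeed(seed, 4L, 18L)))
  swR <- stage("sweep-radiomics",
    sweepModelOrder(selR, radTrain, config$model, config$B,
                    .deriveSeed(seed, 5L, 19L)))
  featV <- selectedFeatures(selV)[seq_len(swV@optimalOrder)]
  featR <- selectedFeatures(selR)[seq_len(swR@optimalOrder)]

  repV <- stage("evaluate-vasari",
    evaluateModel(vasTrain, vasVal, featV, config$model,
                  .deriveSeed(seed, 6L, 20L)))
  repR <- stage("evaluate-radiomics",
    evaluateModel(radTrain, radVal, featR, config$model,
                  .deriveSeed(seed, 7L, 21L)))
  repF <- stage("fuse",
    .evaluateFusion(vasTrain, vasVal, featV, radTrain, radVal, featR,
                    config$weight, config$model, .deriveSeed(seed, 8L, 22L)))

  reports <- list(vasari = repV, radiomics = repR, fused = repF)
  if (config$includeClinical) {
    radTrainC <- augmentWithClinical(radTrain)
    radValC <- augmentWithClinical(
      radVal, bounds = normBounds(radTrainC)[
        normBounds(radTrainC)$feature %in% c("Age", "Gender"), ])
    reports$fusedClinical <- stage("fuse-clinical",
      .evaluateFusion(vasTrain, vasVal, featV, radTrainC, radValC,
                      c(featR, "Age", "Gender"), config$weight,
                      config$model, .deriveSeed(seed, 9L, 23L)))
  }

  corr <- stage("correlate",
    featureCorrelation(subsetFeatures(vasAll, featV),
                       subsetFeatures(radAll, selectedFeatures(selR))))

  chars <- data.frame(id = ids,
                      age = vapply(cohort@subjects, `[[`, numeric(1), "age"),
                      gender = vapply(cohort@subjects, `[[`, character(1),
                                      "gender"),
                      IDH1 = as.character(labels))
  balance <- stage("balance", cohortBalance(chars, split))

  result <- list(cohort = cohort, split = split,
                 radiomics = list(train = radTrain, validation = radVal),
                 vasari = list(train = vasTrain, validation = vasVal),
                 selection = list(vasari = selV, radiomics = selR),
                 sweep = list(vasari = swV, radiomics = swR),
                 features = list(vasari = featV, radiomics = featR),
                 reports = reports, correlation = corr, balance = balance,
                 config = config)
  result$manifest <- .writeStageOutputs(result, outDir)
  result
}

# Serialize stage outputs (when outDir is set) and assemble the manifest.
# Hashes cover file contents; the timestamp lives only in the manifest.
#' @noRd
.writeStageOutputs <- function(result, outDir) {
  manifest <- list(
    package = "RadioGliomics",
    version = as.character(utils::packageVersion("RadioGliomics")),
    seed = result$config$seed,
    nSubjects = result$config$synthetic@nSubjects,
    timestamp = format(Sys.time(), tz = "UTC"))
  selTable <- function(sel)
    data.frame(feature = selectedFeatures(sel), auc = featureAuc(sel),
               row.names = NULL)
  repTable <- function(rep) reportMetrics(rep)
  if (is.null(outDir)) {
    manifest$hashes <- list(
      selection_vasari = .objectHash(selTable(result$selection$vasari)),
      selection_radiomics = .objectHash(selTable(result$selection$radiomics)),
      reports = .objectHash(lapply(result$reports, repTable)),
      cohort = .objectHash(lapply(result$cohort@subjects, function(s)
        s$volume@intensities)))
    return(manifest)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    files <<- c(files, setNames(unname(tools::md5sum(path)), name))
  }
  put("selection_vasari.csv", function(p)
    utils::write.csv(selTable(result$selection$vasari), p, row.names = FALSE))
  put("selection_radiomics.csv", function(p)
    utils::write.csv(selTable(result$selection$radiomics), p,
                     row.names = FALSE))
  for (nm in names(result$reports)) {
    rep <- result$reports[[nm]]
    put(paste0("report_", nm, ".json"), function(p)
      jsonlite::write_json(list(metrics = repTable(rep),
                                threshold = rep@threshold,
                                repeats = rep@repeats),
                           p, auto_unbox = TRUE, digits = NA))
    put(paste0("roc_", nm, ".csv"), function(p)
      utils::write.csv(reportRoc(rep), p, row.names = FALSE))
  }
  put("sweep.json", function(p)
    jsonlite::write_json(list(
      vasari = list(auc = result$sweep$vasari@auc,
                    optimal = result$sweep$vasari@optimalOrder),
      radiomics = list(auc = result$sweep$radiomics@auc,
                       optimal = result$sweep$radiomics@optimalOrder)),
      p, auto_unbox = TRUE, digits = NA))
  put("correlation.csv", function(p) {
    m <- result$correlation
    utils::write.csv(as.data.frame(m), p)
  })
  put("balance.csv", function(p)
    utils::write.csv(result$balance, p, row.names = FALSE))
  manifest$hashes <- as.list(files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Render a human-readable run summary
#'
#' One text document tabulating the selected features with their AUCs,
#' the order sweeps, and the model comparison (one ROC series per
#' available report). Missing stages are listed as absent rather than
#' failing the render.
#'
#' @param result output of [runPipeline()].
#' @param path optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
renderReport <- function(result, path = NULL) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, paste0(...))
  add("IDH1 genotype prediction — run summary")
  add(strrep("=", 42))
  add(sprintf("seed %d, %d subjects (%d train / %d validation)",
              result$config$seed, length(result$cohort@subjects),
              length(result$split$train), length(result$split$validation)))
  add("")
  for (type in c("vasari", "radiomics")) {
    sel <- result$selection[[type]]
    if (is.null(sel)) { add("selection (", type, "): ABSENT"); next }
    add(sprintf("Selected %s features (top %d):", type,
                length(selectedFeatures(sel))))
    tab <- data.frame(feature = selectedFeatures(sel),
                      AUC = sprintf("%.3f", featureAuc(sel)))
    add(sprintf("  %-45s %s", tab$feature, tab$AUC))
    sw <- result$sweep[[type]]
    if (!is.null(sw))
      add(sprintf("  order sweep 1..%d: optimal %d (bootstrap AUC %.3f)",
                  max(sw@orders), sw@optimalOrder, sw@auc[sw@optimalOrder]))
    add("")
  }
  add("Validation performance:")
  series <- 0L
  for (nm in c("vasari", "radiomics", "fused", "fusedClinical")) {
    rep <- result$reports[[nm]]
    if (is.null(rep)) {
      if (nm %in% c("vasari", "radiomics", "fused"))
        add(sprintf("  %-14s ABSENT", nm))
      next
    }
    m <- reportMetrics(rep)
    add(sprintf("  %-14s AUC %.3f+/-%.3f sens %.3f spec %.3f acc %.3f",
                nm, m$mean[m$metric == "auc"], m$sd[m$metric == "auc"],
                m$mean[m$metric == "sensitivity"],
                m$mean[m$metric == "specificity"],
                m$mean[m$metric == "accuracy"]))
    if (nm %in% c("vasari", "radiomics", "fused")) {
      series <- series + 1L
      add(sprintf("    ROC series %d: %d points", series,
                  nrow(reportRoc(rep))))
    }
  }
  add(sprintf("ROC series rendered: %d", series))
  if (!is.null(result$correlation))
    add(sprintf("Cross-type correlation: mean |r| = %.3f",
                mean(abs(result$correlation))))
  if (!is.null(path)) {
    writeLines(ln, path)
    return(invisible(ln))
  }
  ln
}
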
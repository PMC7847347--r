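# NIfTI import/export for volumes and masks, plus cohort serialization
# (volume + mask pairs, manifest CSV, VASARI CSV, config JSON).

#' Write a MaskedVolume as a NIfTI pair
#'
#' Writes `<prefix>_adc.nii.gz` and `<prefix>_mask.nii.gz` with the
#' voxel spacing in the header.
#'
#' @param volume a [MaskedVolume-class].
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
writeMaskedVolume <- function(volume, prefix) {
  stopifnot(is(volume, "MaskedVolume"))
  paths <- paste0(prefix, c("_adc.nii.gz", "_mask.nii.gz"))
  img <- RNifti::asNifti(intensities(volume))
  RNifti::pixdim(img) <- voxelSpacing(volume)
  RNifti::writeNifti(img, paths[1])
  msk <- RNifti::asNifti(array(as.integer(tumorMask(volume)),
                               dim = dim(tumorMask(volume))))
  RNifti::pixdim(msk) <- voxelSpacing(volume)
  RNifti::writeNifti(msk, paths[2])
  invisible(paths)
}

#' Read a MaskedVolume from a NIfTI pair
#'
#' @param adcPath path to the ADC volume (NIfTI).
#' @param maskPath path to the binary mask (NIfTI, same grid).
#' @return A [MaskedVolume-class]; spacing is taken from the ADC header.
#' @export
readMaskedVolume <- function(adcPath, maskPath) {
  adc <- RNifti::readNifti(adcPath)
  msk <- RNifti::readNifti(maskPath)
  sp <- RNifti::pixdim(adc)[1:3]
  MaskedVolume(array(as.numeric(adc), dim = dim(adc)),
               array(as.numeric(msk) != 0, dim = dim(msk)), sp)
}

#' Write a synthetic cohort to disk
#'
#' Produces per-subject NIfTI volume/mask pairs, a `manifest.csv`
#' (id, label, age, gender, file paths), a `vasari.csv` of trait
#' records, and `config.json` with the generator settings.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort@subjects, function(s) {
    paths <- writeMaskedVolume(s$volume, file.path(dir, s$id))
    data.frame(id = s$id, label = s$label, age = s$age, gender = s$gender,
               adc = basename(paths[1]), mask = basename(paths[2]),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  vas <- do.call(rbind, lapply(cohort@subjects, function(s)
    as.data.frame(as.list(s$vasari), check.names = FALSE)))
  vas <- cbind(id = manifest$id, vas)
  utils::write.csv(vas, file.path(dir, "vasari.csv"), row.names = FALSE)
  cfg <- cohort@config
  cfgList <- list(nSubjects = cfg@nSubjects, mutantFraction = cfg@mutantFraction,
                  volumeShape = cfg@volumeShape, voxelSpacing = cfg@voxelSpacing,
                  tumorRadiusRange = cfg@tumorRadiusRange,
                  adcBackgroundMean = cfg@adcBackgroundMean,
                  adcBackgroundSd = cfg@adcBackgroundSd,
                  necrosisMean = cfg@necrosisMean, necrosisSd = cfg@necrosisSd,
                  baseTextureSigma = cfg@baseTextureSigma,
                  textureSigmaSd = cfg@textureSigmaSd,
                  baseNecrosisRate = cfg@baseNecrosisRate,
                  baseEccentricity = cfg@baseEccentricity,
                  eccentricitySd = cfg@eccentricitySd,
                  classEffects = cfg@classEffects,
                  clinicalEffects = cfg@clinicalEffects,
                  seed = cfg@seed)
  jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir the cohort directory.
#' @return A list of subject lists (id, volume, vasari, label, age,
#'   gender) usable with [extractCohortFeatures()].
#' @export
readCohortDir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  vas <- utils::read.csv(file.path(dir, "vasari.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rec <- unlist(vas[vas$id == row$id, setdiff(colnames(vas), "id")])
    list(id = row$id,
         volume = readMaskedVolume(file.path(dir, row$adc),
                                   file.path(dir, row$mask)),
         vasari = rec, label = row$label, age = row$age,
         gender = row$gender)
  })
}
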
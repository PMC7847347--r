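# Synthetic cohort generator: seeded ADC tumor volumes, masks, rater-style
# mask perturbations and class-conditional VASARI records with plantable,
# separable class effects, so every downstream stage is testable without
# patient data.

#' Configure the synthetic cohort generator
#'
#' The generator emulates a lower-grade-glioma diffusion-MRI cohort:
#' ellipsoidal tumors embedded in a 3-D ADC map (units 10^-3 mm^2/s),
#' with class signal planted through four separable knobs
#' (`classEffects`) plus class-conditional VASARI category probabilities.
#' Defaults mirror the near-balanced 102-subject study design (50
#' mutant : 52 wildtype) and a plausible LGG diffusion range; tumor ADC
#' is Gaussian around 1.2 with necrosis-like foci around 0.6.
#'
#' `classEffects` fields (all zero = identical class distributions):
#' * `minShift` - added to the wildtype per-subject minimum ADC voxel
#'   (negative lowers the wildtype histogram minimum by that amount);
#' * `necrosisRate` - extra expected count of low-ADC necrosis foci in
#'   wildtype tumors (mutant tumors keep `baseNecrosisRate`);
#' * `textureShift` - extra Gaussian correlation length (voxels) of the
#'   mutant intensity texture: mutant tumors are smoother, with longer
#'   runs and larger zones;
#' * `eccentricityShift` - added to the wildtype mean mask eccentricity.
#'
#' @param nSubjects cohort size (>= 4).
#' @param mutantFraction expected IDH1-mutant fraction, in (0, 1).
#' @param volumeShape voxel grid, length 3.
#' @param voxelSpacing mm per axis, length 3.
#' @param tumorRadiusRange (min, max) mean tumor radius in mm.
#' @param adcBackgroundMean,adcBackgroundSd in-tumor ADC field moments.
#' @param necrosisMean,necrosisSd ADC moments inside necrosis foci.
#' @param baseTextureSigma Gaussian texture correlation length (voxels)
#'   shared by both classes before `textureShift` is added.
#' @param textureSigmaSd between-subject sd of the correlation length
#'   (texture heterogeneity within a class).
#' @param baseNecrosisRate expected necrosis focus count in mutants.
#' @param baseEccentricity,eccentricitySd mean/sd of the target mask
#'   eccentricity before `eccentricityShift` is added.
#' @param classEffects list of the four effect sizes (see Details).
#' @param clinicalEffects list with `ageShift` (years added to the
#'   wildtype mean age; default 4.1 years, a realistic but
#'   non-significant gap at this cohort size)
#'   and `maleFraction`.
#' @param vasariConditionals per-trait 2 x k matrices of class-conditional
#'   category probabilities (rows mutant, wildtype).
#' @param seed integer master seed; all randomness derives from it.
#' @return A validated [SyntheticConfig-class].
#' @examples
#' cfg <- syntheticConfig(nSubjects = 8, seed = 1)
#' @export
syntheticConfig <- function(nSubjects = 102L,
                            mutantFraction = 50 / 102,
                            volumeShape = c(32L, 32L, 32L),
                            voxelSpacing = c(1, 1, 1),
                            tumorRadiusRange = c(6, 10),
                            adcBackgroundMean = 1.2,
                            adcBackgroundSd = 0.15,
                            necrosisMean = 0.6,
                            necrosisSd = 0.1,
                            baseTextureSigma = 0.8,
                            textureSigmaSd = 0.25,
                            baseNecrosisRate = 0.8,
                            baseEccentricity = 0.45,
                            eccentricitySd = 0.12,
                            classEffects = list(minShift = -0.04,
                                                necrosisRate = 0.3,
                                                textureShift = 0.2,
                                                eccentricityShift = 0.07),
                            clinicalEffects = list(ageShift = 4.1,
                                                   maleFraction = 60 / 102),
                            vasariConditionals = NULL,
                            seed = 1L) {
  if (is.null(vasariConditionals))
    vasariConditionals <- .defaultVasariConditionals()
  defaults <- list(minShift = 0, necrosisRate = 0, textureShift = 0,
                   eccentricityShift = 0)
  classEffects <- utils::modifyList(defaults, classEffects)
  obj <- new("SyntheticConfig",
             nSubjects = as.integer(nSubjects),
             mutantFraction = mutantFraction,
             volumeShape = as.integer(volumeShape),
             voxelSpacing = as.numeric(voxelSpacing),
             tumorRadiusRange = as.numeric(tumorRadiusRange),
             adcBackgroundMean = adcBackgroundMean,
             adcBackgroundSd = adcBackgroundSd,
             necrosisMean = necrosisMean, necrosisSd = necrosisSd,
             baseTextureSigma = baseTextureSigma,
             textureSigmaSd = textureSigmaSd,
             baseNecrosisRate = baseNecrosisRate,
             baseEccentricity = baseEccentricity,
             eccentricitySd = eccentricitySd,
             classEffects = classEffects,
             clinicalEffects = clinicalEffects,
             vasariConditionals = vasariConditionals,
             seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Remove all planted class signal from a config
#'
#' Sets the four `classEffects` to zero, the clinical age shift to zero
#' and every VASARI conditional to the average of its two class rows, so
#' mutant and wildtype subjects are drawn from identical distributions.
#' Used for permutation-style null calibration of the whole pipeline.
#'
#' @param config a [SyntheticConfig-class].
#' @return A config with no class signal.
#' @export
zeroSignalConfig <- function(config) {
  config@classEffects <- list(minShift = 0, necrosisRate = 0,
                              textureShift = 0, eccentricityShift = 0)
  config@clinicalEffects$ageShift <- 0
  config@vasariConditionals <- lapply(config@vasariConditionals, function(m) {
    p <- colMeans(m)
    rbind(mutant = p, wildtype = p)
  })
  validObject(config)
  config
}

#' Labels of a synthetic cohort as a factor
#' @param cohort a [SyntheticCohort-class].
#' @export
cohortLabels <- function(cohort) {
  factor(vapply(cohort@subjects, `[[`, character(1), "label"),
         levels = .CLASS_LEVELS)
}

#' Generate one synthetic ADC tumor volume
#'
#' Builds a rotated ellipsoidal mask inside the voxel grid, fills it
#' with a Gaussian ADC field whose spatial correlation length depends on
#' class, adds Poisson-count low-ADC necrosis foci, and (wildtype only)
#' lowers the single minimum voxel by `minShift`. Outside the mask the
#' volume holds normal-appearing tissue around 0.8. Values clip at 0.
#'
#' @param label `"mutant"` or `"wildtype"`.
#' @param config a [SyntheticConfig-class].
#' @param seed integer seed for this subject's stream.
#' @return A [MaskedVolume-class].
#' @examples
#' vol <- generateTumorVolume("mutant", syntheticConfig(nSubjects = 4), seed = 2)
#' @export
generateTumorVolume <- function(label, config, seed = config@seed) {
  label <- match.arg(label, .CLASS_LEVELS)
  .withSeed(seed, {
    shape <- config@volumeShape
    sp <- config@voxelSpacing
    eff <- config@classEffects
    wild <- label == "wildtype"

    r0 <- runif(1, config@tumorRadiusRange[1], config@tumorRadiusRange[2])
    extent <- shape * sp
    maxAxis <- min(extent) / 2 - max(sp)
    if (r0 > maxAxis)
      stop("tumor larger than volume: radius ", round(r0, 1),
           " mm does not fit in ", paste(round(extent, 1), collapse = "x"),
           " mm", call. = FALSE)
    eTarget <- config@baseEccentricity + if (wild) eff$eccentricityShift else 0
    e <- min(max(rnorm(1, eTarget, config@eccentricitySd), 0), 0.95)
    # elongation is capped so the major axis r0/s still fits in the grid
    eFit <- sqrt(max(1 - (r0 / maxAxis)^4, 0))
    e <- min(e, eFit)
    s <- (1 - e^2)^0.25
    radii <- c(r0 / s, r0, r0 * s)   # rmin/rmax = sqrt(1 - e^2)

    center <- extent / 2 + runif(3, -1, 1)
    rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]

    co <- cbind(
      rep((seq_len(shape[1]) - 0.5) * sp[1], times = shape[2] * shape[3]),
      rep(rep((seq_len(shape[2]) - 0.5) * sp[2], each = shape[1]),
          times = shape[3]),
      rep((seq_len(shape[3]) - 0.5) * sp[3], each = shape[1] * shape[2]))
    u <- sweep(co, 2, center) %*% rot
    u <- sweep(u, 2, radii, "/")
    mask <- array(rowSums(u^2) <= 1, dim = shape)
    if (!any(mask))
      stop("tumor larger than volume: empty mask after discretization",
           call. = FALSE)

    vol <- array(rnorm(prod(shape), 0.8, 0.1), dim = shape)
    sigmaClass <- config@baseTextureSigma + if (wild) 0 else eff$textureShift
    sigma <- max(rnorm(1, sigmaClass, config@textureSigmaSd), 0)
    noise <- array(rnorm(prod(shape)), dim = shape)
    field <- cpp_smooth3(noise, sigma)
    # Gaussian-copula texture: rank-map the in-mask field onto exact normal
    # scores, so the correlation length shapes runs/zones/co-occurrence but
    # leaves the first-order distribution (and its minimum) untouched
    fv <- field[mask]
    z <- stats::qnorm(rank(fv, ties.method = "first") / (length(fv) + 1))
    vol[mask] <- config@adcBackgroundMean + config@adcBackgroundSd * z

    rate <- config@baseNecrosisRate + if (wild) eff$necrosisRate else 0
    nFoci <- rpois(1, rate)
    if (nFoci > 0) {
      inIdx <- which(mask)
      for (f in seq_len(nFoci)) {
        cIdx <- sample(inIdx, 1)
        cPos <- co[cIdx, ]
        rf <- runif(1, 1.5, 2.5)
        hit <- which(mask & array(rowSums(sweep(co, 2, cPos)^2) <= rf^2,
                                  dim = shape))
        vol[hit] <- rnorm(length(hit), config@necrosisMean, config@necrosisSd)
      }
    }

    if (wild && eff$minShift != 0) {
      inIdx <- which(mask)
      lowest <- inIdx[which.min(vol[inIdx])]
      vol[lowest] <- vol[lowest] + eff$minShift
    }

    vol[vol < 0] <- 0
    MaskedVolume(vol, mask, sp)
  })
}

#' Generate one class-conditional VASARI record
#'
#' Samples each of the 23 traits from its class-conditional multinomial
#' in `config@vasariConditionals`; the result always passes lexicon
#' validation.
#'
#' @inheritParams generateTumorVolume
#' @param lexicon lexicon list from [vasariLexicon()].
#' @return Named character vector of 23 trait values.
#' @export
generateVasariRecord <- function(label, config, seed = config@seed,
                                 lexicon = vasariLexicon()) {
  label <- match.arg(label, .CLASS_LEVELS)
  miss <- setdiff(names(lexicon), names(config@vasariConditionals))
  if (length(miss))
    stop("vasariConditionals: missing distribution for trait(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  .withSeed(seed, {
    vapply(names(lexicon), function(trait) {
      p <- config@vasariConditionals[[trait]][label, ]
      cats <- lexicon[[trait]]$categories
      if (length(p) != length(cats))
        stop("vasariConditionals: trait '", trait, "' has ", length(p),
             " probabilities for ", length(cats), " categories",
             call. = FALSE)
      sample(cats, 1, prob = p)
    }, character(1))
  })
}

#' Generate a full synthetic cohort
#'
#' Class labels are allocated exactly (`round(n * mutantFraction)`
#' mutants) and shuffled; each subject then receives a tumor volume, a
#' VASARI record and clinical covariates from its own derived seed, so a
#' subject's data are reproducible independently of cohort size.
#'
#' @param config a [SyntheticConfig-class].
#' @return A [SyntheticCohort-class].
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSubjects = 6, seed = 3))
#' table(cohortLabels(cohort))
#' @export
generateCohort <- function(config) {
  validObject(config)
  lexicon <- vasariLexicon()
  n <- config@nSubjects
  nMut <- round(n * config@mutantFraction)
  if (nMut < 1L || nMut > n - 1L)
    stop("mutantFraction: allocation leaves a class empty at nSubjects = ",
         n, call. = FALSE)
  labels <- .withSeed(.deriveSeed(config@seed, 0L, 1L),
                      sample(rep(.CLASS_LEVELS, c(nMut, n - nMut))))
  ce <- config@clinicalEffects
  subjects <- lapply(seq_len(n), function(i) {
    lab <- labels[i]
    vol <- generateTumorVolume(lab, config, .deriveSeed(config@seed, i, 2L))
    vas <- generateVasariRecord(lab, config, .deriveSeed(config@seed, i, 3L),
                                lexicon)
    clin <- .withSeed(.deriveSeed(config@seed, i, 4L), {
      age <- rnorm(1, 45.3 - 2.05 + if (lab == "wildtype") ce$ageShift else 0,
                   16.3)
      list(age = round(min(max(age, 18), 77), 1),
           gender = if (rbinom(1, 1, ce$maleFraction) == 1) "M" else "F")
    })
    list(id = sprintf("S%03d", i), volume = vol, vasari = vas, label = lab,
         age = clin$age, gender = clin$gender)
  })
  new("SyntheticCohort", subjects = subjects, config = config)
}

#' Perturb a tumor mask into a second-rater surrogate
#'
#' Emulates interobserver segmentation disagreement: each voxel flips
#' with probability `(1 - exp(-severity)) * exp(-d / severity)` where
#' `d` is its 6-connected distance (in voxels) to the mask boundary.
#' Severity 0 returns the mask unchanged (Dice 1); as severity grows the
#' flip zone widens and deepens until, in the limit, the whole volume
#' flips and the overlap with the original vanishes. Interior voxels far
#' from the boundary are effectively never touched at moderate severity.
#'
#' @param mask 3-D logical array with at least one foreground voxel.
#' @param severity nonnegative voxel-scale disagreement level.
#' @param seed integer seed.
#' @return Perturbed logical mask of the same shape.
#' @seealso [calibratePerturbation()] to pick a severity matching a
#'   target mean Dice coefficient.
#' @export
perturbMask <- function(mask, severity, seed = 1L) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (severity < 0) stop("severity must be >= 0", call. = FALSE)
  if (severity == 0) return(mask)
  maxLayer <- min(12L, as.integer(ceiling(3 * severity)) + 1L)
  d <- .boundaryDistance(mask, maxLayer)
  p <- (1 - exp(-severity)) * exp(-d / severity)
  .withSeed(seed, {
    flip <- array(runif(length(mask)) < p, dim = dim(mask))
    xor(mask, flip)
  })
}

# 6-connected voxel distance to the mask boundary (0 = boundary voxel on
# either side), capped at maxLayer (treated as "far": flip prob ~ 0).
#' @noRd
.boundaryDistance <- function(mask, maxLayer) {
  shift1 <- function(a, axis, by) {
    d <- dim(a)
    idx <- lapply(d, seq_len)
    src <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
    out <- do.call(`[`, c(list(a), replace(idx, axis, list(src))))
    # out-of-range positions replicate the edge; mark them as same value
    array(out, dim = d)
  }
  neighborDisagree <- function(a) {
    dis <- array(FALSE, dim = dim(a))
    for (axis in 1:3) for (by in c(-1L, 1L))
      dis <- dis | (shift1(a, axis, by) != a)
    dis
  }
  d <- array(Inf, dim = dim(mask))
  frontier <- neighborDisagree(mask)
  d[frontier] <- 0
  reached <- frontier
  layer <- 0L
  while (layer < maxLayer && !all(reached)) {
    layer <- layer + 1L
    grow <- array(FALSE, dim = dim(mask))
    for (axis in 1:3) for (by in c(-1L, 1L))
      grow <- grow | shift1(reached, axis, by)
    new <- grow & !reached
    d[new] <- layer
    reached <- reached | new
  }
  d
}

#' Calibrate the mask-perturbation severity to a target Dice score
#'
#' Bisection search for the severity whose mean Dice coefficient against
#' the unperturbed masks matches `targetDsc` — the knob used to emulate
#' a given interobserver agreement regime.
#'
#' @param masks list of logical masks (or [MaskedVolume-class] objects).
#' @param targetDsc target mean Dice coefficient in (0, 1).
#' @param seed integer seed.
#' @param lower,upper severity search bracket.
#' @param tol bisection tolerance on severity.
#' @return list with `severity` and the achieved `meanDsc`.
#' @export
calibratePerturbation <- function(masks, targetDsc = 0.879, seed = 1L,
                                  lower = 1e-3, upper = 5, tol = 1e-3) {
  masks <- lapply(masks, function(m) if (is(m, "MaskedVolume")) tumorMask(m) else m)
  meanDsc <- function(sev)
    mean(vapply(seq_along(masks), function(i)
      diceCoefficient(masks[[i]],
                      perturbMask(masks[[i]], sev,
                                  .deriveSeed(seed, i, 5L)))$dsc,
      numeric(1)))
  lo <- lower; hi <- upper
  if (meanDsc(hi) > targetDsc) hi <- upper * 4
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (meanDsc(mid) > targetDsc) lo <- mid else hi <- mid
  }
  sev <- (lo + hi) / 2
  list(severity = sev, meanDsc = meanDsc(sev))
}
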
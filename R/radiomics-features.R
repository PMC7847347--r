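# The 56-feature ADC radiomics registry: 3 shape + 13 first-order histogram
# + 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM features, computed over in-mask
# voxels of a masked ADC volume. Formula conventions are documented per
# family below; the registry order is the canonical output order.

#' The canonical 56-feature registry
#'
#' @return data.frame with columns `name` and `family`, in extraction order.
#' @examples
#' table(featureRegistry()$family)
#' @export
featureRegistry <- function() {
  fam <- function(family, names) data.frame(name = names, family = family)
  rbind(
    fam("shape", c("Eccentricity", "Volume", "Surface-to-volume ratio")),
    fam("histogram", paste("Histogram",
        c("mean", "median", "minimum", "maximum", "range", "variance",
          "standard deviation", "skewness", "kurtosis", "energy", "entropy",
          "uniformity", "mean absolute deviation"))),
    fam("GLCM", paste("GLCM",
        c("energy", "contrast", "correlation", "homogeneity", "entropy",
          "variance", "sum average", "dissimilarity", "autocorrelation"))),
    fam("GLRLM", paste("GLRLM",
        c("short run emphasis", "long run emphasis",
          "gray-level nonuniformity", "run-length nonuniformity",
          "run percentage", "low gray-level run emphasis",
          "high gray-level run emphasis", "short run low gray-level emphasis",
          "short run high gray-level emphasis",
          "long run low gray-level emphasis",
          "long run high gray-level emphasis", "gray-level variance",
          "run-length variance"))),
    fam("GLSZM", paste("GLSZM",
        c("small zone emphasis", "large zone emphasis",
          "gray-level nonuniformity", "zone-size nonuniformity",
          "zone percentage", "low gray-level zone emphasis",
          "high gray-level zone emphasis",
          "small zone low gray-level emphasis",
          "small zone high gray-level emphasis",
          "large zone low gray-level emphasis",
          "large zone high gray-level emphasis", "gray-level variance",
          "zone-size variance"))),
    fam("NGTDM", paste("NGTDM",
        c("coarseness", "contrast", "busyness", "complexity", "strength"))))
}

#' Shape features of a tumor mask
#'
#' Three descriptors of the binary volume of interest:
#' * eccentricity: `sqrt(1 - lambda_min / lambda_max)` from the
#'   eigenvalues of the spatial covariance of in-mask voxel coordinates
#'   in physical (mm) units; 0 for a single voxel;
#' * volume: voxel count times voxel volume (mm^3);
#' * surface-to-volume ratio: face-counted surface area (mm^2) divided
#'   by the volume.
#'
#' @param mask 3-D logical array or a [MaskedVolume-class].
#' @param spacing voxel spacing in mm (ignored when `mask` is a
#'   [MaskedVolume-class]).
#' @return Named numeric vector of length 3.
#' @examples
#' m <- array(FALSE, c(3, 3, 10)); m[2, 2, 2:9] <- TRUE
#' shapeFeatures(m, c(1, 1, 1))  # 1 x 1 x 8 rod: volume 8, surface 34
#' @export
shapeFeatures <- function(mask, spacing = c(1, 1, 1)) {
  if (is(mask, "MaskedVolume")) {
    spacing <- voxelSpacing(mask)
    mask <- tumorMask(mask)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  co <- sweep(idx, 2, spacing, "*")
  nVox <- nrow(idx)
  vol <- nVox * prod(spacing)

  ecc <- 0
  if (nVox > 1L) {
    ev <- eigen(stats::cov(co), symmetric = TRUE, only.values = TRUE)$values
    lmax <- max(ev); lmin <- max(min(ev), 0)
    if (lmax > 0) ecc <- sqrt(1 - lmin / lmax)
  }

  surf <- 0
  for (axis in 1:3) {
    faceArea <- prod(spacing[-axis])
    for (by in c(-1L, 1L)) {
      nb <- idx
      nb[, axis] <- nb[, axis] + by
      inside <- nb[, axis] >= 1L & nb[, axis] <= d[axis]
      exposed <- !inside
      if (any(inside))
        exposed[inside] <- !mask[nb[inside, , drop = FALSE]]
      surf <- surf + sum(exposed) * faceArea
    }
  }

  c("Eccentricity" = ecc, "Volume" = vol,
    "Surface-to-volume ratio" = surf / vol)
}

#' First-order histogram features of the in-mask ADC values
#'
#' Thirteen first-order statistics over the in-mask voxels. Entropy
#' (base 2) and uniformity are computed on a fixed-width histogram with
#' `entropyBins` bins spanning the in-mask range (a constant volume has
#' entropy 0 and uniformity 1); energy is the raw sum of squares; the
#' variance/sd use the n-1 denominator.
#'
#' @param volume a [MaskedVolume-class].
#' @param entropyBins bins for the entropy/uniformity histogram (default 64).
#' @return Named numeric vector of length 13.
#' @export
histogramFeatures <- function(volume, entropyBins = 64L) {
  stopifnot(is(volume, "MaskedVolume"))
  x <- intensities(volume)[tumorMask(volume)]
  n <- length(x)
  m <- mean(x)
  v <- if (n > 1) stats::var(x) else 0
  m2 <- mean((x - m)^2)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0
  rng <- max(x) - min(x)
  if (rng > 0) {
    br <- seq(min(x), max(x), length.out = entropyBins + 1L)
    cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE),
                         entropyBins), nbins = entropyBins)
    p <- cnt / n
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
    unif <- sum(p^2)
  } else {
    ent <- 0; unif <- 1
  }
  c("Histogram mean" = m, "Histogram median" = median(x),
    "Histogram minimum" = min(x), "Histogram maximum" = max(x),
    "Histogram range" = rng, "Histogram variance" = v,
    "Histogram standard deviation" = sqrt(v),
    "Histogram skewness" = skew, "Histogram kurtosis" = kurt,
    "Histogram energy" = sum(x^2), "Histogram entropy" = ent,
    "Histogram uniformity" = unif,
    "Histogram mean absolute deviation" = mean(abs(x - m)))
}

#' GLCM features
#'
#' Nine features of the merged symmetric normalized co-occurrence matrix
#' p(i, j). Correlation is defined as 0 when only one gray level occurs
#' (zero marginal variance).
#'
#' @param matrices a [TextureMatrices-class].
#' @return Named numeric vector of length 9.
#' @export
glcmFeatures <- function(matrices) {
  p <- matrices@glcm
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mu <- sum(i * p)           # symmetric: row and column means coincide
  sig2 <- sum((i - mu)^2 * p)
  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * p) / sig2 else 0
  pp <- p[p > 0]
  c("GLCM energy" = sum(p^2),
    "GLCM contrast" = sum((i - j)^2 * p),
    "GLCM correlation" = corr,
    "GLCM homogeneity" = sum(p / (1 + abs(i - j))),
    "GLCM entropy" = if (length(pp)) -sum(pp * log2(pp)) else 0,
    "GLCM variance" = sig2,
    "GLCM sum average" = sum((i + j) * p),
    "GLCM dissimilarity" = sum(abs(i - j) * p),
    "GLCM autocorrelation" = sum(i * j * p))
}

# Shared run/zone feature kernel: counts m(i, j) with j = run length or
# zone size, total N = sum(m), plus the voxel mass sum(j * m).
#' @noRd
.runZoneFeatures <- function(m, prefix, jName, voxelMass) {
  ng <- nrow(m)
  i <- matrix(seq_len(ng), ng, ncol(m))
  j <- matrix(seq_len(ncol(m)), ng, ncol(m), byrow = TRUE)
  n <- sum(m)
  if (n == 0) stop("empty ", prefix, " matrix", call. = FALSE)
  p <- m / n
  mui <- sum(i * p)
  muj <- sum(j * p)
  vals <- c(
    sum(m / j^2) / n,                 # short emphasis
    sum(m * j^2) / n,                 # long emphasis
    sum(rowSums(m)^2) / n,            # gray-level nonuniformity
    sum(colSums(m)^2) / n,            # size nonuniformity
    n / voxelMass,                    # percentage
    sum(m / i^2) / n,                 # low gray-level emphasis
    sum(m * i^2) / n,                 # high gray-level emphasis
    sum(m / (i^2 * j^2)) / n,         # short + low
    sum(m * i^2 / j^2) / n,           # short + high
    sum(m * j^2 / i^2) / n,           # long + low
    sum(m * i^2 * j^2) / n,           # long + high
    sum(p * (i - mui)^2),             # gray-level variance
    sum(p * (j - muj)^2))             # size variance
  short <- if (prefix == "GLRLM") "short run" else "small zone"
  long <- if (prefix == "GLRLM") "long run" else "large zone"
  run <- if (prefix == "GLRLM") "run" else "zone"
  names(vals) <- paste(prefix, c(
    paste(short, "emphasis"), paste(long, "emphasis"),
    "gray-level nonuniformity", paste0(jName, " nonuniformity"),
    paste(run, "percentage"), paste("low gray-level", run, "emphasis"),
    paste("high gray-level", run, "emphasis"),
    paste(short, "low gray-level emphasis"),
    paste(short, "high gray-level emphasis"),
    paste(long, "low gray-level emphasis"),
    paste(long, "high gray-level emphasis"),
    "gray-level variance", paste0(jName, " variance")))
  vals
}

#' GLRLM features
#'
#' Thirteen run-length features on the direction-merged run matrix
#' r(i, j). The run percentage divides the run count by the total voxel
#' mass `sum(j * r)`, i.e. the in-mask voxel count times the number of
#' directions, so it stays in (0, 1] for any direction set.
#'
#' @param matrices a [TextureMatrices-class].
#' @return Named numeric vector of length 13.
#' @export
glrlmFeatures <- function(matrices) {
  m <- matrices@glrlm
  j <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  .runZoneFeatures(m, "GLRLM", "run-length", voxelMass = sum(j * m))
}

#' GLSZM features
#'
#' The thirteen zone analogues of the run-length set, on 26-connected
#' equal-level zones within the mask; the zone percentage divides the
#' zone count by the in-mask voxel count.
#'
#' @param matrices a [TextureMatrices-class].
#' @return Named numeric vector of length 13.
#' @export
glszmFeatures <- function(matrices) {
  .runZoneFeatures(matrices@glszm, "GLSZM", "zone-size",
                   voxelMass = matrices@nVoxels)
}

#' NGTDM features
#'
#' Five neighbourhood gray-tone difference features (coarseness,
#' contrast, busyness, complexity, strength) from the per-level
#' difference totals s(i) and level probabilities p(i). Zero
#' denominators are guarded with `eps`; a zero-difference field (e.g. a
#' constant volume) caps coarseness at `1/eps`.
#'
#' @param matrices a [TextureMatrices-class].
#' @param eps denominator guard (default 1e-12).
#' @return Named numeric vector of length 5.
#' @export
ngtdmFeatures <- function(matrices, eps = 1e-12) {
  s <- matrices@ngtdm$s
  cnt <- matrices@ngtdm$n
  nTot <- sum(cnt)
  if (nTot == 0) stop("empty NGTDM: no voxel has an in-mask neighbour",
                      call. = FALSE)
  p <- cnt / nTot
  lv <- seq_along(p)
  occ <- which(p > 0)
  ngp <- length(occ)

  coarse <- min(1 / (sum(p * s) + eps), 1 / eps)

  contrast <- 0
  if (ngp > 1) {
    dif2 <- outer(lv[occ], lv[occ], function(a, b) (a - b)^2)
    contrast <- sum(outer(p[occ], p[occ]) * dif2) / (ngp * (ngp - 1)) *
      sum(s) / nTot
  }

  busy <- 0
  if (ngp > 1) {
    denom <- sum(abs(outer(lv[occ] * p[occ], lv[occ] * p[occ], `-`)))
    busy <- sum(p * s) / (denom + eps)
  }

  cx <- 0
  if (ngp > 1) {
    for (a in occ) for (b in occ)
      cx <- cx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    cx <- cx / nTot
  }

  strength <- 0
  if (ngp > 1) {
    st <- 0
    for (a in occ) for (b in occ)
      st <- st + (p[a] + p[b]) * (a - b)^2
    strength <- st / (sum(s) + eps)
  }

  c("NGTDM coarseness" = coarse, "NGTDM contrast" = contrast,
    "NGTDM busyness" = busy, "NGTDM complexity" = cx,
    "NGTDM strength" = strength)
}

#' Extract all 56 radiomics features from a masked volume
#'
#' Runs the whole registry — shape, first-order histogram, and the four
#' texture families on the quantized volume — returning one named value
#' per registry entry, in registry order.
#'
#' @param volume a [MaskedVolume-class].
#' @param nLevels gray levels for quantization (default 32).
#' @param entropyBins histogram bins for first-order entropy/uniformity.
#' @return Named numeric vector of length 56.
#' @examples
#' vol <- generateTumorVolume("mutant", syntheticConfig(nSubjects = 4), seed = 1)
#' length(extractRadiomics(vol))  # 56
#' @export
extractRadiomics <- function(volume, nLevels = 32L, entropyBins = 64L) {
  stopifnot(is(volume, "MaskedVolume"))
  withFamily <- function(family, expr)
    tryCatch(expr, error = function(e)
      stop(family, " features: ", conditionMessage(e), call. = FALSE))
  gv <- withFamily("texture", discretizeVolume(volume, nLevels))
  tm <- withFamily("texture", textureMatrices(gv))
  out <- c(withFamily("shape", shapeFeatures(volume)),
           withFamily("histogram", histogramFeatures(volume, entropyBins)),
           withFamily("GLCM", glcmFeatures(tm)),
           withFamily("GLRLM", glrlmFeatures(tm)),
           withFamily("GLSZM", glszmFeatures(tm)),
           withFamily("NGTDM", ngtdmFeatures(tm)))
  reg <- featureRegistry()$name
  stopifnot(identical(names(out), reg))
  out
}

#' Extract radiomics features for every subject of a cohort
#'
#' @param cohort a [SyntheticCohort-class] (or a list of subject lists
#'   with `id`, `volume`, `label`, and optional `age`/`gender`).
#' @param nLevels gray levels for quantization.
#' @return A [FeatureTable-class] of 56 features with age/gender (when
#'   present) carried as covariates.
#' @export
extractCohortFeatures <- function(cohort, nLevels = 32L) {
  subjects <- if (is(cohort, "SyntheticCohort")) cohort@subjects else cohort
  vals <- t(vapply(subjects, function(s)
    extractRadiomics(s$volume, nLevels), numeric(56L)))
  rownames(vals) <- vapply(subjects, `[[`, character(1), "id")
  labels <- vapply(subjects, `[[`, character(1), "label")
  cov <- NULL
  if (!is.null(subjects[[1]]$age))
    cov <- data.frame(age = vapply(subjects, `[[`, numeric(1), "age"),
                      gender = vapply(subjects, `[[`, character(1), "gender"))
  FeatureTable(vals, labels = labels, covariates = cov)
}
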
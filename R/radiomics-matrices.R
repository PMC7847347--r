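# Quantization and gray-level texture matrix construction. The heavy
# enumeration (pair counts, run scans, 26-connected zones, neighbourhood
# averages) is compiled code; this file owns the conventions: fixed bin
# count between the in-mask min and max, 13 merged directions at Chebyshev
# distance 1, runs and zones broken by the mask.

#' Quantize a masked volume to gray levels
#'
#' Uniform quantization of the in-mask intensities between the in-mask
#' minimum and maximum: the minimum maps to level 1 and the maximum to
#' level `nLevels`. Voxels outside the mask are level 0 and take no part
#' in any texture matrix. A constant in-mask volume maps entirely to
#' level 1 and is flagged degenerate.
#'
#' @param volume a [MaskedVolume-class].
#' @param nLevels number of gray levels (>= 2; default 32).
#' @return A [GrayLevelVolume-class].
#' @examples
#' vol <- MaskedVolume(array(runif(64), c(4, 4, 4)), array(TRUE, c(4, 4, 4)))
#' discretizeVolume(vol, nLevels = 8)
#' @export
discretizeVolume <- function(volume, nLevels = 32L) {
  stopifnot(is(volume, "MaskedVolume"))
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("nLevels must be >= 2", call. = FALSE)
  v <- intensities(volume)[tumorMask(volume)]
  lo <- min(v); hi <- max(v)
  lev <- array(0L, dim = dim(intensities(volume)))
  degenerate <- hi == lo
  if (degenerate) {
    lev[tumorMask(volume)] <- 1L
  } else {
    q <- floor((intensities(volume)[tumorMask(volume)] - lo) /
                 (hi - lo) * nLevels) + 1L
    q[q > nLevels] <- nLevels
    lev[tumorMask(volume)] <- as.integer(q)
  }
  new("GrayLevelVolume", levels = lev, nLevels = nLevels,
      range = c(lo, hi), degenerate = degenerate)
}

#' Build the four texture matrices of a quantized volume
#'
#' GLCM: symmetric co-occurrence counts at distance 1 accumulated over
#' the given directions (default: the 13 unique 3-D offsets) and
#' normalized to sum 1. GLRLM: run-length counts per direction, plus
#' their merged sum; runs break at mask boundaries and level changes.
#' GLSZM: zone-size counts of 26-connected equal-level components
#' within the mask. NGTDM: per-level totals of the absolute difference
#' between a voxel's level and the mean of its in-mask 26-neighbours
#' (averaging over available neighbours; isolated voxels are excluded).
#'
#' @param grayVolume a [GrayLevelVolume-class] from [discretizeVolume()].
#' @param directions integer matrix of direction offsets (rows = dx, dy,
#'   dz); default all 13. A subset gives direction-restricted GLCM/GLRLM.
#' @return A [TextureMatrices-class].
#' @export
textureMatrices <- function(grayVolume, directions = NULL) {
  stopifnot(is(grayVolume, "GrayLevelVolume"))
  if (is.null(directions)) directions <- .offsets13()
  storage.mode(directions) <- "integer"
  lev <- grayVolume@levels
  ng <- grayVolume@nLevels
  nVox <- sum(lev > 0L)

  glcmCounts <- cpp_glcm(lev, ng, directions)
  tot <- sum(glcmCounts)
  glcm <- if (tot > 0) glcmCounts / tot else
    matrix(0, ng, ng) # single isolated voxel: no pairs
  byDir <- cpp_glrlm(lev, ng, directions)
  rmax <- max(vapply(byDir, ncol, integer(1)))
  glrlm <- matrix(0, ng, rmax)
  for (m in byDir) glrlm[, seq_len(ncol(m))] <- glrlm[, seq_len(ncol(m))] + m
  glszm <- cpp_glszm(lev, ng)
  ngtdm <- cpp_ngtdm(lev, ng)

  new("TextureMatrices", glcm = glcm, glrlm = glrlm,
      glrlmByDirection = byDir, glszm = glszm, ngtdm = ngtdm,
      nVoxels = as.integer(nVox), nLevels = ng)
}
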
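# Shared in-code fixtures: small deterministic volumes and feature tables.

# random masked volume with integer-ish intensities for texture oracles
randomGrayLevels <- function(dim3 = c(6, 6, 6), ng = 4, pMask = 0.7) {
  lev <- array(0L, dim3)
  mask <- array(runif(prod(dim3)) < pMask, dim3)
  if (!any(mask)) mask[1] <- TRUE
  lev[mask] <- sample.int(ng, sum(mask), replace = TRUE)
  lev
}

grayVolumeFromLevels <- function(lev, ng) {
  new("GrayLevelVolume", levels = lev, nLevels = as.integer(ng),
      range = c(1, ng), degenerate = FALSE)
}

maskedVolumeFromValues <- function(values, mask = NULL, spacing = c(1, 1, 1)) {
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  MaskedVolume(values, mask, spacing)
}

# a feature table with a planted separable feature and pure-noise columns
separableTable <- function(n = 30, noiseCols = 3, seed = 42) {
  withr::with_seed(seed, {
    labels <- rep(c("mutant", "wildtype"), length.out = n)
    sig <- ifelse(labels == "wildtype", 1, 0) + rnorm(n, 0, 0.05)
    X <- cbind(signal = sig,
               matrix(rnorm(n * noiseCols), n,
                      dimnames = list(NULL, paste0("noise", seq_len(noiseCols)))))
    FeatureTable(X, labels)
  })
}

# small generator config shared by the unit tests
smallConfig <- function(nSubjects = 8L, volumeShape = c(24L, 24L, 24L),
                        tumorRadiusRange = c(5, 8), seed = 1L, ...) {
  syntheticConfig(nSubjects = nSubjects, volumeShape = volumeShape,
                  tumorRadiusRange = tumorRadiusRange, seed = seed, ...)
}
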
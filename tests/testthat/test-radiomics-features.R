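# Radiomics extraction: quantization, shape, first-order and the four
# texture families, against hand-worked values and enumeration oracles.

test_that("quantization maps the in-mask range uniformly onto 1..Ng", {
  vol <- maskedVolumeFromValues(array(rep(0:3, length.out = 8), c(2, 2, 2)))
  gv <- discretizeVolume(vol, nLevels = 4)
  expect_setequal(unique(as.vector(gv@levels)), 1:4)
  expect_equal(sort(unique(gv@levels[vol@intensities == 0])), 1L)
  expect_equal(sort(unique(gv@levels[vol@intensities == 3])), 4L)
  expect_false(gv@degenerate)

  const <- maskedVolumeFromValues(array(2.5, c(3, 3, 3)))
  gvc <- discretizeVolume(const, nLevels = 32)
  expect_true(gvc@degenerate)
  expect_true(all(gvc@levels == 1L))

  expect_error(discretizeVolume(const, nLevels = 1), "nLevels")
})

test_that("quantization of uniform draws fills bins binomially", {
  withr::with_seed(7, {
    v <- array(runif(1000), c(10, 10, 10))
    gv <- discretizeVolume(maskedVolumeFromValues(v), nLevels = 8)
    counts <- tabulate(gv@levels[gv@levels > 0], 8)
    sigma <- sqrt(1000 * (1 / 8) * (7 / 8))
    expect_true(all(abs(counts - 125) < 3 * sigma))
  })
})

test_that("shape features match closed forms for rod, ball and scaled grids", {
  rod <- array(FALSE, c(3, 3, 10)); rod[2, 2, 2:9] <- TRUE
  f <- shapeFeatures(rod, c(1, 1, 1))
  expect_equal(unname(f["Volume"]), 8)
  expect_equal(unname(f["Surface-to-volume ratio"]) * 8, 34)
  # collinear points: zero covariance across the rod, eccentricity 1
  expect_equal(unname(f["Eccentricity"]), 1)

  # doubling the spacing scales volume by 8 and leaves eccentricity alone
  f2 <- shapeFeatures(rod, c(2, 2, 2))
  expect_equal(unname(f2["Volume"]), 64)
  expect_equal(unname(f2["Eccentricity"]), unname(f["Eccentricity"]))

  n <- 23; r <- 10; c0 <- (n + 1) / 2
  co <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array((co$x - c0)^2 + (co$y - c0)^2 + (co$z - c0)^2 <= r^2,
                c(n, n, n))
  fb <- shapeFeatures(ball, c(1, 1, 1))
  expect_lt(unname(fb["Eccentricity"]), 0.15)
  expect_equal(unname(fb["Volume"]), sum(ball))

  expect_equal(unname(shapeFeatures(array(TRUE, c(1, 1, 1)))["Eccentricity"]),
               0)
  expect_error(shapeFeatures(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("histogram features agree with hand arithmetic and moment limits", {
  v <- maskedVolumeFromValues(array(c(1, 2, 3), c(3, 1, 1)))
  f <- histogramFeatures(v)
  expect_equal(unname(f[c("Histogram mean", "Histogram minimum",
                          "Histogram range", "Histogram energy")]),
               c(2, 1, 2, 14))
  expect_equal(unname(f["Histogram median"]), 2)

  const <- histogramFeatures(maskedVolumeFromValues(array(5, c(2, 2, 2))))
  expect_equal(unname(const[c("Histogram variance", "Histogram entropy",
                              "Histogram uniformity")]), c(0, 0, 1))

  withr::with_seed(11, {
    x <- array(rnorm(10000), c(10, 10, 100))
    fn <- histogramFeatures(maskedVolumeFromValues(x))
    expect_lt(abs(fn[["Histogram skewness"]]), 0.1)
    expect_lt(abs(fn[["Histogram kurtosis"]]), 0.2)
    expect_equal(fn[["Histogram standard deviation"]],
                 sd(x), tolerance = 1e-12)
  })
})

test_that("single-direction GLCM of an alternating stripe has correlation -1", {
  lev <- array(0L, c(4, 4, 4))
  for (z in 1:4) lev[, , z] <- 1L + z %% 2L
  gv <- grayVolumeFromLevels(lev, 2)
  tm <- textureMatrices(gv, directions = matrix(c(0L, 0L, 1L), 1))
  f <- glcmFeatures(tm)
  expect_equal(unname(f["GLCM correlation"]), -1)
  expect_equal(tm@glcm, oracleGlcm(lev, 2, matrix(c(0, 0, 1), 1)),
               tolerance = 1e-12)
  # contrast is maximal among same-size 2-level volumes along this axis
  withr::with_seed(3, {
    for (i in 1:5) {
      rnd <- array(sample(1:2, 64, replace = TRUE), c(4, 4, 4))
      tmr <- textureMatrices(grayVolumeFromLevels(rnd, 2),
                             directions = matrix(c(0L, 0L, 1L), 1))
      expect_lte(glcmFeatures(tmr)[["GLCM contrast"]], f[["GLCM contrast"]])
    }
  })
})

test_that("constant volume collapses GLCM to a single cell", {
  lev <- array(1L, c(3, 3, 3))
  f <- glcmFeatures(textureMatrices(grayVolumeFromLevels(lev, 2)))
  expect_equal(unname(f[c("GLCM energy", "GLCM contrast", "GLCM entropy")]),
               c(1, 0, 0))
  expect_equal(unname(f["GLCM correlation"]), 0) # zero-variance guard
})

test_that("run matrix of [1,1,2] along one direction gives SRE 0.625", {
  lev <- array(c(1L, 1L, 2L), c(3, 1, 1))
  tm <- textureMatrices(grayVolumeFromLevels(lev, 2),
                        directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(sum(tm@glrlm), 2) # two runs
  f <- glrlmFeatures(tm)
  expect_equal(unname(f["GLRLM short run emphasis"]), 0.625)
  expect_equal(unname(f["GLRLM run percentage"]), 2 / 3)
})

test_that("constant volume yields one maximal run per line per direction", {
  lev <- array(1L, c(4, 5, 3))
  for (ax in 1:3) {
    d <- matrix(0L, 1, 3); d[1, ax] <- 1L
    tm <- textureMatrices(grayVolumeFromLevels(lev, 2), directions = d)
    nLines <- prod(dim(lev)[-ax])
    expect_equal(sum(tm@glrlm), nLines)
    expect_equal(unname(glrlmFeatures(tm)["GLRLM run percentage"]),
                 nLines / prod(dim(lev)))
  }
})

test_that("zone matrix of a two-zone slab matches hand counts", {
  lev <- array(c(1L, 2L, 1L, 2L), c(2, 2, 1))
  tm <- textureMatrices(grayVolumeFromLevels(lev, 2))
  f <- glszmFeatures(tm)
  expect_equal(sum(tm@glszm), 2)
  expect_equal(unname(f["GLSZM zone-size nonuniformity"]), 2)
  expect_equal(unname(f["GLSZM small zone emphasis"]), 0.25)

  const <- array(1L, c(3, 3, 3))
  fc <- glszmFeatures(textureMatrices(grayVolumeFromLevels(const, 2)))
  expect_equal(unname(fc["GLSZM zone percentage"]), 1 / 27)
  expect_equal(unname(fc["GLSZM large zone emphasis"]), 27^2)
})

test_that("NGTDM totals match hand counts on checkerboards and constants", {
  lev <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  tm <- textureMatrices(grayVolumeFromLevels(lev, 2))
  expect_equal(tm@ngtdm$s, c(4 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(tm@ngtdm$n, c(2, 2))

  const <- textureMatrices(grayVolumeFromLevels(array(1L, c(3, 3, 3)), 2))
  fc <- ngtdmFeatures(const)
  expect_equal(sum(const@ngtdm$s), 0)
  expect_equal(unname(fc["NGTDM contrast"]), 0)
  expect_equal(unname(fc["NGTDM coarseness"]), 1e12) # 1/eps cap
})

test_that("extraction returns all 56 registry features, finite and ordered", {
  reg <- featureRegistry()
  expect_equal(nrow(reg), 56)
  expect_equal(as.integer(table(reg$family)[c("shape", "histogram", "GLCM",
                                              "GLRLM", "GLSZM", "NGTDM")]),
               c(3L, 13L, 9L, 13L, 13L, 5L))
  vol <- generateTumorVolume("wildtype", smallConfig(), seed = 21)
  f <- extractRadiomics(vol)
  expect_identical(names(f), reg$name)
  expect_true(all(is.finite(f)))
})

test_that("features are invariant under translation and axis permutation", {
  withr::with_seed(5, {
    base <- array(rnorm(6 * 6 * 6, 1, 0.2), c(6, 6, 6))
    mask <- array(FALSE, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE
  })
  pad <- function(a, big = c(12, 12, 12), at = c(1, 1, 1)) {
    out <- array(0, big)
    out[at[1]:(at[1] + 5), at[2]:(at[2] + 5), at[3]:(at[3] + 5)] <- a
    out
  }
  v1 <- MaskedVolume(pad(base), pad(mask) > 0)
  v2 <- MaskedVolume(pad(base, at = c(4, 3, 5)), pad(mask, at = c(4, 3, 5)) > 0)
  expect_equal(extractRadiomics(v1), extractRadiomics(v2), tolerance = 1e-12)

  v3 <- MaskedVolume(aperm(pad(base), c(3, 1, 2)),
                     aperm(pad(mask), c(3, 1, 2)) > 0)
  f1 <- extractRadiomics(v1); f3 <- extractRadiomics(v3)
  texture <- featureRegistry()$name[featureRegistry()$family %in%
                                      c("GLCM", "GLRLM", "GLSZM", "NGTDM")]
  expect_equal(f1[texture], f3[texture], tolerance = 1e-9)
})

test_that("texture features ignore affine intensity rescaling (same bins)", {
  withr::with_seed(6, {
    v <- array(rnorm(5^3, 1.2, 0.15), c(5, 5, 5))
    mask <- array(runif(5^3) < 0.8, c(5, 5, 5)); mask[1] <- TRUE
  })
  f1 <- extractRadiomics(MaskedVolume(v, mask))
  f2 <- extractRadiomics(MaskedVolume(3.7 * v + 11, mask))
  texture <- featureRegistry()$name[featureRegistry()$family %in%
                                      c("GLCM", "GLRLM", "GLSZM", "NGTDM")]
  expect_equal(f1[texture], f2[texture], tolerance = 1e-9)
})

test_that("mass conservation holds on random volumes", {
  withr::with_seed(8, {
    for (i in 1:10) {
      lev <- randomGrayLevels(c(6, 6, 6), ng = 4)
      tm <- textureMatrices(grayVolumeFromLevels(lev, 4))
      nVox <- sum(lev > 0)
      expect_equal(sum(tm@glcm), 1, tolerance = 1e-9)
      for (m in tm@glrlmByDirection) {
        jr <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
        expect_equal(sum(jr * m), nVox)
      }
      jz <- matrix(seq_len(ncol(tm@glszm)), nrow(tm@glszm), ncol(tm@glszm),
                   byrow = TRUE)
      expect_equal(sum(jz * tm@glszm), nVox)
    }
  })
})

test_that("normalization maps to [0,1], is idempotent, clips with bounds", {
  ft <- FeatureTable(cbind(f1 = c(2, 4, 6), f2 = c(1, 1, 1)),
                     labels = c("mutant", "wildtype", "mutant"))
  n1 <- normalizeFeatures(ft)
  expect_equal(unname(featureValues(n1)[, "f1"]), c(0, 0.5, 1))
  expect_equal(unname(featureValues(n1)[, "f2"]), c(0, 0, 0)) # constant -> 0
  expect_true(normBounds(n1)$degenerate[normBounds(n1)$feature == "f2"])

  n2 <- normalizeFeatures(n1)
  expect_equal(featureValues(n2), featureValues(n1)) # idempotent

  val <- FeatureTable(cbind(f1 = c(7, 1), f2 = c(0, 2)),
                      labels = c("wildtype", "mutant"))
  nv <- normalizeFeatures(val, normBounds(n1))
  expect_equal(unname(featureValues(nv)[, "f1"]), c(1, 0)) # 7 clipped
})

test_that("longer texture correlation increases run and zone lengths", {
  lre <- lze <- c()
  for (sg in c(0.4, 1.4)) {
    cfg <- smallConfig(baseTextureSigma = sg, textureSigmaSd = 0,
                       classEffects = list(minShift = 0, necrosisRate = 0,
                                           textureShift = 0,
                                           eccentricityShift = 0))
    v <- vapply(1:8, function(i) {
      f <- extractRadiomics(generateTumorVolume("mutant", cfg, 300 + i))
      c(f[["GLRLM long run emphasis"]], f[["GLSZM large zone emphasis"]])
    }, numeric(2))
    lre <- c(lre, mean(v[1, ])); lze <- c(lze, mean(v[2, ]))
  }
  expect_gt(lre[2], lre[1])
  expect_gt(lze[2], lze[1])
})
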
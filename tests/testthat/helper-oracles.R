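# Brute-force enumeration oracles for the texture machinery, written as
# plain nested loops over voxels, independent of the package's compiled
# implementations. Used to pin every texture feature to first principles.

oracleOffsets13 <- function() {
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o <- o[rowSums(abs(o)) > 0, ]
  o[apply(o, 1, function(v) v[which(v != 0)[1]] > 0), , drop = FALSE]
}

# pair enumeration over all voxels and offsets (both orientations)
oracleGlcm <- function(lev, ng, offsets = oracleOffsets13()) {
  d <- dim(lev)
  m <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    for (k in seq_len(nrow(offsets))) {
      x2 <- x + offsets[k, 1]; y2 <- y + offsets[k, 2]; z2 <- z + offsets[k, 3]
      if (x2 < 1 || y2 < 1 || z2 < 1 || x2 > d[1] || y2 > d[2] || z2 > d[3])
        next
      b <- lev[x2, y2, z2]
      if (b == 0) next
      m[a, b] <- m[a, b] + 1
      m[b, a] <- m[b, a] + 1
    }
  }
  if (sum(m) > 0) m / sum(m) else m
}

# line scanner: walk every maximal same-level run along one direction
oracleGlrlmDir <- function(lev, ng, d3) {
  d <- dim(lev)
  runs <- list()
  inb <- function(x, y, z)
    x >= 1 && y >= 1 && z >= 1 && x <= d[1] && y <= d[2] && z <= d[3]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    px <- x - d3[1]; py <- y - d3[2]; pz <- z - d3[3]
    if (inb(px, py, pz) && lev[px, py, pz] == a) next
    len <- 1
    cx <- x + d3[1]; cy <- y + d3[2]; cz <- z + d3[3]
    while (inb(cx, cy, cz) && lev[cx, cy, cz] == a) {
      len <- len + 1
      cx <- cx + d3[1]; cy <- cy + d3[2]; cz <- cz + d3[3]
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  rmax <- max(1, vapply(runs, `[`, numeric(1), 2))
  m <- matrix(0, ng, rmax)
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

# recursive flood fill over 26-neighbourhoods, one zone at a time
oracleGlszm <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  for (x0 in 1:d[1]) for (y0 in 1:d[2]) for (z0 in 1:d[3]) {
    a <- lev[x0, y0, z0]
    if (a == 0 || seen[x0, y0, z0]) next
    stack <- list(c(x0, y0, z0))
    seen[x0, y0, z0] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        x <- v[1] + dx; y <- v[2] + dy; z <- v[3] + dz
        if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) next
        if (!seen[x, y, z] && lev[x, y, z] == a) {
          seen[x, y, z] <- TRUE
          stack[[length(stack) + 1]] <- c(x, y, z)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  zmax <- max(1, vapply(zones, `[`, numeric(1), 2))
  m <- matrix(0, ng, zmax)
  for (zn in zones) m[zn[1], zn[2]] <- m[zn[1], zn[2]] + 1
  m
}

# per-voxel neighbourhood means restricted to in-mask neighbours
oracleNgtdm <- function(lev, ng) {
  d <- dim(lev)
  s <- numeric(ng); cnt <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || y2 < 1 || z2 < 1 || x2 > d[1] || y2 > d[2] || z2 > d[3])
        next
      b <- lev[x2, y2, z2]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    s[a] <- s[a] + abs(a - mean(nb))
    cnt[a] <- cnt[a] + 1
  }
  list(s = s, n = cnt)
}

# independent feature formulas, written as explicit double sums
oracleGlcmFeatures <- function(p) {
  ng <- nrow(p)
  energy <- contrast <- homog <- entropy <- dissim <- autoc <- 0
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  sig2 <- covv <- sumavg <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    energy <- energy + v^2
    contrast <- contrast + (i - j)^2 * v
    homog <- homog + v / (1 + abs(i - j))
    if (v > 0) entropy <- entropy - v * log2(v)
    dissim <- dissim + abs(i - j) * v
    autoc <- autoc + i * j * v
    sig2 <- sig2 + (i - mu)^2 * v
    covv <- covv + (i - mu) * (j - mu) * v
    sumavg <- sumavg + (i + j) * v
  }
  corr <- if (sig2 > 0) covv / sig2 else 0
  c(energy, contrast, corr, homog, entropy, sig2, sumavg, dissim, autoc)
}

oracleRunZoneFeatures <- function(m, voxelMass) {
  ng <- nrow(m); jm <- ncol(m)
  n <- sum(m)
  se <- le <- gln <- sn <- lge <- hge <- slge <- shge <- llge <- lhge <- 0
  mui <- muj <- 0
  for (i in 1:ng) for (j in 1:jm) {
    v <- m[i, j]
    se <- se + v / j^2;  le <- le + v * j^2
    lge <- lge + v / i^2; hge <- hge + v * i^2
    slge <- slge + v / (i^2 * j^2); shge <- shge + v * i^2 / j^2
    llge <- llge + v * j^2 / i^2;  lhge <- lhge + v * i^2 * j^2
    mui <- mui + i * v / n; muj <- muj + j * v / n
  }
  glv <- jv <- 0
  for (i in 1:ng) for (j in 1:jm) {
    glv <- glv + (i - mui)^2 * m[i, j] / n
    jv <- jv + (j - muj)^2 * m[i, j] / n
  }
  for (i in 1:ng) gln <- gln + sum(m[i, ])^2
  for (j in 1:jm) sn <- sn + sum(m[, j])^2
  c(se / n, le / n, gln / n, sn / n, n / voxelMass, lge / n, hge / n,
    slge / n, shge / n, llge / n, lhge / n, glv, jv)
}

oracleNgtdmFeatures <- function(s, cnt, eps = 1e-12) {
  nTot <- sum(cnt)
  p <- cnt / nTot
  occ <- which(p > 0)
  ngp <- length(occ)
  coarse <- min(1 / (sum(p * s) + eps), 1 / eps)
  contrast <- busy <- cx <- strength <- 0
  if (ngp > 1) {
    for (a in occ) for (b in occ) contrast <- contrast + p[a] * p[b] * (a - b)^2
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / nTot
    den <- 0
    for (a in occ) for (b in occ) den <- den + abs(a * p[a] - b * p[b])
    busy <- sum(p * s) / (den + eps)
    for (a in occ) for (b in occ)
      cx <- cx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    cx <- cx / nTot
    st <- 0
    for (a in occ) for (b in occ) st <- st + (p[a] + p[b]) * (a - b)^2
    strength <- st / (sum(s) + eps)
  }
  c(coarse, contrast, busy, cx, strength)
}

# all texture features of a quantized volume via the oracles only
oracleTextureFeatures <- function(lev, ng) {
  offs <- oracleOffsets13()
  glcm <- oracleGlcm(lev, ng, offs)
  byDir <- lapply(seq_len(nrow(offs)), function(k)
    oracleGlrlmDir(lev, ng, offs[k, ]))
  rmax <- max(vapply(byDir, ncol, integer(1)))
  glrlm <- matrix(0, ng, rmax)
  for (m in byDir) glrlm[, seq_len(ncol(m))] <- glrlm[, seq_len(ncol(m))] + m
  glszm <- oracleGlszm(lev, ng)
  ngt <- oracleNgtdm(lev, ng)
  jr <- matrix(seq_len(ncol(glrlm)), ng, ncol(glrlm), byrow = TRUE)
  list(glcm = oracleGlcmFeatures(glcm),
       glrlm = oracleRunZoneFeatures(glrlm, sum(jr * glrlm)),
       glszm = oracleRunZoneFeatures(glszm, sum(lev > 0)),
       ngtdm = oracleNgtdmFeatures(ngt$s, ngt$n),
       byDir = byDir, glszmMat = glszm)
}
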
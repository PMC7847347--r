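# Internal helpers shared across modules.

#' @noRd
.CLASS_LEVELS <- c("mutant", "wildtype")

# The 13 unique 3-D directions at Chebyshev distance 1 (one per +/- pair).
#' @noRd
.offsets13 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[!(o[, 1] == 0 & o[, 2] == 0 & o[, 3] == 0), , drop = FALSE]
  # keep one representative per +/- pair: first nonzero component positive
  keep <- apply(o, 1, function(v) v[which(v != 0)[1]] > 0)
  o <- o[keep, , drop = FALSE]
  storage.mode(o) <- "integer"
  dimnames(o) <- NULL
  o
}

# Deterministic splitting of one integer seed into per-subject / per-stage
# streams, so a subject's data do not depend on cohort size or stage order.
# All arithmetic stays below 2^53, result below 2^31.
#' @noRd
.deriveSeed <- function(seed, index, stream = 0L) {
  m <- 2147483647
  as.integer(((seed %% m) * 48271 + index * 32717 + stream * 104729) %% m) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
#' @noRd
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' @noRd
.assertLabels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .CLASS_LEVELS)
  if (length(bad) > 0)
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected 'mutant'/'wildtype')", call. = FALSE)
  factor(labels, levels = .CLASS_LEVELS)
}

# md5 of an arbitrary R object via its version-3 serialization.
#' @noRd
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3)
  close(con)
  unname(tools::md5sum(f))
}
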
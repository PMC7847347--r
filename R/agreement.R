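# Segmentation agreement (Dice) and cohort-balance statistics.

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2 |A n B| / (|A| + |B|)`: 0 means no overlap, 1 exact
#' overlap. Symmetric in its arguments.
#'
#' @param maskA,maskB logical arrays of identical shape (or
#'   [MaskedVolume-class] objects); at least one must be non-empty.
#' @return list with `dsc`, `sizeA`, `sizeB`, `intersection`.
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
#' diceCoefficient(a, a)$dsc  # 1
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (is(maskA, "MaskedVolume")) maskA <- tumorMask(maskA)
  if (is(maskB, "MaskedVolume")) maskB <- tumorMask(maskB)
  if (!identical(dim(maskA), dim(maskB)))
    stop("mask shapes differ", call. = FALSE)
  a <- sum(maskA); b <- sum(maskB)
  if (a == 0L && b == 0L)
    stop("both masks are empty", call. = FALSE)
  inter <- sum(maskA & maskB)
  list(dsc = 2 * inter / (a + b), sizeA = a, sizeB = b,
       intersection = inter)
}

#' Cohort balance tests between training and validation subsets
#'
#' For each characteristic, compares its distribution between the two
#' sides of a split: categorical variables with the chi-square test
#' without continuity correction, falling back to Fisher's exact test
#' when any expected cell count is below 5; continuous variables with
#' the classical equal-variance two-sample t-test. Variables with a
#' single observed level are flagged and skipped.
#'
#' @param characteristics data.frame of per-subject variables, rownames
#'   (or an `id` column) identifying subjects.
#' @param split a split from [splitCohort()] (list with `train` and
#'   `validation` id vectors).
#' @return data.frame with columns `variable`, `type`, `test`,
#'   `statistic`, `p.value`, `note`.
#' @export
cohortBalance <- function(characteristics, split) {
  ids <- if ("id" %in% colnames(characteristics)) characteristics$id
         else rownames(characteristics)
  if (is.null(ids)) stop("characteristics must identify subjects", call. = FALSE)
  grp <- ifelse(ids %in% split$train, "train",
                ifelse(ids %in% split$validation, "validation", NA))
  if (anyNA(grp)) stop("subjects not covered by the split", call. = FALSE)
  vars <- setdiff(colnames(characteristics), "id")
  rows <- lapply(vars, function(v) {
    x <- characteristics[[v]]
    if (is.numeric(x)) {
      if (length(unique(x)) < 2L)
        return(data.frame(variable = v, type = "continuous", test = NA,
                          statistic = NA_real_, p.value = NA_real_,
                          note = "degenerate: single value"))
      tt <- stats::t.test(x[grp == "train"], x[grp == "validation"],
                          var.equal = TRUE)
      return(data.frame(variable = v, type = "continuous",
                        test = "Student t", statistic = unname(tt$statistic),
                        p.value = tt$p.value, note = ""))
    }
    tab <- table(factor(grp, levels = c("train", "validation")), x)
    if (ncol(tab) < 2L)
      return(data.frame(variable = v, type = "categorical", test = NA,
                        statistic = NA_real_, p.value = NA_real_,
                        note = "degenerate: single level"))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      data.frame(variable = v, type = "categorical", test = "Fisher exact",
                 statistic = NA_real_, p.value = ft$p.value,
                 note = "expected count < 5")
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      data.frame(variable = v, type = "categorical", test = "chi-square",
                 statistic = unname(ct$statistic), p.value = ct$p.value,
                 note = "")
    }
  })
  do.call(rbind, rows)
}
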
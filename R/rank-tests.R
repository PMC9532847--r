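#' Row-wise two-tailed Wilcoxon rank-sum test
#'
#' Vectorized Mann-Whitney/Wilcoxon location test applied to every row of a
#' matrix, comparing columns in `idx1` against the remaining columns. Uses
#' the normal approximation with tie correction and continuity correction,
#' which is the regime the splicing caller operates in (group sizes in the
#' tens to hundreds); `stats::wilcox.test(exact = FALSE, correct = TRUE)`
#' is the reference implementation in the unit tests. The inner loop is
#' compiled (the caller evaluates hundreds of label permutations and
#' down-samples per event).
#'
#' Rows that are constant across both groups get p = 1.
#'
#' @param x numeric matrix (events x samples), no missing values.
#' @param idx1 column indices (or logical mask) of the first group.
#' @return numeric vector of two-tailed p-values, one per row.
#' @export
wilcoxon_rows <- function(x, idx1) {
  if (is.logical(idx1)) idx1 <- which(idx1)
  n1 <- length(idx1)
  stopifnot(n1 >= 1, ncol(x) - n1 >= 1, !anyNA(x))
  .wilcoxon_rows_cpp(x, as.integer(idx1))
}

#' Row-wise Fligner-Killeen scale test
#'
#' Vectorized Fligner-Killeen homogeneity-of-variances test (two groups)
#' applied to every row of a matrix: each group is centered at its median,
#' absolute deviations are jointly ranked, mapped to normal scores
#' `qnorm((1 + r/(n+1))/2)` and compared via the chi-square statistic with
#' one degree of freedom. `stats::fligner.test` is the reference in tests.
#'
#' Rows with zero variance in the normal scores get p = 1.
#'
#' @inheritParams wilcoxon_rows
#' @return numeric vector of p-values, one per row.
#' @export
fligner_rows <- function(x, idx1) {
  if (is.logical(idx1)) idx1 <- which(idx1)
  n1 <- length(idx1)
  stopifnot(n1 >= 2, ncol(x) - n1 >= 2, !anyNA(x))
  .fligner_rows_cpp(x, as.integer(idx1))
}
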
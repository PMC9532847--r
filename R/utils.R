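#' Linear-interpolation percentile
#'
#' All percentile rules in the pipeline (expression stratification, delta
#' prefilters, NMD probability classification, S-statistic stratification,
#' Matching-Score calls) use the same quantile definition: linear
#' interpolation between order statistics (type 7).
#'
#' @param x numeric vector (NAs removed).
#' @param pct percentile in [0, 100].
#' @return the percentile value.
#' @export
pctl <- function(x, pct) {
  stopifnot(is.numeric(pct), pct >= 0, pct <= 100)
  unname(stats::quantile(x, probs = pct / 100, na.rm = TRUE, type = 7))
}

#' Empirical p-value from a null collection
#'
#' The proportion of null statistics strictly smaller than the observed one
#' (literal mode), with an optional add-one pseudocount variant.
#'
#' @param observed observed p-value (or statistic on a smaller-is-stronger
#'   scale).
#' @param null_ps numeric vector of null p-values.
#' @param pseudocount if `TRUE`, return `(k + 1) / (n + 1)` instead of the
#'   literal proportion `k / n`.
#' @return empirical p-value in [0, 1].
#' @export
empirical_pvalue <- function(observed, null_ps, pseudocount = FALSE) {
  if (length(null_ps) == 0) stop("empty null collection")
  k <- sum(null_ps < observed, na.rm = TRUE)
  n <- sum(!is.na(null_ps))
  if (n == 0) stop("all null p-values missing")
  if (pseudocount) (k + 1) / (n + 1) else k / n
}

# Deterministic sub-stream seed for a named pipeline stage. Keeps every
# derived seed a valid 32-bit integer.
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Internal guard: x is a numeric matrix with dimnames.
assert_named_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have row and column names")
  invisible(x)
}
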
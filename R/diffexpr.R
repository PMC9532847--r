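#' Stratify samples by a gene's expression percentile
#'
#' Samples at or above the given percentile of the gene's expression
#' distribution (linear-interpolation quantile) form the "high" group; the
#' remainder form "rest".
#'
#' @param expr genes x samples expression matrix.
#' @param gene gene identifier (row of `expr`).
#' @param pct percentile threshold (default 75).
#' @return logical vector (TRUE = high), named by sample.
#' @export
stratify_by_expression <- function(expr, gene, pct = 75) {
  assert_named_matrix(expr, "expression matrix")
  if (!gene %in% rownames(expr)) stop("gene not found: ", gene)
  if (ncol(expr) < 8) stop("need at least 8 samples to stratify")
  v <- expr[gene, ]
  thr <- pctl(v, pct)
  high <- v >= thr
  if (all(high) || !any(high))
    stop("degenerate stratification: one group is empty")
  high
}

#' Per-gene two-tailed Kolmogorov-Smirnov differential test
#'
#' Compares each gene's TPM distribution between the high group and the
#' rest with a two-sample two-tailed KS test; p-values are
#' Benjamini-Hochberg adjusted across genes. Genes that are all-zero in
#' both groups get p = 1 and are flagged.
#'
#' @param expr genes x samples matrix.
#' @param high logical group mask from [stratify_by_expression()].
#' @return data.frame (gene, ks_stat, p, fdr, flat) in the row order of
#'   `expr`.
#' @export
ks_diffexpr <- function(expr, high) {
  if (sum(high) < 3 || sum(!high) < 3) stop("both groups need >= 3 samples")
  res <- t(apply(expr, 1, function(v) {
    if (all(v == 0)) return(c(0, 1, 1))
    kt <- suppressWarnings(stats::ks.test(v[high], v[!high]))
    c(unname(kt$statistic), kt$p.value, 0)
  }))
  data.frame(gene = rownames(expr), ks_stat = res[, 1], p = res[, 2],
             fdr = stats::p.adjust(res[, 2], method = "BH"),
             flat = res[, 3] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Monte Carlo null distribution of per-gene KS p-values
#'
#' For each iteration, group labels of the observed sizes are shuffled
#' (without replacement) and the per-gene two-tailed KS p-value is
#' recorded; all genes share the same label draw within an iteration.
#'
#' @param expr genes x samples matrix.
#' @param n_high size of the high group.
#' @param n_iter number of iterations (study default 10,000).
#' @param seed integer seed.
#' @return genes x n_iter matrix of null p-values.
#' @export
run_null_iterations <- function(expr, n_high, n_iter = 10000L, seed = 1L) {
  if (n_iter <= 0) stop("n_iter must be positive")
  if (n_iter < 100) warning("fewer than 100 null iterations")
  set.seed(substream_seed(seed, "diffexpr_null"))
  n <- ncol(expr)
  out <- matrix(NA_real_, nrow = nrow(expr), ncol = n_iter,
                dimnames = list(rownames(expr), NULL))
  for (it in seq_len(n_iter)) {
    hi <- rep(FALSE, n)
    hi[sample.int(n, n_high)] <- TRUE
    out[, it] <- apply(expr, 1, function(v) {
      if (all(v == 0)) return(1)
      suppressWarnings(stats::ks.test(v[hi], v[!hi]))$p.value
    })
  }
  out
}

# log2 fold change of group medians with pseudocount 1 (guards zero
# medians).
median_log2fc <- function(expr, high) {
  apply(expr, 1, function(v)
    log2((stats::median(v[high]) + 1) / (stats::median(v[!high]) + 1)))
}

#' Call differentially expressed genes
#'
#' Combines the KS/BH results, empirical p-values and fold-change
#' criteria into final calls. In `counts` mode a gene must satisfy
#' FDR <= 0.01, emp-pv <= 0.01, and at least one external parametric
#' source (e.g. DESeq2 or edgeR result tables) with |log2FC| >= 0.2 and
#' adjusted p <= 0.01. In `tpm_only` mode the external requirement is
#' replaced by |log2 median-TPM FC| >= 0.2 (pseudocount 1). Direction is
#' the fold-change sign.
#'
#' @param ks data.frame from [ks_diffexpr()].
#' @param emp named numeric vector of empirical p-values (per gene).
#' @param log2fc named numeric vector of median-TPM log2 fold changes.
#' @param mode `"counts"` or `"tpm_only"`.
#' @param external in `counts` mode, a list of data.frames with columns
#'   (gene, log2FC, adjusted_p).
#' @return data.frame with per-gene statistics and
#'   `call` in {up, down, unchanged}.
#' @export
call_differential <- function(ks, emp, log2fc, mode = c("tpm_only", "counts"),
                              external = NULL) {
  mode <- match.arg(mode)
  genes <- ks$gene
  emp <- emp[genes]
  log2fc <- log2fc[genes]
  stat_ok <- ks$fdr <= 0.01 & emp <= 0.01
  if (mode == "counts") {
    if (is.null(external) || length(external) == 0)
      stop("counts mode requires at least one external parametric table")
    ext_ok <- rep(FALSE, length(genes))
    ext_fc <- rep(NA_real_, length(genes))
    for (tab in external) {
      need <- c("gene", "log2FC", "adjusted_p")
      if (!all(need %in% names(tab)))
        stop("external table lacks columns: ",
             paste(setdiff(need, names(tab)), collapse = ", "))
      m <- match(genes, tab$gene)
      ok <- !is.na(m) & abs(tab$log2FC[m]) >= 0.2 & tab$adjusted_p[m] <= 0.01
      ok[is.na(ok)] <- FALSE
      ext_fc[ok & !ext_ok] <- tab$log2FC[m][ok & !ext_ok]
      ext_ok <- ext_ok | ok
    }
    called <- stat_ok & ext_ok
    dir_fc <- ifelse(is.na(ext_fc), log2fc, ext_fc)
  } else {
    called <- stat_ok & abs(log2fc) >= 0.2
    dir_fc <- log2fc
  }
  call <- ifelse(!called, "unchanged", ifelse(dir_fc > 0, "up", "down"))
  data.frame(gene = genes, ks_stat = ks$ks_stat, p = ks$p, fdr = ks$fdr,
             emp_pv = unname(emp), log2fc = unname(log2fc),
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Full nonparametric differential-expression pipeline
#'
#' Stratifies by the focal gene, runs the KS tests, the Monte Carlo
#' empirical null and the final calling in one pass.
#'
#' @param expr genes x samples matrix (the focal gene's own row is
#'   excluded from testing).
#' @param gene focal gene used for stratification.
#' @param mode,external see [call_differential()].
#' @param n_iter null iterations.
#' @param seed integer seed.
#' @param pct stratification percentile.
#' @return data.frame of per-gene calls (see [call_differential()]).
#' @export
diffexpr_pipeline <- function(expr, gene, mode = "tpm_only",
                              external = NULL, n_iter = 10000L, seed = 1L,
                              pct = 75) {
  high <- stratify_by_expression(expr, gene, pct)
  test_expr <- expr[setdiff(rownames(expr), gene), , drop = FALSE]
  ks <- ks_diffexpr(test_expr, high)
  nulls <- run_null_iterations(test_expr, sum(high), n_iter, seed)
  emp <- vapply(seq_len(nrow(ks)), function(i)
    empirical_pvalue(ks$p[i], nulls[i, ]), numeric(1))
  names(emp) <- ks$gene
  fc <- median_log2fc(test_expr, high)
  call_differential(ks, emp, fc, mode = mode, external = external)
}
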
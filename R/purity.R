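#' Mix tumor and benign expression profiles at a given purity
#'
#' Each tumor sample is combined with one independently drawn benign
#' profile (sampled with replacement):
#' `g = tumor * p/100 + benign * (1 - p/100)` entrywise, so `p = 100`
#' reproduces the tumor matrix exactly and `p = 0` the drawn benign
#' profiles.
#'
#' @param tumor,benign genes x samples matrices over the same gene set.
#' @param p tumor purity in percent (0-100).
#' @param seed integer seed for the benign draw.
#' @return mixed genes x samples matrix (tumor sample names).
#' @export
mix_profiles <- function(tumor, benign, p, seed = 1L) {
  if (p < 0 || p > 100) stop("p must be in [0, 100]")
  bad <- c(setdiff(rownames(tumor), rownames(benign)),
           setdiff(rownames(benign), rownames(tumor)))
  if (length(bad) > 0)
    stop("gene sets differ: ", paste(unique(bad), collapse = ", "))
  benign <- benign[rownames(tumor), , drop = FALSE]
  set.seed(substream_seed(seed, "purity_mix"))
  draw <- sample.int(ncol(benign), ncol(tumor), replace = TRUE)
  tumor * (p / 100) + benign[, draw, drop = FALSE] * (1 - p / 100)
}

#' Tumor-purity sweep of the covariance analysis
#'
#' For each purity level and iteration, mixes the tumor cohort with
#' randomly drawn benign profiles, recomputes the TF relative-importance
#' decomposition of cumulative SRG expression (and optionally the
#' differential-SRG calls), and aggregates the per-TF mean and SD of the
#' R-squared contribution across iterations, plus a per-gene
#' differential-call success rate per level.
#'
#' @param tumor,benign genes x samples matrices sharing the gene set.
#' @param tf_names,srg_names row subsets acting as regressors / response
#'   pool.
#' @param levels purity levels in percent (default 10, 20, ..., 100).
#' @param n_iter iterations per level (study default 100).
#' @param seed integer seed.
#' @param run_diffexpr also run the differential-expression caller per
#'   iteration.
#' @param diffexpr_n_null Monte Carlo null iterations inside each
#'   differential run (0 disables the empirical-p criterion, leaving the
#'   FDR and fold-change conjuncts).
#' @return list with `contributions` (data.frame: level, tf, mean_share,
#'   sd_share) and `diffexpr_sr` (data.frame: level, gene, sr; NULL when
#'   disabled).
#' @export
purity_sweep <- function(tumor, benign, tf_names, srg_names,
                         levels = seq(10, 100, by = 10), n_iter = 100L,
                         seed = 1L, run_diffexpr = FALSE,
                         diffexpr_n_null = 0L) {
  stopifnot(all(tf_names %in% rownames(tumor)),
            all(srg_names %in% rownames(tumor)))
  contrib <- list()
  sr_rows <- list()
  for (p in sort(levels)) {
    shares <- matrix(NA_real_, nrow = n_iter, ncol = length(tf_names),
                     dimnames = list(NULL, tf_names))
    calls <- matrix(FALSE, nrow = n_iter, ncol = length(srg_names),
                    dimnames = list(NULL, srg_names))
    for (it in seq_len(n_iter)) {
      it_seed <- substream_seed(seed, sprintf("sweep_p%d_i%d", p, it))
      mixed <- mix_profiles(tumor, benign, p, seed = it_seed)
      res <- tryCatch({
        X <- preprocess_regressors(t(mixed[tf_names, , drop = FALSE]))
        y <- colSums(mixed[srg_names, , drop = FALSE])
        y <- as.numeric(preprocess_regressors(data.frame(y = y)))
        sh <- lmg_importance(y, X)
        full <- stats::setNames(rep(NA_real_, length(tf_names)), tf_names)
        full[names(sh)] <- sh
        full
      }, error = function(e) NULL)
      if (!is.null(res)) shares[it, ] <- res
      if (run_diffexpr) {
        dr <- tryCatch({
          sub <- mixed[c(tf_names[1], srg_names), , drop = FALSE]
          high <- stratify_by_expression(sub, tf_names[1])
          srg_expr <- sub[srg_names, , drop = FALSE]
          ks <- ks_diffexpr(srg_expr, high)
          fc <- median_log2fc(srg_expr, high)
          if (diffexpr_n_null > 0) {
            nulls <- run_null_iterations(srg_expr, sum(high),
                                         n_iter = diffexpr_n_null,
                                         seed = it_seed)
            emp <- vapply(seq_len(nrow(ks)), function(i)
              empirical_pvalue(ks$p[i], nulls[i, ]), numeric(1))
          } else {
            emp <- rep(0, nrow(ks))
          }
          names(emp) <- ks$gene
          cd <- call_differential(ks, emp, fc, mode = "tpm_only")
          stats::setNames(cd$call != "unchanged", cd$gene)
        }, error = function(e) NULL)
        if (!is.null(dr)) calls[it, names(dr)] <- dr
      }
    }
    contrib[[length(contrib) + 1L]] <- data.frame(
      level = p, tf = tf_names,
      mean_share = colMeans(shares, na.rm = TRUE),
      sd_share = apply(shares, 2, stats::sd, na.rm = TRUE),
      row.names = NULL, stringsAsFactors = FALSE)
    if (run_diffexpr)
      sr_rows[[length(sr_rows) + 1L]] <- data.frame(
        level = p, gene = srg_names, sr = colMeans(calls),
        row.names = NULL, stringsAsFactors = FALSE)
  }
  list(contributions = do.call(rbind, contrib),
       diffexpr_sr = if (run_diffexpr) do.call(rbind, sr_rows) else NULL)
}
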
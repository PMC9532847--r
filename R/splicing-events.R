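#' Filter a PSI atlas and mean-impute missing values
#'
#' Events are retained iff (i) more than 75% of samples have a value,
#' (ii) the mean of available PSI lies strictly between 0.01 and 0.99
#' (i.e. not constitutively excluded/included), and (iii) the host gene
#' carries fewer than 500 events. Remaining missing entries are replaced
#' by the event's mean over available samples, which leaves every event's
#' mean unchanged.
#'
#' @param psi events x samples matrix with NAs for missing values.
#' @param meta per-event metadata data.frame with columns `event_id` and
#'   `gene`, aligned with the rows of `psi`.
#' @param min_frac minimum fraction of observed samples (strict >).
#' @param mu_bounds open interval the event mean must fall in.
#' @param max_gene_events host-gene event-count bound (strict <).
#' @return list with the imputed `psi` matrix and the filtered `meta`.
#' @export
filter_and_impute <- function(psi, meta, min_frac = 0.75,
                              mu_bounds = c(0.01, 0.99),
                              max_gene_events = 500L) {
  stopifnot(nrow(psi) == nrow(meta))
  obs_frac <- rowMeans(!is.na(psi))
  mu <- rowMeans(psi, na.rm = TRUE)
  gene_n <- table(meta$gene)
  keep <- obs_frac > min_frac &
    mu > mu_bounds[1] & mu < mu_bounds[2] &
    as.integer(gene_n[meta$gene]) < max_gene_events
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no events survive filtering")
  psi <- psi[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  mu <- rowMeans(psi, na.rm = TRUE)
  na_idx <- which(is.na(psi), arr.ind = TRUE)
  if (nrow(na_idx) > 0) psi[na_idx] <- mu[na_idx[, 1]]
  list(psi = psi, meta = meta)
}

#' Per-event group means, SDs and their differences
#'
#' @param psi imputed events x samples matrix.
#' @param high logical group mask (high-TF samples).
#' @return data.frame with per-event `mu_high`, `mu_rest`, `sd_high`,
#'   `sd_rest`, `delta_mu` (high - rest), `delta_sigma`, and the overall
#'   mean `mu_all`.
#' @export
delta_stats <- function(psi, high) {
  if (sum(high) < 3 || sum(!high) < 3) stop("both groups need >= 3 samples")
  xh <- psi[, high, drop = FALSE]
  xr <- psi[, !high, drop = FALSE]
  mu_h <- rowMeans(xh)
  mu_r <- rowMeans(xr)
  sd_h <- apply(xh, 1, stats::sd)
  sd_r <- apply(xr, 1, stats::sd)
  data.frame(event_id = rownames(psi), mu_high = mu_h, mu_rest = mu_r,
             sd_high = sd_h, sd_rest = sd_r,
             delta_mu = mu_h - mu_r, delta_sigma = sd_h - sd_r,
             mu_all = rowMeans(psi), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Quantile prefilter on delta mu / delta sigma
#'
#' Discards events with negligible changes: an event passes iff its
#' delta mu is strictly below the 15th or strictly above the 85th
#' percentile of the delta-mu distribution, or its delta sigma is
#' strictly below the 20th or strictly above the 80th percentile of the
#' delta-sigma distribution. Percentiles are computed once over all
#' filtered events.
#'
#' @param stats data.frame from [delta_stats()].
#' @param mu_pcts,sigma_pcts lower/upper percentile pairs.
#' @return logical pass flag per event.
#' @export
quantile_prefilter <- function(stats, mu_pcts = c(15, 85),
                               sigma_pcts = c(20, 80)) {
  if (nrow(stats) < 100)
    stop("need at least 100 events for meaningful percentiles")
  dm <- stats$delta_mu
  ds <- stats$delta_sigma
  dm_lo <- pctl(dm, mu_pcts[1]); dm_hi <- pctl(dm, mu_pcts[2])
  ds_lo <- pctl(ds, sigma_pcts[1]); ds_hi <- pctl(ds, sigma_pcts[2])
  (dm < dm_lo) | (dm > dm_hi) | (ds < ds_lo) | (ds > ds_hi)
}

#' Dual nonparametric tests on prefilter-passing events
#'
#' Two-tailed Wilcoxon rank-sum (location) and Fligner-Killeen (scale)
#' per passing event, with Benjamini-Hochberg correction within each test
#' family across the tested events.
#'
#' @param psi imputed events x samples matrix.
#' @param high logical group mask.
#' @param passers logical prefilter flags (from [quantile_prefilter()]).
#' @return data.frame (event_id, wilcox_p, wilcox_fdr, fligner_p,
#'   fligner_fdr) for passing events only.
#' @export
test_events <- function(psi, high, passers) {
  x <- psi[passers, , drop = FALSE]
  wp <- wilcoxon_rows(x, high)
  fp <- fligner_rows(x, high)
  data.frame(event_id = rownames(x),
             wilcox_p = wp, wilcox_fdr = stats::p.adjust(wp, "BH"),
             fligner_p = fp, fligner_fdr = stats::p.adjust(fp, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shuffle-based empirical p-values for both tests
#'
#' Permutes the group labels `n_iter` times; for each tested event the
#' empirical p-value is the proportion of null p-values strictly below
#' the observed one (shared [empirical_pvalue()] semantics, literal
#' mode).
#'
#' @param psi imputed events x samples matrix (tested events only).
#' @param high logical group mask.
#' @param observed data.frame from [test_events()] for the same events.
#' @param n_iter number of label shuffles (study default 1,000).
#' @param seed integer seed.
#' @return data.frame (event_id, wilcox_emp, fligner_emp).
#' @export
shuffle_empirical <- function(psi, high, observed, n_iter = 1000L, seed = 1L) {
  stopifnot(nrow(psi) == nrow(observed))
  set.seed(substream_seed(seed, "shuffle"))
  n <- ncol(psi)
  n1 <- sum(high)
  idx_mat <- vapply(seq_len(n_iter), function(i) sample.int(n, n1),
                    integer(n1))
  cnt <- .shuffle_counts_cpp(psi, idx_mat, observed$wilcox_p,
                             observed$fligner_p)
  data.frame(event_id = observed$event_id,
             wilcox_emp = cnt$wilcox / n_iter,
             fligner_emp = cnt$fligner / n_iter,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Down-sampling success rate for both tests
#'
#' Repeatedly down-samples the larger ("rest") group to the size of the
#' high group (without replacement) and re-runs both tests; the success
#' rate (SR) is the fraction of iterations with p < 0.05. Guards against
#' significance driven purely by the group-size imbalance.
#'
#' @inheritParams shuffle_empirical
#' @param alpha per-iteration significance level.
#' @return data.frame (event_id, wilcox_sr, fligner_sr).
#' @export
downsample_success_rate <- function(psi, high, n_iter = 1000L, seed = 1L,
                                    alpha = 0.05) {
  set.seed(substream_seed(seed, "downsample"))
  hi_idx <- which(high)
  rest_idx <- which(!high)
  n1 <- length(hi_idx)
  if (length(rest_idx) <= n1) {
    warning("rest group not larger than high group; SR computed on full rest")
    wp <- wilcoxon_rows(psi, hi_idx) < alpha
    fp <- fligner_rows(psi, hi_idx) < alpha
    return(data.frame(event_id = rownames(psi),
                      wilcox_sr = as.numeric(wp), fligner_sr = as.numeric(fp),
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  sub_mat <- vapply(seq_len(n_iter), function(i) sample(rest_idx, n1),
                    integer(n1))
  cnt <- .downsample_counts_cpp(psi, hi_idx, sub_mat, alpha)
  data.frame(event_id = rownames(psi),
             wilcox_sr = cnt$wilcox / n_iter, fligner_sr = cnt$fligner / n_iter,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Final regulated/unregulated classification
#'
#' An event is called regulated iff, for at least one of the two tests,
#' FDR < 0.05 AND emp-pv < 0.05 AND SR > 0.7 hold jointly (the same test
#' must satisfy all three). Events failing the prefilter or the
#' thresholds are unregulated.
#'
#' @param stats full per-event stats data.frame (merged output of the
#'   pipeline; must contain the fdr/emp/sr columns and `prefilter_pass`).
#' @param fdr_max,emp_max,sr_min thresholds (strict comparisons).
#' @return character vector of calls in {regulated, unregulated}.
#' @export
classify_events <- function(stats, fdr_max = 0.05, emp_max = 0.05,
                            sr_min = 0.7) {
  w_ok <- !is.na(stats$wilcox_fdr) &
    stats$wilcox_fdr < fdr_max & stats$wilcox_emp < emp_max &
    stats$wilcox_sr > sr_min
  f_ok <- !is.na(stats$fligner_fdr) &
    stats$fligner_fdr < fdr_max & stats$fligner_emp < emp_max &
    stats$fligner_sr > sr_min
  reg <- stats$prefilter_pass & (w_ok | f_ok)
  reg[is.na(reg)] <- FALSE
  ifelse(reg, "regulated", "unregulated")
}

#' End-to-end splicing-event caller
#'
#' Runs filtering/imputation, delta statistics, quantile prefilter, dual
#' tests with BH correction, shuffle-based empirical p-values,
#' down-sampling success rates, and final classification.
#'
#' @param psi raw events x samples PSI matrix (NAs allowed).
#' @param meta per-event metadata (event_id, gene, ...).
#' @param high logical high-TF group mask over samples.
#' @param n_shuffle,n_downsample iteration counts (study defaults 1,000).
#' @param seed integer seed.
#' @return data.frame with one row per retained event: delta statistics,
#'   test p-values/FDRs, empirical p-values, success rates,
#'   `prefilter_pass` and `call`; attribute `n_excluded` counts events
#'   removed by the atlas filter.
#' @export
call_splicing_events <- function(psi, meta, high, n_shuffle = 1000L,
                                 n_downsample = 1000L, seed = 1L) {
  n_in <- nrow(psi)
  fl <- filter_and_impute(psi, meta)
  st <- delta_stats(fl$psi, high)
  st$prefilter_pass <- quantile_prefilter(st)
  tested <- fl$psi[st$prefilter_pass, , drop = FALSE]
  tt <- test_events(fl$psi, high, st$prefilter_pass)
  emp <- shuffle_empirical(tested, high, tt, n_iter = n_shuffle, seed = seed)
  sr <- downsample_success_rate(tested, high, n_iter = n_downsample,
                                seed = seed)
  res <- merge(merge(tt, emp, by = "event_id"), sr, by = "event_id")
  out <- merge(st, res, by = "event_id", all.x = TRUE, sort = FALSE)
  out <- out[match(st$event_id, out$event_id), ]
  out$call <- classify_events(out)
  out <- merge(fl$meta, out, by = "event_id", sort = FALSE)
  attr(out, "n_excluded") <- n_in - nrow(fl$psi)
  out
}

#' Filter Whippet-style differential-splicing output
#'
#' Drops events whose confidence-interval width is >= 0.2 in at least one
#' sample, then calls an event regulated iff its splicing complexity is
#' above K0, its probability is >= 0.9 and |delta PSI| > 0.05. Remaining
#' events are retained as unregulated controls.
#'
#' @param tab data.frame with columns `event_id`, `ci_width_max` (the
#'   largest per-sample CI width), `complexity` (ordered categorical
#'   "K0" < "K1" < ...), `probability`, `delta_psi`.
#' @return `tab` restricted to retained events with an added `call`
#'   column.
#' @export
filter_whippet_output <- function(tab) {
  need <- c("event_id", "ci_width_max", "complexity", "probability",
            "delta_psi")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  tab <- tab[tab$ci_width_max < 0.2, , drop = FALSE]
  k_level <- as.integer(sub("^K", "", as.character(tab$complexity)))
  if (anyNA(k_level)) stop("complexity must be K0, K1, ... labels")
  reg <- k_level > 0 & tab$probability >= 0.9 & abs(tab$delta_psi) > 0.05
  tab$call <- ifelse(reg, "regulated", "unregulated")
  tab
}
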
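make_meta <- function(n, gene = sprintf("GENE%03d", ceiling(seq_len(n) / 8))) {
  data.frame(event_id = sprintf("EV%04d", seq_len(n)), gene = gene,
             category = "CE", chrom = "chr1",
             start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 100L,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("atlas filter applies the three retention rules and mean-imputes", {
  psi <- rbind(
    keep = c(0.5, 0.6, NA, 0.4, 0.5, 0.4, 0.6, 0.5, 0.5, 0.5),
    sparse = c(0.5, NA, NA, NA, 0.4, 0.5, NA, NA, 0.6, 0.5),
    const_high = c(rep(0.999, 9), 0.97))
  colnames(psi) <- paste0("S", 1:10)
  meta <- make_meta(3)
  out <- filter_and_impute(psi, meta)
  expect_identical(rownames(out$psi), "keep")
  # imputed entry equals the pre-imputation mean, which is unchanged
  pre_mean <- mean(psi["keep", ], na.rm = TRUE)
  expect_equal(unname(out$psi["keep", 3]), pre_mean)
  expect_equal(unname(mean(out$psi["keep", ])), pre_mean)

  # host genes at the event-count cap are excluded entirely
  n <- 600
  psi_big <- matrix(0.5 + rnorm(n * 10, sd = 0.05), nrow = n,
                    dimnames = list(sprintf("EV%04d", 1:n), paste0("S", 1:10)))
  meta_big <- make_meta(n, gene = "ONEGENE")
  expect_error(filter_and_impute(psi_big, meta_big), "no events")

  expect_error(filter_and_impute(psi["const_high", , drop = FALSE],
                                 meta[3, ]), "no events")
})

test_that("delta statistics equal a direct two-pass oracle", {
  set.seed(4)
  psi <- matrix(rbeta(50 * 30, 2, 2), nrow = 50,
                dimnames = list(sprintf("E%02d", 1:50), paste0("S", 1:30)))
  high <- c(rep(TRUE, 10), rep(FALSE, 20))
  st <- delta_stats(psi, high)
  for (i in c(1, 25, 50)) {
    expect_equal(st$delta_mu[i],
                 mean(psi[i, high]) - mean(psi[i, !high]), tolerance = 1e-12)
    expect_equal(st$delta_sigma[i],
                 sd(psi[i, high]) - sd(psi[i, !high]), tolerance = 1e-12)
  }
  # identical groups: zero deltas
  psi2 <- cbind(psi[, 1:10], psi[, 1:10])
  colnames(psi2) <- paste0("S", 1:20)
  st2 <- delta_stats(psi2, c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(st2$delta_mu, rep(0, 50))
  expect_equal(st2$delta_sigma, rep(0, 50))
})

test_that("quantile prefilter uses strict comparisons and the stated bands", {
  set.seed(5)
  st <- data.frame(delta_mu = rnorm(1000), delta_sigma = rnorm(1000))
  pass <- quantile_prefilter(st)
  # union of a 30% band and a 40% band
  expect_gte(mean(pass), 0.4)
  expect_lte(mean(pass), 0.7)
  mu_only <- st$delta_mu < pctl(st$delta_mu, 15) |
    st$delta_mu > pctl(st$delta_mu, 85)
  expect_true(all(pass[mu_only]))
  expect_gte(mean(pass), mean(mu_only))
  # an event exactly at the 85th percentile fails the strict comparison
  st2 <- data.frame(delta_mu = c(rep(0, 99), seq_len(101) / 101),
                    delta_sigma = 0)
  q85 <- pctl(st2$delta_mu, 85)
  at <- which(abs(st2$delta_mu - q85) < 1e-15)
  if (length(at) > 0) expect_false(any(quantile_prefilter(st2)[at]))
  expect_error(quantile_prefilter(st[1:50, ]), "100")
})

test_that("dual tests separate location and scale effects", {
  set.seed(6)
  n1 <- 40; n2 <- 120
  loc <- t(replicate(60, c(rbeta(n1, 30, 20), rbeta(n2, 20, 30))))
  scl <- t(replicate(60, c(rbeta(n1, 4, 4), rbeta(n2, 60, 60))))
  nul <- t(replicate(60, rbeta(n1 + n2, 10, 10)))
  psi <- rbind(loc, scl, nul)
  rownames(psi) <- sprintf("E%03d", 1:180)
  colnames(psi) <- paste0("S", 1:(n1 + n2))
  high <- c(rep(TRUE, n1), rep(FALSE, n2))
  tt <- test_events(psi, high, rep(TRUE, 180))
  expect_lt(median(tt$wilcox_p[1:60]), 1e-6)
  expect_lt(median(tt$fligner_p[61:120]), 1e-6)
  expect_gt(median(tt$fligner_p[1:60]), median(tt$fligner_p[61:120]))
  # null events: p-values roughly uniform
  expect_gt(suppressWarnings(ks.test(tt$wilcox_p[121:180], "punif"))$p.value, 0.01)
})

test_that("shuffle empirical p-values are seeded and uniform under the null", {
  set.seed(7)
  psi <- matrix(rbeta(500 * 60, 5, 5), nrow = 500,
                dimnames = list(sprintf("E%03d", 1:500), paste0("S", 1:60)))
  high <- c(rep(TRUE, 15), rep(FALSE, 45))
  tt <- test_events(psi, high, rep(TRUE, 500))
  e1 <- shuffle_empirical(psi, high, tt, n_iter = 100, seed = 2)
  e2 <- shuffle_empirical(psi, high, tt, n_iter = 100, seed = 2)
  expect_identical(e1, e2)
  expect_gt(suppressWarnings(ks.test(e1$wilcox_emp, "punif"))$p.value, 0.01)
})

test_that("down-sampling success rate reflects the nominal level and power", {
  set.seed(8)
  n1 <- 90; n2 <- 300
  null_psi <- t(replicate(40, rbeta(n1 + n2, 25, 25)))
  shift_psi <- t(replicate(40, c(rbeta(n1, 0.8 * 50, 0.2 * 50),
                                 rbeta(n2, 0.5 * 50, 0.5 * 50))))
  psi <- rbind(null_psi, shift_psi)
  rownames(psi) <- sprintf("E%03d", 1:80)
  colnames(psi) <- paste0("S", 1:(n1 + n2))
  high <- c(rep(TRUE, n1), rep(FALSE, n2))
  sr <- downsample_success_rate(psi, high, n_iter = 100, seed = 3)
  expect_lt(mean(sr$wilcox_sr[1:40]), 0.15)      # near the nominal level
  expect_gt(min(sr$wilcox_sr[41:80]), 0.9)       # planted delta mu = 0.3
  sr2 <- downsample_success_rate(psi, high, n_iter = 100, seed = 3)
  expect_identical(sr, sr2)
  expect_warning(
    downsample_success_rate(psi[1:5, c(1:90, 91:150)],
                            c(rep(TRUE, 90), rep(FALSE, 60)), n_iter = 10,
                            seed = 1),
    "not larger")
})

test_that("classification requires the full conjunction within one test", {
  base <- data.frame(event_id = "e", prefilter_pass = TRUE,
                     wilcox_fdr = 0.01, wilcox_emp = 0.01, wilcox_sr = 0.9,
                     fligner_fdr = 0.9, fligner_emp = 0.9, fligner_sr = 0)
  expect_equal(classify_events(base), "regulated")
  one_off <- base; one_off$wilcox_emp <- 0.2
  expect_equal(classify_events(one_off), "unregulated")
  # mixing conjuncts across tests must not rescue the call
  mixed <- base
  mixed$wilcox_sr <- 0.2; mixed$fligner_sr <- 0.9
  expect_equal(classify_events(mixed), "unregulated")
  # boundary values fail the strict comparisons
  bound <- base; bound$wilcox_fdr <- 0.05
  expect_equal(classify_events(bound), "unregulated")
  unfil <- base; unfil$prefilter_pass <- FALSE
  expect_equal(classify_events(unfil), "unregulated")
})

test_that("the caller is invariant to sample ordering", {
  cohort <- small_cohort(seed = 9, n_samples = 80, n_events = 250,
                         frac_regulated = 0.2)
  ev1 <- call_splicing_events(cohort$psi$psi, cohort$psi$meta, cohort$high,
                              n_shuffle = 30, n_downsample = 30, seed = 1)
  perm <- sample(ncol(cohort$psi$psi))
  ev2 <- call_splicing_events(cohort$psi$psi[, perm], cohort$psi$meta,
                              cohort$high[perm],
                              n_shuffle = 30, n_downsample = 30, seed = 1)
  expect_equal(ev1$delta_mu, ev2$delta_mu, tolerance = 1e-12)
  expect_equal(ev1$wilcox_p, ev2$wilcox_p, tolerance = 1e-12)
  expect_identical(ev1$prefilter_pass, ev2$prefilter_pass)
})

test_that("Whippet-style filtering applies the quoted thresholds", {
  tab <- data.frame(
    event_id = paste0("w", 1:4),
    ci_width_max = c(0.25, 0.1, 0.1, 0.1),
    complexity = c("K1", "K1", "K1", "K0"),
    probability = c(0.95, 0.95, 0.95, 0.95),
    delta_psi = c(0.06, 0.06, 0.05, 0.06))
  out <- filter_whippet_output(tab)
  expect_false("w1" %in% out$event_id)              # wide CI dropped
  expect_equal(out$call[out$event_id == "w2"], "regulated")
  expect_equal(out$call[out$event_id == "w3"], "unregulated")  # strict >
  expect_equal(out$call[out$event_id == "w4"], "unregulated")  # K0
  expect_error(filter_whippet_output(tab[, -2]), "missing columns")
})
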
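test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
  expect_error(sim_config(psi_concentration = 0), "psi_concentration")
  expect_error(sim_config(delta_mu_effect = 1.5), "delta_mu_effect")
  w <- matrix(Inf, 148, 4)
  expect_error(sim_config(tf_to_srg_weights = w), "finite")
})

test_that("expression generator is deterministic and respects the weights", {
  cfg <- sim_config(seed = 5, n_samples = 60, n_genes = 10,
                    srg_names = sprintf("G%02d", 1:10))
  e1 <- generate_expression(cfg)
  e2 <- generate_expression(cfg)
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0))

  # zero weights: SRG rows independent of TF rows
  w0 <- matrix(0, 10, 4)
  cfg0 <- sim_config(seed = 5, n_samples = 500, n_genes = 10,
                     srg_names = sprintf("G%02d", 1:10),
                     tf_to_srg_weights = w0)
  e0 <- generate_expression(cfg0)
  cors <- abs(cor(log(e0["FOXA1", ]), log(t(e0[5:14, ]))))
  expect_lt(max(cors), 0.15)

  # weight 1 on one TF, no noise: SRG log-TPM tracks the TF exactly
  w1 <- matrix(0, 1, 4); w1[1, 2] <- 1
  cfg1 <- sim_config(seed = 2, n_samples = 40, n_genes = 1,
                     srg_names = "G1", tf_to_srg_weights = w1,
                     expr_noise_sd = 0)
  e <- generate_expression(cfg1)
  expect_equal(log(e["G1", ]), log(e["AR", ]), tolerance = 1e-12)
})

test_that("dominant planted regressor carries the largest fitted effect", {
  cfg <- sim_config(seed = 3, n_samples = 500)
  e <- generate_expression(cfg)
  X <- scale(t(log(e[cfg$tf_names, ])))
  y <- scale(log(colSums(e[cfg$srg_names, ])))
  beta <- fit_glm(as.numeric(y), X)$beta
  expect_gt(beta[["FOXA1"]], 0)
  expect_equal(names(which.max(abs(beta))), "FOXA1")
})

test_that("psi generator plants recoverable group shifts and missingness", {
  cfg <- sim_config(seed = 7, n_samples = 400, n_events = 500,
                    frac_regulated = 0.2, delta_mu_effect = 0.2,
                    psi_concentration = 100, missing_rate = 0)
  foxa1 <- generate_expression(cfg)["FOXA1", ]
  pd <- generate_psi(cfg, foxa1)
  expect_true(all(pd$psi >= 0 & pd$psi <= 1))
  high <- foxa1 >= pctl(foxa1, 75)
  expect_identical(pd$high_group, high)
  planted <- pd$truth$planted & pd$truth$mu0 > 0.25 & pd$truth$mu0 < 0.75
  dm <- rowMeans(pd$psi[planted, high]) - rowMeans(pd$psi[planted, !high])
  expect_equal(mean(abs(dm)), 0.2, tolerance = 0.03)

  cfg0 <- sim_config(seed = 7, n_events = 200, frac_regulated = 0)
  pd0 <- generate_psi(cfg0, generate_expression(cfg0)["FOXA1", ])
  expect_true(all(pd0$truth$label == "unregulated"))

  cfgm <- sim_config(seed = 8, n_events = 300, missing_rate = 0.3)
  pdm <- generate_psi(cfgm, generate_expression(cfgm)["FOXA1", ])
  expect_equal(mean(is.na(pdm$psi)), 0.3, tolerance = 0.01)
})

test_that("survival generator produces positive, hazard-linked times", {
  cfg <- sim_config(seed = 2, n_samples = 300, n_events = 10,
                    hazard_coefficients = c(EV0001 = log(2)))
  pd <- generate_psi(cfg, rnorm(300))
  cl <- generate_survival(pd$psi, cfg)
  expect_true(all(cl$time > 0))
  expect_true(all(cl$status %in% 0:1))
  expect_lt(abs(mean(cl$status == 0) - cfg$censoring_rate), 0.1)
  expect_error(generate_survival(pd$psi,
    sim_config(seed = 2, n_samples = 300,
               hazard_coefficients = c(NOPE = 1))), "unknown events")

  # null coefficients: strata built on any event are exchangeable
  cfg0 <- sim_config(seed = 3, n_samples = 300, n_events = 10)
  pd0 <- generate_psi(cfg0, rnorm(300))
  cl0 <- generate_survival(pd0$psi, cfg0)
  lab <- stratify_patients(pd0$psi["EV0001", ])
  res <- cox_univariate(cl0$time, cl0$status, lab)
  expect_gt(res$logrank_p, 0.01)
})

test_that("sequence generator plants the tetramer in R1 with matched peaks", {
  cfg <- sim_config(seed = 4)
  sd <- generate_sequences_and_peaks(cfg, tetramer = "GCAT",
                                     n_regulated = 50, n_control = 50,
                                     plant_frac_regulated = 1,
                                     plant_frac_control = 0)
  expect_error(generate_sequences_and_peaks(cfg, tetramer = "GCATA"),
               "length 4")
  lay <- sd$layout
  regions <- extract_regions(sd$regulated, lay)
  expect_true(all(grepl("GCAT", regions$r1)))
  # peaks sit over the planted occurrences (R1 lies in the acceptor panel)
  expect_true(all(sd$peaks$start >= lay$r1[1] - 15 &
                    sd$peaks$end <= lay$r1[2] + 15))
  # reproducibility of the whole bundle
  sd2 <- generate_sequences_and_peaks(cfg, tetramer = "GCAT",
                                      n_regulated = 50, n_control = 50,
                                      plant_frac_regulated = 1,
                                      plant_frac_control = 0)
  expect_identical(sd, sd2)
})

test_that("dataset writer round-trips matrices, FASTA and clinical tables", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 1, n_samples = 20, n_events = 30, n_genes = 5,
                    srg_names = sprintf("G%d", 1:5))
  expr <- generate_expression(cfg)
  pd <- generate_psi(cfg, expr["FOXA1", ])
  cl <- generate_survival(pd$psi, cfg)
  sq <- generate_sequences_and_peaks(cfg, n_regulated = 25, n_control = 25)
  write_sim_dataset(dir, expr = expr, psi_data = pd, clinical = cl,
                    seq_data = sq)
  expect_equal(read_matrix_tsv(file.path(dir, "expression.tsv")), expr)
  psi_back <- read_matrix_tsv(file.path(dir, "psi.tsv"))
  expect_equal(psi_back, pd$psi)
  fa <- read_fasta(file.path(dir, "windows.fa"))
  expect_identical(fa[names(sq$regulated)], sq$regulated)
})
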
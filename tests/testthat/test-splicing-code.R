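toy_layout <- function() region_layout(intron_len = 300L, exon_len = 100L,
                                        map_intron = 200L, map_exon = 20L)

rand_seqs <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
}

test_that("region layout encodes the published windows and the R2 rule", {
  lay <- region_layout(intron_len = 1000L, exon_len = 150L)
  expect_equal(lay$r1, c(1000 - 205, 1000 - 5))
  expect_equal(lay$r3, c(1150 + 10, 1150 + 210))
  expect_equal(length(lay$map_positions), 2 * 1050)
  # long exons: R2 becomes two 200-nt blocks off each splice site
  lay_long <- region_layout(intron_len = 1000L, exon_len = 500L)
  expect_equal(length(lay_long$r2), 2)
  expect_equal(lay_long$r2[[1]], c(1000, 1200))
  expect_equal(lay_long$r2[[2]], c(1300, 1500))
  w <- paste(rep("A", 2500), collapse = "")
  r <- extract_regions(w, lay_long)
  expect_equal(nchar(r$r2), 400)
  # short exon: R2 is the whole exon
  lay_short <- region_layout(intron_len = 1000L, exon_len = 100L)
  expect_equal(lay_short$r2[[1]], c(1000, 1100))
  expect_error(region_layout(intron_len = 100), "215")
})

test_that("window extraction is strand-aware", {
  genome <- list(chr1 = paste(c(rep("A", 300), rep("C", 50), rep("G", 300)),
                              collapse = ""))
  w_plus <- extract_window(genome, "chr1", 300, 350, "+", intron_len = 250)
  expect_equal(nchar(w_plus), 550)
  expect_equal(substr(w_plus, 251, 300), paste(rep("C", 50), collapse = ""))
  w_minus <- extract_window(genome, "chr1", 300, 350, "-", intron_len = 250)
  # reverse complement: upstream intron (R1 side) is now the G-run
  expect_equal(substr(w_minus, 1, 250), paste(rep("C", 250), collapse = ""))
  expect_equal(substr(w_minus, 251, 300), paste(rep("G", 50), collapse = ""))
  expect_error(extract_window(genome, "chr1", 10, 60, "+", intron_len = 50),
               "outside")
  expect_error(extract_window(genome, "chrX", 300, 350), "not in genome")
})

test_that("tetramer space has 512 members and degenerate matching works", {
  tets <- all_tetramers()
  expect_length(tets, 512)
  expect_length(unique(tets), 512)
  expect_equal(sum(grepl("^[ACGT]{4}$", tets)), 256)
  expect_equal(sum(grepl("^[RYSW]{4}$", tets)), 256)
  pres <- splicescape:::tetramer_presence(c(a = "AAGCATAA", b = "AAAAAAAA"),
                                          c("GCAT", "RYRY", "GGGG"))
  expect_equal(unname(pres["GCAT", ]), c(TRUE, FALSE))
  # R=A/G, Y=C/T: GCAT matches RYRY
  expect_equal(unname(pres["RYRY", ]), c(TRUE, FALSE))
  expect_error(splicescape:::check_tetramer("GCNT"), "IUPAC")
})

test_that("planted tetramer is the top R1 enrichment and null data are clean", {
  cfg <- sim_config(seed = 2)
  sd <- generate_sequences_and_peaks(cfg, tetramer = "GCAT",
                                     n_regulated = 150, n_control = 150,
                                     plant_frac_regulated = 0.5,
                                     plant_frac_control = 0.02,
                                     intron_len = 300, exon_len = 100)
  reg <- extract_regions(sd$regulated, sd$layout)
  ctl <- extract_regions(sd$control, sd$layout)
  enr <- tetramer_enrichment(reg$r1, ctl$r1, n_boot = 2000, seed = 1)
  expect_equal(enr$tetramer[1], "GCAT")
  expect_true(enr$enriched[1])
  expect_lte(enr$emp_p[1], 5e-4)

  # plant fraction 0: the truth tetramer is not called
  sd0 <- generate_sequences_and_peaks(cfg, tetramer = "GCAT",
                                      n_regulated = 60, n_control = 60,
                                      plant_frac_regulated = 0,
                                      plant_frac_control = 0,
                                      intron_len = 300, exon_len = 100)
  reg0 <- extract_regions(sd0$regulated, sd0$layout)
  ctl0 <- extract_regions(sd0$control, sd0$layout)
  enr0 <- tetramer_enrichment(reg0$r1, ctl0$r1, n_boot = 500, seed = 1)
  expect_false(enr0$enriched[enr0$tetramer == "GCAT"])
  expect_gt(enr0$fisher_p[enr0$tetramer == "GCAT"], 0.05)
  expect_error(tetramer_enrichment(reg$r1[1:5], ctl$r1), "at least 20")
})

test_that("motif map peaks inside R1 for planted occurrences and is non-negative",
{
  cfg <- sim_config(seed = 3)
  sd <- generate_sequences_and_peaks(cfg, tetramer = "GCAT",
                                     n_regulated = 100, n_control = 100,
                                     plant_frac_regulated = 0.8,
                                     plant_frac_control = 0,
                                     intron_len = 300, exon_len = 100)
  lay <- sd$layout
  q <- motif_map("GCAT", sd$regulated, sd$control, lay)
  expect_true(all(q >= 0))
  pos <- attr(q, "positions")
  in_r1 <- pos >= lay$r1[1] & pos < lay$r1[2]
  expect_true(in_r1[which.max(q)])
  # identical sets: the one-sided p never drops below 1/2, so the map
  # stays at background level everywhere
  q0 <- motif_map("GCAT", sd$regulated, sd$regulated, lay)
  expect_lt(max(q0), -2 * log(0.5) + 1e-9)
})

test_that("occurrence PWM has stochastic columns and a sharp core", {
  win <- c(a = "AAGCATAA", b = "CCGCATGG", c = "TTGCATCC")
  pwm <- pwm_from_occurrences("GCAT", win)
  expect_equal(dim(pwm), c(4, 8))
  expect_equal(colSums(pwm), rep(1, 8), tolerance = 1e-9)
  # core columns are dominated by the planted letters
  expect_gt(pwm["G", 3], 0.6); expect_gt(pwm["C", 4], 0.6)
  expect_gt(pwm["A", 5], 0.6); expect_gt(pwm["T", 6], 0.6)
  # uniform random flanks converge to 0.25
  set.seed(4)
  wins <- vapply(1:500, function(i)
    paste0(paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = ""),
           "GCAT",
           paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = "")),
    character(1))
  pwm2 <- pwm_from_occurrences("GCAT", wins)
  expect_equal(unname(pwm2[, 1]), rep(0.25, 4), tolerance = 0.08)
  expect_error(pwm_from_occurrences("GCAT", c(x = "AAAAAAA")),
               "no occurrences")
})

test_that("PWM similarity is maximal for self-comparison", {
  set.seed(5)
  m <- matrix(runif(4 * 8), 4)
  m <- sweep(m, 2, colSums(m), "/")
  ref <- cbind(m, matrix(0.25, 4, 3))   # 11 columns, informative core first
  expect_equal(pwm_similarity(m, ref), 1, tolerance = 1e-9)
  # column-shuffled version scores lower
  shuf <- ref[, c(3, 1, 2, 5, 4, 7, 6, 8, 9, 10, 11)]
  expect_lt(pwm_similarity(m, shuf), 1 - 1e-6)
  expect_error(pwm_similarity(m, m[, 1:6]), "at least 7")
  # omega averages over reference PWMs
  expect_equal(omega(m, list(ref, ref)), 1, tolerance = 1e-9)
  expect_error(omega(m, list()), "no reference")
})

test_that("Bhattacharyya coefficient has the right bounds and special cases", {
  expect_equal(bhattacharyya(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyya(rep(1, 4), c(1, 0, 0, 0)), 0.5,
               tolerance = 1e-12)
  expect_equal(bhattacharyya(c(0, 0), c(1, 1)), 0)
  expect_error(bhattacharyya(1:3, 1:4), "lengths")
  # product form is the plain inner product of the normalized maps
  expect_equal(bhattacharyya(c(1, 1), c(1, 1), form = "product"), 0.5)
  set.seed(6)
  for (i in 1:50) {
    q <- runif(30); t <- runif(30)
    bc <- bhattacharyya(q, t)
    expect_gte(bc, 0); expect_lte(bc, 1 + 1e-12)
    expect_equal(bc, bhattacharyya(t, q), tolerance = 1e-12)
  }
})

test_that("crosslink map scores follow CES = -2 ln p and localize peaks", {
  lay <- toy_layout()
  # p = exp(-1) at every position gives CES = 2 exactly
  expect_equal(splicescape:::runmean(-2 * log(rep(exp(-1), 5)), 1),
               rep(2, 5))
  ids_r <- sprintf("R%02d", 1:40)
  ids_c <- sprintf("C%02d", 1:40)
  peaks <- data.frame(seq_id = ids_r[1:30], factor = "F",
                      start = 120L, end = 160L)   # inside acceptor panel
  tmap <- crosslink_map(peaks, ids_r, ids_c, lay)
  expect_true(all(tmap >= 0))
  pos <- attr(tmap, "positions")
  expect_true(pos[which.max(tmap)] >= 120 && pos[which.max(tmap)] < 160)
  expect_warning(crosslink_map(peaks[0, ], ids_r, ids_c, lay), "no peaks")
})

test_that("matching scores rank the matched synthetic factor first", {
  cfg <- sim_config(seed = 7)
  sd <- generate_sequences_and_peaks(cfg, tetramer = "GCAT",
                                     n_regulated = 120, n_control = 120,
                                     plant_frac_regulated = 0.6,
                                     plant_frac_control = 0.02,
                                     intron_len = 300, exon_len = 100)
  # decoy factor: random peaks in the donor panel, unrelated PWM
  set.seed(8)
  decoy_peaks <- data.frame(seq_id = sample(names(sd$regulated), 30),
                            factor = "RBP_DECOY",
                            start = 500L, end = 540L)
  peaks <- rbind(sd$peaks[, c("seq_id", "factor", "start", "end")],
                 decoy_peaks)
  dm <- matrix(runif(44), 4); dm <- sweep(dm, 2, colSums(dm), "/")
  refs <- list(RBP_TRUE = list(pwm_from_occurrences("GCAT", sd$regulated)),
               RBP_DECOY = list(dm))
  res <- splicing_code_analysis(sd$regulated, sd$control, sd$layout, refs,
                                peaks, n_boot = 2000, seed = 1)
  m <- res$matching[res$matching$tetramer == "GCAT", ]
  expect_equal(m$factor[which.max(m$matching_score)], "RBP_TRUE")
  expect_true(m$associated[m$factor == "RBP_TRUE"])
  expect_equal(m$matching_score, m$omega * m$bc)
})

test_that("association calls use the per-tetramer 75th percentile", {
  rec <- data.frame(tetramer = rep(c("AAAA", "CCCC"), each = 4),
                    factor = rep(paste0("F", 1:4), 2),
                    omega = c(0.1, 0.2, 0.3, 0.4, 0.4, 0.3, 0.2, 0.1),
                    bc = 1)
  out <- call_associations(rec)
  expect_equal(out$associated,
               c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  outg <- call_associations(rec, scope = "global")
  expect_equal(sum(outg$associated), 2)
  expect_warning(call_associations(rec[1, ]), "trivial")
})
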
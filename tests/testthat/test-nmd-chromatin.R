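test_that("coordinate annotation uses any-overlap with half-open bounds", {
  ev <- data.frame(event_id = c("a", "b", "c"), chrom = "chr1",
                   start = c(100L, 100L, 500L), end = c(200L, 200L, 600L))
  li <- data.frame(chrom = "chr1", start = c(150L, 200L),
                   end = c(160L, 300L),
                   label = c("PTC-introducing", "PTC-preventing"))
  ann <- annotate_by_coordinates(ev[1, ], li)
  expect_equal(ann$nmd_label, "PTC-introducing")
  # book-ended intervals do not overlap under half-open coordinates
  ann_b <- annotate_by_coordinates(ev[2, ], li[2, , drop = FALSE])
  expect_equal(ann_b$nmd_label, "none")
  # both classes hit: ambiguous, labelled none
  li2 <- data.frame(chrom = "chr1", start = c(110L, 150L),
                    end = c(130L, 160L),
                    label = c("PTC-preventing", "PTC-introducing"))
  ann2 <- annotate_by_coordinates(ev[1, ], li2)
  expect_equal(ann2$nmd_label, "none")
  expect_true(ann2$ambiguous)
  expect_error(annotate_by_coordinates(
    ev, transform(li, chrom = "1")), "naming mismatch")
})

test_that("random coordinate annotation equals the quadratic oracle", {
  set.seed(1)
  ev <- data.frame(event_id = sprintf("e%03d", 1:120),
                   chrom = sample(c("chr1", "chr2"), 120, TRUE),
                   start = sample.int(5000, 120))
  ev$end <- ev$start + sample(20:200, 120, TRUE)
  li <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                   start = sample.int(5000, 60))
  li$end <- li$start + sample(20:200, 60, TRUE)
  li$label <- sample(c("PTC-introducing", "PTC-preventing"), 60, TRUE)
  ann <- annotate_by_coordinates(ev, li)
  pairs <- oracle_overlap_pairs(ev, li)
  for (i in seq_len(nrow(ev))) {
    labs <- unique(li$label[pairs$b_idx[pairs$a_idx == i]])
    want <- if (length(labs) == 1) labs else "none"
    expect_equal(ann$nmd_label[i], want)
  }
})

test_that("probability classification matches the percentile rule", {
  set.seed(2)
  n <- 400
  pw <- runif(n); po <- runif(n)
  ann <- classify_by_probability(sprintf("e%03d", 1:n), pw, po)
  delta <- pw - po
  expect_equal(ann$nmd_label,
               ifelse(delta < quantile(delta, 0.15, type = 7),
                      "PTC-preventing",
                      ifelse(delta > quantile(delta, 0.85, type = 7),
                             "PTC-introducing", "none")))
  expect_equal(mean(ann$nmd_label == "PTC-introducing"), 0.15,
               tolerance = 0.02)
  expect_equal(ann$nmd_label[which.max(delta)], "PTC-introducing")
  expect_warning(classify_by_probability(c("a", "b"), c(0.5, 0.5),
                                         c(0.2, 0.2)), "constant")
  expect_error(classify_by_probability("a", 1.5, 0.2), "in \\[0, 1\\]")
})

test_that("2x2 enrichment agrees with exact enumeration and handles margins", {
  ann <- data.frame(event_id = sprintf("e%02d", 1:12),
                    nmd_label = rep(c("PTC-introducing", "none"), 6))
  res <- enrichment_2x2(sprintf("e%02d", 1:6), sprintf("e%02d", 7:12),
                        ann, "PTC-introducing")
  expect_equal(res$p, fisher.test(res$table)$p.value)
  expect_equal(res$p, oracle_fisher_two_tailed(res$table), tolerance = 1e-9)
  expect_equal(res$odds_ratio, 1)

  tab <- matrix(c(5, 1, 1, 5), 2)
  expect_equal(fisher.test(tab)$p.value, oracle_fisher_two_tailed(tab),
               tolerance = 1e-9)

  ann0 <- transform(ann, nmd_label = "none")
  res0 <- enrichment_2x2(sprintf("e%02d", 1:6), sprintf("e%02d", 7:12),
                         ann0, "PTC-introducing")
  expect_true(is.na(res0$odds_ratio))
  expect_equal(res0$p, 1)
  expect_error(enrichment_2x2(c("e01"), c("e01"), ann, "x"), "disjoint")
})

test_that("SACS marking enforces the 90% reciprocal-overlap rule", {
  ev <- data.frame(event_id = c("a", "b"), chrom = "chr1",
                   start = c(0L, 0L), end = c(100L, 100L))
  sx <- data.frame(chrom = "chr1", start = c(0L, 0L), end = c(100L, 89L),
                   sacs_class = c("S1", "S2"))
  ann <- sacs_overlap(ev[1, ], sx[1, , drop = FALSE])
  expect_equal(ann$sacs_class, "S1")
  expect_equal(ann$overlap_frac, 1)
  # 89/100 of the longer interval falls short of the reciprocal threshold
  ann2 <- sacs_overlap(ev[2, ], sx[2, , drop = FALSE])
  expect_equal(ann2$sacs_class, "none")

  set.seed(3)
  ev_r <- data.frame(event_id = sprintf("e%03d", 1:100), chrom = "chr1",
                     start = sample.int(3000, 100))
  ev_r$end <- ev_r$start + sample(50:150, 100, TRUE)
  sx_r <- data.frame(chrom = "chr1", start = sample.int(3000, 50))
  sx_r$end <- sx_r$start + sample(50:150, 50, TRUE)
  sx_r$sacs_class <- "S"
  ann_r <- sacs_overlap(ev_r, sx_r)
  pairs <- oracle_overlap_pairs(ev_r, sx_r)
  marked_oracle <- vapply(seq_len(nrow(ev_r)), function(i) {
    hit <- pairs[pairs$a_idx == i, , drop = FALSE]
    if (nrow(hit) == 0) return(FALSE)
    any(hit$overlap / (ev_r$end[i] - ev_r$start[i]) >= 0.9 &
          hit$overlap / (sx_r$end[hit$b_idx] - sx_r$start[hit$b_idx]) >= 0.9)
  }, logical(1))
  expect_equal(ann_r$sacs_class == "S", marked_oracle)
})

test_that("inclusion-change shift detects a planted negative shift", {
  set.seed(4)
  n <- 100
  st <- data.frame(event_id = sprintf("e%03d", 1:(2 * n)),
                   delta_mu = c(rnorm(n, -0.1, 0.05), rnorm(n, 0, 0.05)),
                   call = rep(c("regulated", "unregulated"), each = n))
  ann <- data.frame(event_id = st$event_id,
                    nmd_label = rep(c("PTC-introducing", "none"), each = n))
  res <- inclusion_change_shift(st, ann, "PTC-introducing")
  expect_lt(res$p, 0.05)
  expect_lt(res$median_shift, 0)
  expect_message(
    expect_null(inclusion_change_shift(st[101:200, ], ann,
                                       "PTC-introducing")),
    "too few")
})
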
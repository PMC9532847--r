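#' Region layout around a cassette exon
#'
#' Fixes the coordinate system of the sequence windows the splicing-code
#' analysis operates on. A window is (upstream intron | exon | downstream
#' intron). The three tetramer-enrichment regions are R1 = [-205, -5]
#' of intronic sequence upstream of the 3' splice site, R2 = the exonic
#' sequence (truncated to 200 nt from each splice site when the exon
#' exceeds 400 nt), and R3 = [+10, +210] of intronic sequence downstream
#' of the 5' splice site. The splicing-map meta-coordinates cover the two
#' cassette-exon junctions, extending `map_intron` nucleotides into each
#' intron and `map_exon` into the exon (acceptor panel then donor panel).
#'
#' @param intron_len length of each flanking intron window (>= 215).
#' @param exon_len exon length.
#' @param map_intron,map_exon map extents per junction (defaults 1,000
#'   and 50).
#' @return a `region_layout` list with window geometry, R1/R2/R3
#'   half-open window-coordinate intervals, and `map_positions` (the
#'   window coordinate of every meta-position).
#' @export
region_layout <- function(intron_len = 1000L, exon_len = 150L,
                          map_intron = 1000L, map_exon = 50L) {
  intron_len <- as.integer(intron_len); exon_len <- as.integer(exon_len)
  if (intron_len < 215) stop("intron windows must be at least 215 nt")
  ex_start <- intron_len
  ex_end <- intron_len + exon_len
  total <- 2L * intron_len + exon_len
  r2 <- if (exon_len > 400) {
    list(c(ex_start, ex_start + 200L), c(ex_end - 200L, ex_end))
  } else list(c(ex_start, ex_end))
  mi <- min(map_intron, intron_len)
  me <- min(map_exon, exon_len)
  acceptor <- seq.int(ex_start - mi, ex_start + me - 1L)
  donor <- seq.int(ex_end - me, ex_end + mi - 1L)
  structure(list(intron_len = intron_len, exon_len = exon_len,
                 total = total, exon_start = ex_start, exon_end = ex_end,
                 r1 = c(ex_start - 205L, ex_start - 5L),
                 r2 = r2,
                 r3 = c(ex_end + 10L, ex_end + 210L),
                 map_positions = c(acceptor, donor),
                 map_break = length(acceptor)),
            class = "region_layout")
}

#' Extract a strand-aware cassette-exon window from genome sequence
#'
#' Returns the (upstream intron | exon | downstream intron) window in
#' transcript orientation: minus-strand exons are reverse-complemented so
#' that R1 is always the intron upstream of the 3' splice site.
#'
#' @param genome a named list/`DNAStringSet` of chromosome sequences.
#' @param chrom,start,end exon coordinates (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param intron_len flanking window length.
#' @return character scalar window sequence.
#' @export
extract_window <- function(genome, chrom, start, end, strand = "+",
                           intron_len = 1000L) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("chromosome not in genome: ", chrom)
  seq <- as.character(seq)
  lo <- start - intron_len
  hi <- end + intron_len
  if (lo < 0 || hi > nchar(seq))
    stop("exon window extends outside the sequence bounds")
  w <- substr(seq, lo + 1L, hi)
  if (strand == "-")
    w <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
  w
}

#' Split windows into the three enrichment regions
#'
#' @param windows character vector of window sequences (equal lengths
#'   consistent with `layout`).
#' @param layout a [region_layout()].
#' @return list with character vectors `r1`, `r2`, `r3` (R2 pieces are
#'   concatenated when the exon is truncated).
#' @export
extract_regions <- function(windows, layout) {
  stopifnot(inherits(layout, "region_layout"))
  if (any(nchar(windows) != layout$total))
    stop("window lengths do not match the layout")
  cut <- function(iv) substr(windows, iv[1] + 1L, iv[2])
  r2 <- do.call(paste0, lapply(layout$r2, cut))
  list(r1 = cut(layout$r1), r2 = r2, r3 = cut(layout$r3))
}

#' The 512-tetramer motif space
#'
#' 256 concrete tetramers over {A, C, G, T} plus 256 fully degenerate
#' tetramers over the two-fold IUPAC codes {R, Y, S, W}.
#'
#' @return character vector of 512 tetramers.
#' @export
all_tetramers <- function() {
  conc <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), 4),
                                      stringsAsFactors = FALSE))
  degen <- do.call(paste0, expand.grid(rep(list(c("R", "Y", "S", "W")), 4),
                                       stringsAsFactors = FALSE))
  c(sort(conc), sort(degen))
}

check_tetramer <- function(tetramer) {
  if (any(nchar(tetramer) != 4)) stop("tetramers must have length 4")
  bad <- grepl("[^ACGTRYSW]", tetramer)
  if (any(bad))
    stop("tetramer symbols outside IUPAC {A,C,G,T,R,Y,S,W}: ",
         paste(tetramer[bad], collapse = ", "))
  invisible(tetramer)
}

# Presence/absence matrix: tetramers x sequences. Degenerate symbols are
# matched through Biostrings' IUPAC machinery.
tetramer_presence <- function(seqs, tetramers) {
  ss <- Biostrings::DNAStringSet(seqs)
  m <- matrix(FALSE, nrow = length(tetramers), ncol = length(seqs),
              dimnames = list(tetramers, names(seqs)))
  for (i in seq_along(tetramers)) {
    m[i, ] <- Biostrings::vcountPattern(tetramers[i], ss, fixed = FALSE) > 0
  }
  m
}

#' Position-specific tetramer enrichment between exon sets
#'
#' For each tetramer, tests whether its presence in a region is more
#' frequent among regulated than control exons (two-tailed Fisher's exact
#' test on the presence/absence table) and attaches a label-permutation
#' empirical p-value: labels are reshuffled `n_boot` times and the
#' empirical p is the proportion of permutations in which the
#' regulated-set presence count reaches the observed one. A tetramer is
#' called enriched iff its Fisher p is <= `fisher_max` — tightened to the
#' 1st percentile of the Fisher-p distribution when more than 5% of
#' tetramers are significant — AND its empirical p is <= `emp_max`.
#'
#' @param regulated_seqs,control_seqs character vectors of region
#'   sequences (>= 20 each).
#' @param tetramers motif set (default [all_tetramers()]).
#' @param n_boot permutation count (study default 10,000).
#' @param seed integer seed.
#' @param fisher_max,emp_max calling thresholds.
#' @return data.frame per tetramer: presence counts, proportions, Fisher
#'   p, empirical p, `higher_in`, `enriched`; sorted by Fisher p.
#' @export
tetramer_enrichment <- function(regulated_seqs, control_seqs,
                                tetramers = all_tetramers(),
                                n_boot = 10000L, seed = 1L,
                                fisher_max = 0.05, emp_max = 5e-4) {
  check_tetramer(tetramers)
  if (length(regulated_seqs) < 20 || length(control_seqs) < 20)
    stop("each exon set needs at least 20 sequences")
  n1 <- length(regulated_seqs); n2 <- length(control_seqs)
  pres <- tetramer_presence(c(regulated_seqs, control_seqs), tetramers)
  k1 <- rowSums(pres[, seq_len(n1), drop = FALSE])
  k2 <- rowSums(pres[, n1 + seq_len(n2), drop = FALSE])
  fisher_p <- vapply(seq_along(tetramers), function(i) {
    stats::fisher.test(matrix(c(k1[i], n1 - k1[i], k2[i], n2 - k2[i]), 2))$p.value
  }, numeric(1))

  set.seed(substream_seed(seed, "tetramer_boot"))
  n <- n1 + n2
  null_ge <- numeric(length(tetramers))
  block <- 1000L
  done <- 0L
  stor <- matrix(0, nrow = n, ncol = block)
  while (done < n_boot) {
    b <- min(block, n_boot - done)
    P <- matrix(0, nrow = n, ncol = b)
    for (j in seq_len(b)) P[sample.int(n, n1), j] <- 1
    null_counts <- pres %*% P
    null_ge <- null_ge + rowSums(null_counts >= k1)
    done <- done + b
  }
  emp_p <- null_ge / n_boot

  thr <- fisher_max
  if (mean(fisher_p <= fisher_max) > 0.05)
    thr <- min(fisher_max, pctl(fisher_p, 1))
  enriched <- fisher_p <= thr & emp_p <= emp_max
  out <- data.frame(tetramer = tetramers, n_regulated = k1, n_control = k2,
                    prop_regulated = k1 / n1, prop_control = k2 / n2,
                    fisher_p = fisher_p, emp_p = emp_p,
                    higher_in = ifelse(k1 / n1 >= k2 / n2, "regulated",
                                       "control"),
                    enriched = enriched, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$fisher_p, out$emp_p), ]
}

# Per-sequence coverage counts at the layout's map positions: how many
# sequences have >= 1 occurrence interval covering each position.
coverage_counts <- function(starts_by_seq, width, layout) {
  pos <- layout$map_positions
  counts <- integer(length(pos))
  lookup <- integer(layout$total)
  lookup[pos + 1L] <- seq_along(pos)
  for (s in starts_by_seq) {
    if (length(s) == 0) next
    covered <- unique(unlist(lapply(s, function(st) st:(st + width - 1L))))
    covered <- covered[covered >= 0 & covered < layout$total]
    mp <- lookup[covered + 1L]
    mp <- unique(mp[mp > 0])
    counts[mp] <- counts[mp] + 1L
  }
  counts
}

# One-sided (greater-in-group-1) Fisher p, vectorized over positions.
fisher_greater_vec <- function(k1, n1, k2, n2) {
  stats::phyper(k1 - 1, k1 + k2, n1 + n2 - k1 - k2, n1, lower.tail = FALSE)
}

# Centered running mean of width k with edge truncation.
runmean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Tetramer occurrence start positions (0-based) per window sequence.
occurrence_starts <- function(windows, tetramer) {
  ss <- Biostrings::DNAStringSet(windows)
  ml <- Biostrings::vmatchPattern(tetramer, ss, fixed = FALSE)
  lapply(ml, function(ir) BiocGenerics::start(ir) - 1L)
}

#' Motif splicing map
#'
#' Per meta-position enrichment profile of a tetramer around the cassette
#' exon junctions: at each position the proportion of regulated vs
#' control exons with an occurrence covering it is compared by a
#' one-sided Fisher test and scored as `q = -2 ln(p)`, then smoothed with
#' a fixed-width running mean.
#'
#' @param tetramer the motif.
#' @param regulated_windows,control_windows full window sequences.
#' @param layout a [region_layout()].
#' @param smooth running-mean width in nt (default 15).
#' @return numeric vector `q` over the layout's meta-positions
#'   (non-negative), with attribute `positions`.
#' @export
motif_map <- function(tetramer, regulated_windows, control_windows, layout,
                      smooth = 15L) {
  check_tetramer(tetramer)
  k1 <- coverage_counts(occurrence_starts(regulated_windows, tetramer), 4L,
                        layout)
  k2 <- coverage_counts(occurrence_starts(control_windows, tetramer), 4L,
                        layout)
  p <- fisher_greater_vec(k1, length(regulated_windows), k2,
                          length(control_windows))
  q <- runmean(-2 * log(p), smooth)
  q[q < 0] <- 0
  attr(q, "positions") <- layout$map_positions
  q
}

#' Crosslink splicing map (CES profile)
#'
#' Per meta-position crosslink enrichment score for one RNA-binding
#' factor: at each position a one-sided Fisher test compares the
#' proportion of regulated vs control exons having at least one
#' crosslink peak covering it; `CES = -2 ln(p)` (natural log).
#'
#' @param peaks data.frame (seq_id, start, end) of peak intervals in
#'   window coordinates (0-based half-open).
#' @param regulated_ids,control_ids sequence identifiers of the two exon
#'   sets (peaks on other ids are ignored).
#' @param layout a [region_layout()].
#' @param smooth running-mean width (default 1 = none).
#' @return numeric CES vector over meta-positions.
#' @export
crosslink_map <- function(peaks, regulated_ids, control_ids, layout,
                          smooth = 1L) {
  count_set <- function(ids) {
    by_seq <- lapply(ids, function(id) {
      pk <- peaks[peaks$seq_id == id, , drop = FALSE]
      if (nrow(pk) == 0) return(integer(0))
      unlist(mapply(function(s, e) s:(e - 1L), pk$start, pk$end,
                    SIMPLIFY = FALSE))
    })
    pos <- layout$map_positions
    lookup <- integer(layout$total)
    lookup[pos + 1L] <- seq_along(pos)
    counts <- integer(length(pos))
    for (covered in by_seq) {
      covered <- unique(covered[covered >= 0 & covered < layout$total])
      mp <- lookup[covered + 1L]
      mp <- unique(mp[mp > 0])
      counts[mp] <- counts[mp] + 1L
    }
    counts
  }
  if (nrow(peaks) == 0) warning("no peaks for this factor; map is all zero")
  k1 <- count_set(regulated_ids)
  k2 <- count_set(control_ids)
  p <- fisher_greater_vec(k1, length(regulated_ids), k2, length(control_ids))
  t <- runmean(-2 * log(p), smooth)
  t[t < 0] <- 0
  attr(t, "positions") <- layout$map_positions
  t
}

#' PWM from tetramer occurrences with 2-nt flanks
#'
#' Collects the 8-mer contexts (tetramer occurrence extended by two
#' nucleotides on each side) across the supplied windows and returns the
#' 4 x 8 column-stochastic frequency matrix (pseudocount 0.5 per base).
#'
#' @param tetramer the motif.
#' @param windows character vector of sequences to scan.
#' @return 4 x 8 probability matrix (rows A, C, G, T).
#' @export
pwm_from_occurrences <- function(tetramer, windows) {
  check_tetramer(tetramer)
  starts <- occurrence_starts(windows, tetramer)
  ctx <- character(0)
  for (i in seq_along(windows)) {
    for (s in starts[[i]]) {
      lo <- s - 2L; hi <- s + 6L          # 0-based [lo, hi)
      if (lo < 0 || hi > nchar(windows[i])) next
      ctx <- c(ctx, substr(windows[i], lo + 1L, hi))
    }
  }
  if (length(ctx) == 0) stop("no occurrences of ", tetramer)
  pwm_from_kmers(ctx)
}

# Column-stochastic PWM from equal-length k-mers (pseudocount 0.5).
pwm_from_kmers <- function(kmers, pseudocount = 0.5) {
  L <- nchar(kmers[1])
  bases <- c("A", "C", "G", "T")
  m <- matrix(pseudocount, nrow = 4, ncol = L, dimnames = list(bases, NULL))
  for (k in kmers) {
    ch <- strsplit(k, "")[[1]]
    for (j in seq_len(L)) if (ch[j] %in% bases) m[ch[j], j] <- m[ch[j], j] + 1
  }
  sweep(m, 2, colSums(m), "/")
}

# Pearson correlation of two 4-probability columns; equal constant
# columns correlate 1, a single constant column contributes 0.
safe_col_cor <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(a, b))) 1 else 0)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' PWM similarity (omega)
#'
#' Aligns a query PWM (e.g. the 8-column tetramer-derived PWM) against
#' the seven most informative contiguous columns of a reference PWM at
#' offsets J in {-3, -2, -1, 0} (query start relative to the core start);
#' the per-alignment similarity is the mean column-wise Pearson
#' correlation of the probability vectors over overlapping columns, and
#' omega is the maximum over the offsets.
#'
#' @param pwm_a query probability matrix (4 x La).
#' @param pwm_b reference probability matrix (4 x Lb, Lb >= 7).
#' @param offsets integer offsets to try.
#' @return omega in [-1, 1].
#' @export
pwm_similarity <- function(pwm_a, pwm_b, offsets = c(-3L, -2L, -1L, 0L)) {
  stopifnot(nrow(pwm_a) == 4, nrow(pwm_b) == 4)
  if (ncol(pwm_b) < 7) stop("reference PWM needs at least 7 columns")
  ic <- apply(pwm_b, 2, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  wsums <- vapply(seq_len(ncol(pwm_b) - 6L),
                  function(s) sum(ic[s:(s + 6L)]), numeric(1))
  core <- pwm_b[, (which.max(wsums)):(which.max(wsums) + 6L), drop = FALSE]
  La <- ncol(pwm_a)
  best <- -Inf
  for (J in offsets) {
    sims <- c()
    for (i in seq_len(7)) {
      ai <- i - J
      if (ai >= 1 && ai <= La)
        sims <- c(sims, safe_col_cor(pwm_a[, ai], core[, i]))
    }
    if (length(sims) > 0) best <- max(best, mean(sims))
  }
  if (!is.finite(best)) stop("no overlapping columns at any offset")
  best
}

#' Mean PWM similarity over a factor's reference PWMs (Omega)
#'
#' @param pwm_query the tetramer-derived PWM.
#' @param reference_pwms list of reference probability matrices for one
#'   factor.
#' @param offsets passed to [pwm_similarity()].
#' @return Omega, the arithmetic mean of the per-PWM omegas.
#' @export
omega <- function(pwm_query, reference_pwms, offsets = c(-3L, -2L, -1L, 0L)) {
  if (length(reference_pwms) == 0) stop("factor has no reference PWMs")
  mean(vapply(reference_pwms, function(p)
    pwm_similarity(pwm_query, p, offsets), numeric(1)))
}

#' Bhattacharyya coefficient between two splicing maps
#'
#' Both maps are normalized to unit sum; the coefficient is
#' `sum(sqrt(q_i * t_i))` (default) or the plain inner product
#' `sum(q_i * t_i)` behind the `form` switch. A map with zero total mass
#' yields BC = 0.
#'
#' @param q,t non-negative score vectors of equal length.
#' @param form `"sqrt"` (standard Bhattacharyya) or `"product"`.
#' @return BC in [0, 1] (sqrt form).
#' @export
bhattacharyya <- function(q, t, form = c("sqrt", "product")) {
  form <- match.arg(form)
  if (length(q) != length(t)) stop("maps have different lengths")
  if (any(q < 0) || any(t < 0)) stop("map scores must be non-negative")
  sq <- sum(q); st <- sum(t)
  if (sq == 0 || st == 0) return(0)
  qh <- q / sq; th <- t / st
  if (form == "sqrt") sum(sqrt(qh * th)) else sum(qh * th)
}

#' Matching Score and association calls
#'
#' `MS = Omega * BC` per (tetramer, factor) pair; within each tetramer
#' (or globally with `scope = "global"`), factors with MS at or above the
#' 75th percentile of the MS distribution are flagged associated.
#'
#' @param records data.frame with columns `tetramer`, `factor`, `omega`,
#'   `bc`.
#' @param scope `"per_tetramer"` (default) or `"global"`.
#' @return `records` with `matching_score` and logical `associated`.
#' @export
call_associations <- function(records, scope = c("per_tetramer", "global")) {
  scope <- match.arg(scope)
  records$matching_score <- records$omega * records$bc
  if (scope == "global") {
    thr <- pctl(records$matching_score, 75)
    records$associated <- records$matching_score >= thr
  } else {
    records$associated <- FALSE
    for (tet in unique(records$tetramer)) {
      i <- records$tetramer == tet
      if (sum(i) == 1) {
        warning("single candidate factor for ", tet,
                "; association flag is trivial")
        records$associated[i] <- TRUE
      } else {
        thr <- pctl(records$matching_score[i], 75)
        records$associated[i] <- records$matching_score[i] >= thr
      }
    }
  }
  records
}

#' End-to-end splicing-code analysis on sequence windows
#'
#' Runs tetramer enrichment in a chosen region, then for each enriched
#' tetramer builds the occurrence-derived PWM and the motif splicing
#' map, and scores every candidate factor by Omega (PWM similarity) times
#' the Bhattacharyya coefficient between the motif map and the factor's
#' crosslink map.
#'
#' @param regulated_windows,control_windows full window sequences.
#' @param layout a [region_layout()].
#' @param reference_pwms named list (factor -> list of PWMs).
#' @param peaks peak table (seq_id, factor, start, end).
#' @param region which enrichment region to scan (`"r1"`, `"r2"`,
#'   `"r3"`).
#' @param tetramers motif set.
#' @param n_boot,seed enrichment permutation settings.
#' @param bc_form passed to [bhattacharyya()].
#' @return list with `enrichment` (per-tetramer table) and `matching`
#'   (per tetramer x factor Matching-Score records, NULL when nothing is
#'   enriched).
#' @export
splicing_code_analysis <- function(regulated_windows, control_windows,
                                   layout, reference_pwms, peaks,
                                   region = "r1",
                                   tetramers = all_tetramers(),
                                   n_boot = 10000L, seed = 1L,
                                   bc_form = "sqrt") {
  regions_reg <- extract_regions(regulated_windows, layout)
  regions_ctl <- extract_regions(control_windows, layout)
  enr <- tetramer_enrichment(regions_reg[[region]], regions_ctl[[region]],
                             tetramers = tetramers, n_boot = n_boot,
                             seed = seed)
  hits <- enr$tetramer[enr$enriched & enr$higher_in == "regulated"]
  if (length(hits) == 0)
    return(list(enrichment = enr, matching = NULL))
  factors <- names(reference_pwms)
  recs <- list()
  for (tet in hits) {
    qpwm <- pwm_from_occurrences(tet, regulated_windows)
    qmap <- motif_map(tet, regulated_windows, control_windows, layout)
    for (fac in factors) {
      pk <- peaks[peaks$factor == fac, , drop = FALSE]
      tmap <- suppressWarnings(
        crosslink_map(pk, names(regulated_windows), names(control_windows),
                      layout))
      recs[[length(recs) + 1L]] <- data.frame(
        tetramer = tet, factor = fac,
        omega = omega(qpwm, reference_pwms[[fac]]),
        bc = bhattacharyya(qmap, tmap, form = bc_form),
        stringsAsFactors = FALSE)
    }
  }
  matching <- call_associations(do.call(rbind, recs))
  list(enrichment = enr, matching = matching)
}
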
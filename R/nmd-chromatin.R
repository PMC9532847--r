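
# Convert a BED-style data.frame (chrom, start, end; 0-based half-open)
# to GRanges (1-based closed). Strand column optional.
df_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end),
                         strand = strand)
}

# Error on chr1-vs-1 style mismatches between two interval sets.
check_chrom_style <- function(a, b) {
  has_chr <- function(x) grepl("^chr", x)
  ca <- unique(as.character(a$chrom)); cb <- unique(as.character(b$chrom))
  if (length(ca) && length(cb) && any(has_chr(ca)) != any(has_chr(cb)))
    stop("chromosome naming mismatch between interval sets (chr1 vs 1)")
  invisible(NULL)
}

#' Annotate events against a labelled NMD-determinant exon list
#'
#' Any-overlap (>= 1 bp) intersection of event coordinates with a
#' coordinate list of PTC-introducing / PTC-preventing exons. Events
#' overlapping entries of both label classes are ambiguous and labelled
#' `none`.
#'
#' @param events data.frame with `event_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param nmd_list data.frame with `chrom`, `start`, `end`, `label` in
#'   {"PTC-introducing", "PTC-preventing"}.
#' @return data.frame (event_id, nmd_label, ambiguous) with
#'   `nmd_label` in {PTC-introducing, PTC-preventing, none}.
#' @export
annotate_by_coordinates <- function(events, nmd_list) {
  stopifnot(all(nmd_list$label %in% c("PTC-introducing", "PTC-preventing")))
  check_chrom_style(events, nmd_list)
  ev <- df_to_granges(events)
  li <- df_to_granges(nmd_list)
  GenomicRanges::strand(ev) <- "*"
  GenomicRanges::strand(li) <- "*"
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ev, li))
  lab <- rep("none", nrow(events))
  amb <- rep(FALSE, nrow(events))
  if (length(hits) > 0) {
    got <- split(nmd_list$label[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    for (q in names(got)) {
      u <- unique(got[[q]])
      i <- as.integer(q)
      if (length(u) == 1) lab[i] <- u else amb[i] <- TRUE
    }
  }
  data.frame(event_id = events$event_id, nmd_label = lab, ambiguous = amb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify NMD-determinant exons from inclusion/exclusion probabilities
#'
#' The difference `delta = prob_with - prob_without` (NMD probability of
#' the transcript including vs excluding the exon) is ranked; events
#' below its 15th percentile are putative PTC-preventing, above the 85th
#' putative PTC-introducing.
#'
#' @param event_id event identifiers.
#' @param prob_with,prob_without per-event NMD probabilities in [0, 1].
#' @param pcts lower/upper percentile pair.
#' @return data.frame (event_id, delta, nmd_label).
#' @export
classify_by_probability <- function(event_id, prob_with, prob_without,
                                    pcts = c(15, 85)) {
  stopifnot(length(prob_with) == length(prob_without),
            length(event_id) == length(prob_with))
  if (any(prob_with < 0 | prob_with > 1 | prob_without < 0 | prob_without > 1,
          na.rm = TRUE))
    stop("probabilities must be in [0, 1]")
  delta <- prob_with - prob_without
  if (length(unique(delta)) == 1) {
    warning("constant probability difference; no events classified")
    lab <- rep("none", length(delta))
  } else {
    lo <- pctl(delta, pcts[1]); hi <- pctl(delta, pcts[2])
    lab <- ifelse(delta < lo, "PTC-preventing",
                  ifelse(delta > hi, "PTC-introducing", "none"))
  }
  data.frame(event_id = event_id, delta = delta, nmd_label = lab,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-by-two enrichment of an annotation label between event sets
#'
#' Builds the (in set A vs set B) x (labelled vs not) contingency table
#' and runs a two-tailed Fisher's exact test. The odds ratio is the
#' sample cross-product ratio; with an empty margin it is not estimable
#' and p = 1.
#'
#' @param set_a,set_b disjoint character vectors of event ids.
#' @param annotation data.frame (event_id, label column).
#' @param label the annotation value tested for enrichment.
#' @param label_col name of the label column (default `nmd_label`).
#' @return list with `table`, `odds_ratio` (NA when not estimable), `p`.
#' @export
enrichment_2x2 <- function(set_a, set_b, annotation, label,
                           label_col = "nmd_label") {
  if (length(intersect(set_a, set_b)) > 0) stop("event sets must be disjoint")
  lab <- annotation[[label_col]][match(c(set_a, set_b), annotation$event_id)]
  grp <- rep(c("A", "B"), c(length(set_a), length(set_b)))
  tab <- table(factor(grp, c("A", "B")),
               factor(lab == label, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, odds_ratio = NA_real_, p = 1))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p = p)
}

#' Mark events overlapping chromatin-signature exons (reciprocal overlap)
#'
#' An event is marked with a splicing-associated chromatin signature
#' (SACS) class iff the shared stretch covers at least `min_reciprocal`
#' of BOTH intervals' lengths.
#'
#' @param events data.frame (event_id, chrom, start, end).
#' @param sacs_exons data.frame (chrom, start, end, sacs_class).
#' @param min_reciprocal minimum reciprocal overlap fraction (default
#'   0.9).
#' @return data.frame (event_id, sacs_class, overlap_frac) with
#'   `sacs_class = "none"` for unmarked events; `overlap_frac` is the
#'   smaller of the two coverage fractions for the best-matching entry.
#' @export
sacs_overlap <- function(events, sacs_exons, min_reciprocal = 0.9) {
  check_chrom_style(events, sacs_exons)
  ev <- df_to_granges(events); sx <- df_to_granges(sacs_exons)
  GenomicRanges::strand(ev) <- "*"; GenomicRanges::strand(sx) <- "*"
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ev, sx))
  cls <- rep("none", nrow(events))
  frac <- rep(NA_real_, nrow(events))
  if (length(hits) > 0) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(ev[q], sx[s]))
    f <- pmin(ov / GenomicRanges::width(ev[q]), ov / GenomicRanges::width(sx[s]))
    ok <- f >= min_reciprocal
    for (i in which(ok)) {
      qi <- q[i]
      if (is.na(frac[qi]) || f[i] > frac[qi]) {
        frac[qi] <- f[i]
        cls[qi] <- sacs_exons$sacs_class[s[i]]
      }
    }
  }
  data.frame(event_id = events$event_id, sacs_class = cls,
             overlap_frac = frac, row.names = NULL, stringsAsFactors = FALSE)
}

#' Inclusion-change shift of an annotated class
#'
#' Two-tailed Wilcoxon rank-sum test comparing the delta-mu(PSI)
#' distribution of regulated events in one annotation class against
#' unregulated control events.
#'
#' @param stats per-event stats (needs `event_id`, `delta_mu`, `call`).
#' @param annotation data.frame (event_id, nmd_label).
#' @param label annotation class to test (e.g. "PTC-introducing").
#' @return list with `p`, `n_class`, `n_control`, `median_shift`
#'   (class median minus control median), or NULL with a message if the
#'   class has fewer than 3 events.
#' @export
inclusion_change_shift <- function(stats, annotation, label) {
  lab <- annotation$nmd_label[match(stats$event_id, annotation$event_id)]
  x <- stats$delta_mu[stats$call == "regulated" & lab %in% label]
  y <- stats$delta_mu[stats$call == "unregulated"]
  if (length(x) < 3 || length(y) < 3) {
    message("class '", label, "' has too few events; test skipped")
    return(NULL)
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(p = wt$p.value, n_class = length(x), n_control = length(y),
       median_shift = stats::median(x) - stats::median(y))
}
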
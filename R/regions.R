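#' Define promoter windows around transcription start sites
#'
#' The promoter is the window from `up` bp upstream to `down` bp
#' downstream of the TSS (strand-mirrored on the minus strand), clamped
#' at position 0. With the default symmetric 2,000/2,000 window the
#' interval is the same on both strands.
#'
#' @param tss data.frame (gene, chrom, pos, strand), 0-based positions.
#' @param up,down extents in bp.
#' @return data.frame (gene, chrom, start, end, strand), 0-based
#'   half-open.
#' @export
define_promoters <- function(tss, up = 2000L, down = 2000L) {
  stopifnot(all(c("gene", "chrom", "pos", "strand") %in% names(tss)))
  if (any(tss$pos < 0)) stop("TSS positions must be non-negative")
  plus <- tss$strand != "-"
  start <- ifelse(plus, tss$pos - up, tss$pos - down)
  end <- ifelse(plus, tss$pos + down, tss$pos + up)
  data.frame(gene = tss$gene, chrom = tss$chrom,
             start = pmax(0L, as.integer(start)), end = as.integer(end),
             strand = tss$strand, row.names = NULL, stringsAsFactors = FALSE)
}

#' Sort and merge genomic intervals
#'
#' Overlapping or book-ended intervals on the same chromosome are merged;
#' the output is disjoint and positionally sorted.
#'
#' @param df data.frame (chrom, start, end), 0-based half-open.
#' @return merged data.frame (chrom, start, end).
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  gr <- df_to_granges(df)
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = BiocGenerics::start(red) - 1L,
                    end = BiocGenerics::end(red),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Intersect two interval sets
#'
#' Returns the overlapping pairs, either with any (>= 1 bp) overlap or
#' under a reciprocal-fraction threshold applied to both intervals.
#'
#' @param a,b data.frames (chrom, start, end), 0-based half-open.
#' @param mode `"any"` or `"reciprocal"`.
#' @param f reciprocal overlap fraction (required in reciprocal mode).
#' @return data.frame (a_idx, b_idx, overlap) of pairs; `overlap` in bp.
#' @export
intersect_intervals <- function(a, b, mode = c("any", "reciprocal"),
                                f = NULL) {
  mode <- match.arg(mode)
  check_chrom_style(a, b)
  ga <- df_to_granges(a); gb <- df_to_granges(b)
  GenomicRanges::strand(ga) <- "*"; GenomicRanges::strand(gb) <- "*"
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0)
    return(data.frame(a_idx = integer(0), b_idx = integer(0),
                      overlap = integer(0)))
  ov <- GenomicRanges::width(GenomicRanges::pintersect(ga[qi], gb[si]))
  keep <- rep(TRUE, length(qi))
  if (mode == "reciprocal") {
    if (is.null(f)) stop("reciprocal mode requires a fraction f")
    keep <- ov / GenomicRanges::width(ga[qi]) >= f &
      ov / GenomicRanges::width(gb[si]) >= f
  }
  data.frame(a_idx = qi[keep], b_idx = si[keep], overlap = ov[keep],
             row.names = NULL)
}

#' Filter enhancer-gene links by accessibility, promoter overlap and span
#'
#' Keeps links whose enhancer AND the target gene's promoter overlap
#' accessible regions, whose enhancer does not overlap its own gene's
#' promoter, and whose enhancer-promoter span (gap distance; 0 when
#' touching) is below 1 Mbp. Links whose gene has no promoter record are
#' dropped with a message.
#'
#' @param links data.frame (chrom, start, end, gene) of enhancers with
#'   their putative target gene.
#' @param promoters data.frame from [define_promoters()].
#' @param accessible data.frame (chrom, start, end) of accessible
#'   elements.
#' @param max_span span bound in bp (strict <).
#' @return the retained subset of `links` with an added `span` column.
#' @export
link_enhancers <- function(links, promoters, accessible,
                           max_span = 1e6) {
  pm <- match(links$gene, promoters$gene)
  if (anyNA(pm)) {
    message(sum(is.na(pm)), " links dropped: gene without promoter record")
    links <- links[!is.na(pm), , drop = FALSE]
    pm <- pm[!is.na(pm)]
  }
  if (nrow(links) == 0) return(cbind(links, span = numeric(0)))
  prom <- promoters[pm, , drop = FALSE]
  enh_acc <- seq_len(nrow(links)) %in%
    intersect_intervals(links, accessible)$a_idx
  prom_acc <- seq_len(nrow(prom)) %in%
    intersect_intervals(prom, accessible)$a_idx
  same_chrom <- links$chrom == prom$chrom
  ov_own <- same_chrom & links$start < prom$end & prom$start < links$end
  span <- ifelse(!same_chrom, Inf,
                 pmax(0, pmax(links$start, prom$start) -
                        pmin(links$end, prom$end)))
  keep <- enh_acc & prom_acc & !ov_own & span < max_span
  out <- links[keep, , drop = FALSE]
  out$span <- span[keep]
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a gene set against each pathway,
#' restricted to the universe; BH FDR with significance at FDR <= 0.1.
#'
#' @param gene_set character vector (subset of `universe`).
#' @param universe character vector of all testable genes.
#' @param pathways named list of gene vectors.
#' @param fdr_max significance threshold.
#' @return data.frame (pathway, n_hits, n_pathway, p, fdr, significant);
#'   pathways with no universe overlap are skipped.
#' @export
ora <- function(gene_set, universe, pathways, fdr_max = 0.1) {
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  N <- length(unique(universe))
  n <- length(unique(gene_set))
  rows <- lapply(names(pathways), function(pw) {
    path <- intersect(pathways[[pw]], universe)
    K <- length(path)
    if (K == 0) return(NULL)
    k <- length(intersect(gene_set, path))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, n_hits = k, n_pathway = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway overlaps the universe")
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr <= fdr_max
  out[order(out$p), ]
}
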
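#!/usr/bin/env Rscript
# Which cis-acting tetramers mark the regulated exons, and which
# trans-acting factor do they point to? Position-specific tetramer
# enrichment in R1/R2/R3 (Fisher + 10,000-permutation empirical p),
# occurrence-derived PWMs, motif and crosslink splicing maps, and the
# Matching Score (Omega x Bhattacharyya coefficient).

suppressMessages(library(splicescape))
seed <- as.integer(Sys.getenv("SPLICESCAPE_SEED", "1"))
cfg <- sim_config(seed = seed)
sq <- generate_sequences_and_peaks(cfg)   # windows + peaks + truth motif
fa <- read_fasta("results/data/windows.fa")
regulated <- fa[grep("^REG", names(fa))]
control <- fa[grep("^CTL", names(fa))]
peaks_bed <- read_bed("results/data/peaks.bed")
peaks <- data.frame(seq_id = peaks_bed$chrom, factor = peaks_bed$name,
                    start = peaks_bed$start, end = peaks_bed$end)

set.seed(seed)
dm <- matrix(runif(44), 4); dm <- sweep(dm, 2, colSums(dm), "/")
refs <- list(
  RBP_TRUE = list(pwm_from_occurrences(sq$truth_tetramer, regulated)),
  RBP_BG = list(dm))

res <- splicing_code_analysis(regulated, control, sq$layout, refs, peaks,
                              n_boot = 10000, seed = seed)
write.table(res$enrichment, "results/tetramer_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (!is.null(res$matching))
  write.table(res$matching, "results/matching_scores.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)

enr <- res$enrichment
cat(sprintf("%d of %d tetramers enriched in R1; top: %s (planted: %s)\n",
            sum(enr$enriched), nrow(enr), enr$tetramer[1],
            sq$truth_tetramer))
if (!is.null(res$matching)) {
  m <- res$matching[order(-res$matching$matching_score), ]
  cat("matching scores:\n")
  print(m, row.names = FALSE)
}
cat("wrote results/tetramer_enrichment.tsv, results/matching_scores.tsv\n")
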
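#!/usr/bin/env Rscript
# Annotate cassette exons as NMD determinants. Two routes, as in the
# study: coordinate intersection with a labelled exon list, and
# percentile classification of NMD-probability differences. Here the
# probability route runs on emulated probabilities (inputs to the
# classifier, not predictions), and enrichment of PTC-introducing exons
# among regulated events is tested with Fisher's exact test.

suppressMessages(library(splicescape))
seed <- as.integer(Sys.getenv("SPLICESCAPE_SEED", "1"))
ev <- read.delim("results/event_stats.tsv")

set.seed(seed)
ce <- ev[ev$category == "CE", ]
ann <- classify_by_probability(ce$event_id, runif(nrow(ce)), runif(nrow(ce)))
write.table(ann, "results/nmd_annotation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

enr <- enrichment_2x2(ce$event_id[ce$call == "regulated"],
                      ce$event_id[ce$call == "unregulated"],
                      ann, "PTC-introducing")
cat(sprintf("PTC-introducing exons among regulated vs unregulated CEs:\n"))
print(enr$table)
cat(sprintf("odds ratio %.2f, Fisher p = %.3g\n", enr$odds_ratio, enr$p))

shift <- inclusion_change_shift(ce, ann, "PTC-introducing")
if (!is.null(shift))
  cat(sprintf("delta-mu shift of PTC-introducing regulated exons: %.3f (p = %.3g)\n",
              shift$median_shift, shift$p))
cat("wrote results/nmd_annotation.tsv\n")
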
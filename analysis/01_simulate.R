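#!/usr/bin/env Rscript
# Build the synthetic study cohort: a 400-sample tumor expression matrix
# with four TFs driving 148 splicing-related genes (FOXA1 dominant), a
# 2,000-event PSI atlas with 10% planted regulated events, clinical
# follow-up driven by one planted prognostic exon, benign profiles for
# the purity sweep, and sequence windows with a planted tetramer.
# Everything is written as plain text under results/data/.

suppressMessages(library(splicescape))
seed <- as.integer(Sys.getenv("SPLICESCAPE_SEED", "1"))
outdir <- "results/data"

cfg <- sim_config(seed = seed,
                  hazard_coefficients = c(EV0001 = log(3)))
expr <- generate_expression(cfg)
psi_data <- generate_psi(cfg, expr["FOXA1", ])
clinical <- generate_survival(psi_data$psi, cfg)
seq_data <- generate_sequences_and_peaks(cfg)
benign <- generate_benign(cfg)

write_sim_dataset(outdir, expr = expr, psi_data = psi_data,
                  clinical = clinical, seq_data = seq_data)
write_matrix_tsv(benign, file.path(outdir, "benign.tsv"))

cat(sprintf("cohort: %d samples, %d genes (%d TFs), %d events (%d planted)\n",
            ncol(expr), nrow(expr), length(cfg$tf_names),
            nrow(psi_data$psi), sum(psi_data$truth$planted)))
cat(sprintf("missingness: %.1f%%; censored: %.1f%%\n",
            100 * mean(is.na(psi_data$psi)),
            100 * mean(clinical$status == 0)))
cat("wrote", outdir, "\n")
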
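# splicescape

Quantifying how a transcription factor's expression reshapes an
alternative-splicing landscape in bulk tumor transcriptomes.

## The problem

Master transcription factors such as FOXA1 do more than switch target
genes on and off: by driving the expression of splicing-related genes
(SRGs — spliceosome components and auxiliary RNA-binding proteins), they
can remodel which exons the tumor includes in its mature mRNAs.
Detecting that remodelling from bulk RNA-seq is statistically awkward:
SRGs are highly expressed (count models lose power for subtle shifts),
percent-spliced-in values are bounded and noisy, the high-TF group is
much smaller than the rest of the cohort, and stromal contamination can
mimic or mask regulatory signal.

`splicescape` implements the full analysis chain for this design, for
computational biologists who want to run, test or extend it:

* **Covariance modelling** — an OLS fit of cumulative SRG expression on
  preprocessed TF expression (near-zero-variance filter, Yeo–Johnson,
  center/scale), with the model's R² decomposed into per-TF
  relative-importance shares by the LMG averaging-over-orderings method,

  `share_j = (1/k!) Σ_orderings [ R²(before j ∪ {j}) − R²(before j) ]`,

  plus bootstrap confidence intervals.
* **Differential SRG expression** — per-gene two-tailed
  Kolmogorov–Smirnov tests between TF-high (≥ 75th percentile) and
  remaining samples, BH correction, Monte Carlo empirical p-values from
  label shuffles, and a median-TPM fold-change criterion
  (FDR ≤ 0.01 ∧ emp-p ≤ 0.01 ∧ |log₂FC| ≥ 0.2).
* **Differential splicing** — a dual nonparametric caller on Ψ:
  atlas filtering and mean imputation, Δμ(Ψ)/Δσ(Ψ) quantile prefilters,
  Wilcoxon rank-sum and Fligner–Killeen tests with BH correction,
  1,000 label shuffles for empirical p-values, 1,000 balanced
  down-samples for a success rate, and the final call
  (FDR < 0.05 ∧ emp-p < 0.05 ∧ SR > 0.7 for at least one test).
* **Isoform trajectory** — cumulative counts of positive/negative
  splicing changes from mixed (Ψ = 0.5) toward dominant (Ψ = 0, 1)
  isoform populations, against a Monte Carlo random-sign envelope, with
  exact binomial tests in four inclusion bins.
* **NMD / chromatin annotation** — PTC-introducing and PTC-preventing
  cassette-exon labels (coordinate intersection or NMD-probability
  percentiles), 90%-reciprocal-overlap chromatin-signature marking, and
  Fisher/rank-sum enrichment tests.
* **Splicing-code analysis** — enrichment of 512 tetramers in three
  regions around cassette exons (Fisher + 10,000-permutation empirical
  p), occurrence-derived PWMs, motif and crosslink splicing maps scored
  as −2 ln p, and the Matching Score `MS = Ω · BC` (PWM similarity times
  the Bhattacharyya coefficient between maps) linking each tetramer to a
  candidate RNA-binding protein.
* **Survival** — the per-patient S statistic (`n25 ÷ n75` over an exon
  group), 25/75-percentile stratification, univariate Cox models with
  log-rank tests and BH correction, and maximally selected log-rank
  cutpoints.
* **Tumor purity** — in-silico mixtures
  `g = g_tumor · p/100 + g_benign · (1 − p/100)` across ten purity
  levels, tracking the stability of the TF contributions and the
  differential-SRG calls.

A seeded synthetic-data generator (`sim_config()`, `generate_*()`)
emulates the statistical structure of all inputs — log-normal TPMs with a
planted TF→SRG dependence, Beta-distributed Ψ with planted group shifts
and missingness, inclusion-dependent survival, benign profiles, and
sequence windows with planted tetramers and crosslink peaks — so the
whole pipeline runs and is tested without any external download.

## Worked example

```r
library(splicescape)

cfg   <- sim_config(seed = 1, n_samples = 200, n_events = 600)
expr  <- generate_expression(cfg)
atlas <- generate_psi(cfg, expr["FOXA1", ])
high  <- stratify_by_expression(expr, "FOXA1")

events <- call_splicing_events(atlas$psi, atlas$meta, high,
                               n_shuffle = 200, n_downsample = 200,
                               seed = 1)
table(events$call)
#>   regulated unregulated
#>          66         534

truth  <- atlas$truth$planted[match(events$event_id, atlas$truth$event_id)]
called <- events$call == "regulated"
c(sensitivity = sum(called & truth) / sum(truth),
  fdr         = sum(called & !truth) / sum(called))
#> sensitivity         fdr
#>  1.00000000  0.09090909

res <- covariance_analysis(colSums(expr[cfg$srg_names, ]),
                           t(expr[cfg$tf_names, ]), n_boot = 200, seed = 1)
print(res)
#> Relative importance decomposition (R^2 = 0.9956, 200 bootstraps)
#>          beta  share  lower  upper
#> FOXA1  0.9827 0.9629 0.9215 0.9753
#> AR     0.1153 0.0098 0.0049 0.0327
#> HOXB13 0.1104 0.0102 0.0048 0.0259
#> MYC    0.1256 0.0127 0.0059 0.0408
```

The caller recovers all 60 planted events (plus 6 false calls, an
empirical FDR of 0.09), and the LMG decomposition attributes 96% of the
SRG-expression variance to the planted dominant TF, whose confidence
interval clears the other three regulators.

## The analysis workflow

The numbered scripts under `analysis/` rerun the study's computational
arm end-to-end on the synthetic cohort and write their tables under
`results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`01_simulate` builds the cohort; `02`–`09` run covariance, differential
expression, splicing-event calling, trajectory, NMD annotation, the
splicing code, survival and the purity sweep. Each script prints a short
summary of what it found. `SPLICESCAPE_SEED` changes the cohort seed.

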
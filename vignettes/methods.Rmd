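---
title: "Methods: quantifying a TF-driven alternative-splicing landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a TF-driven alternative-splicing landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescape)
```

## Scope and model

`splicescape` implements the computational arm of a study design that asks
how the expression level of a master transcription factor (TF) reshapes a
tumor's alternative-splicing landscape. The package chains seven analyses,
each exposed as ordinary functions and exercised end-to-end on seeded
synthetic cohorts:

1. **Covariance modelling** — how much of the (cumulative) expression of
   splicing-related genes (SRGs) each TF explains, via an OLS fit on
   preprocessed regressors and an LMG decomposition of $R^2$.
2. **Differential SRG expression** — a nonparametric caller
   (Kolmogorov–Smirnov + Monte Carlo empirical p-values + median-TPM fold
   change) built for high-abundance genes where count models lose power.
3. **Differential splicing** — a dual nonparametric caller on
   percent-spliced-in (Ψ) values with quantile prefilters, label-shuffle
   empirical nulls and a down-sampling success rate.
4. **Isoform trajectory** — whether changes push exons from mixed
   (Ψ ≈ 0.5) toward dominant (Ψ ≈ 0 or 1) isoform populations.
5. **NMD/chromatin annotation** — PTC-introducing/PTC-preventing exon
   labels by coordinate intersection or probability percentiles, and
   reciprocal-overlap chromatin-signature marking.
6. **Splicing-code analysis** — position-specific tetramer enrichment
   around regulated exons and a Matching Score linking each enriched
   tetramer to a candidate RNA-binding protein.
7. **Survival and purity** — S-statistic and per-event Cox stratification,
   maximally selected cutpoints, and an in-silico tumor-purity mixing
   simulation.

Throughout the package one quantile definition is used everywhere a
percentile appears (stratification, prefilters, NMD classes, S-statistic
strata, Matching-Score calls): linear interpolation between order
statistics (`type = 7`), exposed as `pctl()`.

## The synthetic cohort

Every stage is testable without external data because the generator in
`sim_config()` / `generate_*()` emulates the statistical structure the
analyses assume. The defaults are the study conditions used by the test
suite and the acceptance script:

| knob | default | meaning |
|---|---|---|
| `n_samples` | 400 | tumor cohort size; the ≥75th-percentile split yields 100 high-TF vs 300 remaining samples |
| `tf_names` | 4 TFs | log-scale regulators; the first (FOXA1) carries weight 0.8 on every SRG, the others 0.1 |
| `n_genes` | 148 | SRG count |
| `expr_noise_sd` | 0.5 | log-scale Gaussian noise on SRG expression |
| `n_events` | 2,000 | Ψ atlas size |
| `frac_regulated` | 0.10 | fraction of events with a planted group effect |
| `delta_mu_effect` | 0.2 | planted shift of mean Ψ in the high-TF group (random sign per event) |
| `psi_concentration` | 60 | Beta precision of Ψ draws |
| `missing_rate` | 0.10 | completely-at-random missing Ψ entries |
| `censoring_rate` | 0.30 | independent censoring fraction |
| `n_benign` | 107 | benign profiles for the purity sweep |

Design choices worth knowing:

* **Beta(mean, concentration) parameterization.** Ψ stays in [0, 1] with
  interpretable effects; dispersion effects are concentration shifts
  (`2^(-delta_sigma_effect)` in the high group).
* **Missingness is completely at random**, matching the mean-imputation
  remedy downstream; informative missingness is out of scope.
* **Truth and caller share the ≥75th-percentile rule**, so planted group
  membership and analysis stratification agree by construction.
* **One master seed**; every generator and resampling loop derives an
  independent sub-stream from it (`substream_seed()`), so stages are
  individually reproducible under a single knob.
* **Hazard-bearing events** (named in `hazard_coefficients`) are planted
  at baseline mean Ψ = 0.5 with Beta concentration 2. A prognostic exon
  can only stratify patients if its inclusion actually varies between
  them; at the atlas-wide concentration of 60 the interquartile spread of
  Ψ is ≈ 0.08 and no realistic hazard coefficient is recoverable. This is
  a property of extreme-group designs, not of the Cox fit.
* Survival times are exponential with log relative hazard
  $\sum_e \beta_e \Psi_{e,\text{patient}}$; the censoring distribution is
  an independent exponential whose rate is tuned to the target censored
  fraction.

What the generator does **not** emulate: read-level noise, transcript
structures, correlated events within genes, informative missingness,
batch effects, or benign profiles with residual TF→SRG coupling. Passing
tests therefore certify the statistical machinery under the stated
generative model — not performance on any real cohort.

## Covariance modelling

Regressors are preprocessed exactly as the analysis prescribes:
near-zero-variance columns dropped (frequency ratio > 19 and unique-value
fraction < 10%), a Yeo–Johnson power transform per column with λ estimated
by maximum likelihood, then centering and scaling (`caret::preProcess`
stands behind `preprocess_regressors()`). The response (cumulative SRG
expression) receives the same chain by default; `covariance_analysis()`
has a flag to disable that.

`lmg_importance()` is authored in-package: the LMG share of regressor $j$
is the average over all $k!$ orderings of the $R^2$ increase when $j$
enters the model, computed by the equivalent subset-sum formulation over
the $2^k$ subsets with weights $|S|!\,(k-|S|-1)!/k!$. Shares always sum to
the full-model $R^2$ (asserted to $10^{-9}$), and an explicit ordering
enumeration is kept as an independent oracle in the test suite. Exact
enumeration is refused above $k = 15$; sampling of orderings is a
non-goal. Bootstrap confidence intervals resample whole observation rows
(default 1,000 times) and report percentile 2.5/97.5 bounds — the CI
estimator is not specified by the procedure, and percentile is the
assumption-light default.

## Differential SRG expression

High-TF membership is `TPM ≥ pctl(x, 75)`. Per gene, a two-tailed
two-sample KS test compares the TPM distributions; BH adjusts across
genes. The empirical p-value is the **literal proportion** of null
p-values strictly below the observed one over (default) 10,000 label
shuffles, with an optional (+1)/(+1) pseudocount variant behind a flag.
Shuffling is without replacement (the label-permutation reading of random
re-selection); all genes share one label draw per iteration. A gene is
called in `tpm_only` mode when FDR ≤ 0.01, emp-p ≤ 0.01 and
|log2 median-TPM fold change| ≥ 0.2 (pseudocount 1 guards zero medians);
in `counts` mode the fold-change conjunct instead defers to externally
supplied parametric tables (DESeq2- or edgeR-style columns
`gene, log2FC, adjusted_p` with |log2FC| ≥ 0.2 and adjusted p ≤ 0.01).
Reimplementing count models is a non-goal.

## Differential splicing

`filter_and_impute()` retains events observed in > 75% of samples, with
mean Ψ strictly inside (0.01, 0.99), in genes with < 500 events, and
mean-imputes the remaining gaps (imputation provably never moves an
event's mean). `quantile_prefilter()` discards negligible changes: an
event is tested only if Δμ(Ψ) falls strictly below the 15th / above the
85th percentile of the Δμ distribution, or Δσ(Ψ) strictly below the
20th / above the 80th percentile of the Δσ distribution — percentiles
computed once over all filtered events (the wording is circular on this
point; computing them once is the simplest consistent reading).

Tested events get a two-tailed Wilcoxon rank-sum (location) and a
two-tailed Fligner–Killeen (scale) comparison, BH-adjusted **within each
test family** over tested events only. Both tests are implemented
row-wise in compiled code with the normal approximation (tie and
continuity corrections) — the caller evaluates them inside 1,000-fold
shuffle and down-sampling loops, and `wilcox.test`/`fligner.test` are the
unit-test references. Inside the shuffle driver the Wilcoxon ranks are
precomputed once per event; they are invariant under label permutation.

The empirical p-value shares the literal-proportion semantics above. The
success rate (SR) guards against imbalance artifacts: the 300-sample rest
group is down-sampled to 100 without replacement 1,000 times and SR is the
fraction of iterations with p < 0.05. An event is **regulated** iff one
and the same test satisfies FDR < 0.05, emp-p < 0.05 and SR > 0.7
(thresholds strict, conjunction within a test; allowing conjuncts to mix
across tests would decouple each test family from its own null).
Whippet-style cell-line tables are handled by `filter_whippet_output()`
with the quoted thresholds (CI width < 0.2 in every sample; complexity
above K0, probability ≥ 0.9, |ΔΨ| > 0.05 strict).

At the study conditions (2,000 events, 10% planted |Δμ| = 0.2 at
concentration 60, 100 vs 300 samples) the caller reaches sensitivity 1.0
with empirical FDR ≈ 0.09–0.10, and calls ≤ 0.1% of events on a fully
null atlas; both are asserted in the acceptance tests. The empirical FDR
sits near 0.1 by construction: with 200 genuine signals among ~1,050
tested events the BH step-up threshold is lenient, and the SR criterion
does not penalize chance deviations of the fixed high group.

## Isoform trajectory

Regulated events with a nonzero change are split at overall mean
inclusion 0.5 and ranked outward toward the boundaries; cumulative counts
of positive and negative changes are recorded at each event's mean
inclusion. The null envelope redraws every event's sign ±1 with
probability 0.5 (1,000 iterations) and reports the per-grid-point mean
and 5–95% band. Exact two-tailed binomial tests (p₀ = 0.5, two-tailed by
summing outcomes no more probable than the observed one — the standard
exact definition) compare positive and negative counts in four
left-closed bins [0, 0.15), [0.15, 0.5), [0.5, 0.85), [0.85, 1]; the
cutoffs are stated by the procedure, the edge assignment is ours and
documented here. Binning uses the overall mean across all samples.

## NMD and chromatin annotation

Two deliberate overlap defaults coexist: the labelled NMD-determinant
exon list is intersected with **any** (≥ 1 bp) overlap (the default of
the standard intersection tool), while chromatin-signature marking
requires ≥ 90% **reciprocal** overlap of both intervals. Events hit by
both NMD label classes are ambiguous and conservatively labelled `none`.
The probability route classifies Δ = P(NMD | with exon) − P(NMD | without)
below its 15th percentile as PTC-preventing and above the 85th as
PTC-introducing, with percentiles over all supplied events. Enrichment
uses the exact conditional 2×2 test (two-tailed, point-probability rule);
inclusion-change asymmetries use the two-tailed rank-sum test.

## Splicing-code analysis

The motif space is the 512 tetramers formed by the 256 concrete words
over {A, C, G, T} plus the 256 fully degenerate words over the two-fold
IUPAC codes {R, Y, S, W} — the only composition of the named alphabet
that yields 512. Occurrence means presence/absence per region (not
counts); degenerate symbols match through the IUPAC machinery.

Regions per cassette exon: R1 = [−205, −5] nt of upstream intron before
the 3′ splice site, R2 = the exon (two 200-nt blocks off each splice site
when the exon exceeds 400 nt), R3 = [+10, +210] nt of downstream intron.
Sequences are handled in transcript orientation (minus-strand windows
reverse-complemented). Enrichment per tetramer is a two-tailed Fisher
test on presence between regulated and control exons plus a
label-permutation empirical p over (default) 10,000 reshuffles; the
permutation statistic is the regulated-set presence count, computed for
all 512 tetramers per iteration in one matrix product — at fixed margins
it orders permutations identically to the Fisher p. A tetramer is called
enriched iff Fisher p ≤ 0.05 — tightened to the 1st percentile of the
Fisher-p distribution when more than 5% of tetramers are significant (the
trigger is unquantified in the source; >5% is our default) — **and**
empirical p ≤ 0.0005.

Splicing maps cover the cassette exon's two junctions, 1,000 nt into each
intron and 50 nt into the exon (meta-map length 2,100). The source
procedure also panels the flanking exons' outer junctions; the synthetic
generator does not emulate flanking-exon sequences, so the default layout
omits those panels — `region_layout()` parameterizes the extents. The
motif map scores each position by a one-sided Fisher comparison of
occurrence coverage, `q = −2 ln p`, smoothed by a 15-nt running mean;
the crosslink map (CES) scores peak coverage the same way with the
natural logarithm — the Fisher-combination convention — and the shared
functional form is what makes q and t commensurable for the Bhattacharyya
comparison. This −2 ln p motif score replaces the original tool's
cluster-based internal score and is the package's principal deviation;
the map scorer is pluggable.

The tetramer's PWM is the column-stochastic frequency matrix of its
occurrences extended two nucleotides on each side (L = 8, pseudocount
0.5). PWM similarity ω aligns that matrix against the seven most
informative contiguous columns of a reference PWM at offsets
J ∈ {−3, −2, −1, 0} and takes the best mean column-wise Pearson
correlation; Ω averages ω over a factor's reference PWMs. The exact
metric of the external PWM-comparison tool is out of scope; the interface
accepts alternatives. The Bhattacharyya coefficient is computed on maps
normalized to unit sum as $\sum_i \sqrt{\hat q_i \hat t_i}$ — the
standard form with the radical; the displayed formula in the source
renders without it, both forms sit behind a switch, and the square-root
form is the default because it alone guarantees BC ∈ [0, 1] with equality
iff the maps coincide. `MatchingScore = Ω · BC`; within each tetramer,
factors at or above the 75th percentile of the MS distribution are called
associated (a global-percentile mode is available).

## Survival analysis

For an event group, each patient's S statistic is
`n25 / n75` — the number of group events at or below their 25th /
at or above their 75th percentile across patients — with an infinite
sentinel when `n75 = 0` that ranks above every finite value (no
pseudocount; the ratio is kept literal). Patients at or below the 25th /
at or above the 75th percentile of S (or of a single event's Ψ) form the
low/high strata; the middle half is excluded, mirroring the extreme-group
design. The Cox fit is a binary-covariate partial likelihood with Efron
tie handling, Wald 95% intervals, and a two-tailed log-rank test; the
per-event screen BH-adjusts log-rank p-values and classifies FDR < 0.05
candidates as harmful (HR > 1) or favorable (HR < 1).
`optimal_cutpoint()` scans midpoints between consecutive unique marker
values that leave at least 10% of patients on each side and returns the
cutpoint maximizing the standardized log-rank statistic.

## Tumor-purity simulation

`mix_profiles()` is the exact affine blend
$g = g_\text{tumor}\,p/100 + g_\text{benign}\,(1 - p/100)$ with one
benign profile drawn (with replacement) per tumor sample — the pairing is
unspecified in the source and per-sample draws are the least structured
choice. The p = 100 endpoint reproduces the tumor matrix bitwise.
`purity_sweep()` repeats the mix across levels and iterations, rerunning
the covariance decomposition (and optionally the differential caller) and
aggregating per-TF means/SDs of the $R^2$ shares plus per-gene
success rates. Within the sweep the differential caller defaults to its
FDR and fold-change conjuncts (`diffexpr_n_null = 0`); the Monte Carlo
empirical-p criterion can be switched on per iteration where its cost is
warranted.

## Numerical and workflow choices

* Strict inequalities at every published threshold, exactly as each is
  quoted (the source mixes <, ≤, >, ≥ across sections).
* BH everywhere via the step-up procedure (`p.adjust`); Fisher exact
  tests via the conditional point-probability rule; one-sided map tests
  via the hypergeometric tail directly.
* Intervals are 0-based half-open at the interfaces; conversions to the
  1-based machinery happen at the boundary. Book-ended intervals merge,
  matching the merging tool's default.
* Degenerate cases are explicit: constant test rows give p = 1, zero-mass
  maps give BC = 0, empty bins are not-applicable, inestimable Cox fits
  are reported as such, degenerate bootstrap resamples are skipped and
  counted (warning above 1%).
* Problem sizes in the tests and acceptance script: the splicing caller
  runs at the full 2,000 × 400 study scale with 1,000 shuffle and
  down-sampling iterations for recovery (200 for the null atlas); the
  motif analysis at 300 + 300 exons with 10,000 permutations; survival
  recovery over 50 (hazard-ratio) and 20 (screen) seeds; the purity sweep
  at 20 iterations per level. The numbered scripts under `analysis/`
  rerun the same workflow narratively and write their tables under
  `results/`.

## Known limitations

* LMG is exact-enumeration only (k ≤ 15); no sampling fallback.
* The motif-map score and the PWM similarity metric are principled
  stand-ins for two external tools whose internals are out of scope; both
  are pluggable.
* The splicing-map layout omits flanking-exon panels (see above).
* The generator's independence assumptions (events independent given the
  TF, benign profiles uncoupled from SRGs) make the planted-recovery
  results an upper bound on what correlated real data would give.
* Empirical FDR of the splicing caller sits near its nominal bound at the
  default conditions; tightening it would require raising SR or lowering
  the per-family FDR threshold, both of which would depart from the
  published procedure.
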
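#' Build a pipeline configuration
#'
#' Assembles every stage toggle, threshold and iteration count with the
#' study defaults pre-filled. The `"paper"` preset uses the published
#' iteration counts (10,000 expression null iterations, 1,000 label
#' shuffles, 1,000 down-samples, 1,000 trajectory iterations, 10,000
#' motif bootstraps, 100 purity iterations); the `"desk"` preset scales
#' them down (500 / 200 / 200 / 200 / 2,000 / 20) for interactive runs.
#'
#' @param seed master seed.
#' @param preset `"desk"` or `"paper"`.
#' @param sim a [sim_config()] (defaults to `sim_config(seed)`).
#' @param stages character vector of stages to run.
#' @param outdir optional output directory for stage TSVs.
#' @param ... overrides for individual iteration counts
#'   (`n_expr_null`, `n_shuffle`, `n_downsample`, `n_trajectory`,
#'   `n_motif_boot`, `n_purity`, `n_lmg_boot`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, preset = c("desk", "paper"),
                            sim = NULL,
                            stages = c("simulate", "covariance", "diffexpr",
                                       "events", "trajectory", "nmd",
                                       "splicing_code", "survival",
                                       "purity"),
                            outdir = NULL, ...) {
  preset <- match.arg(preset)
  iters <- if (preset == "paper") {
    list(n_expr_null = 10000L, n_shuffle = 1000L, n_downsample = 1000L,
         n_trajectory = 1000L, n_motif_boot = 10000L, n_purity = 100L,
         n_lmg_boot = 1000L)
  } else {
    list(n_expr_null = 500L, n_shuffle = 200L, n_downsample = 200L,
         n_trajectory = 200L, n_motif_boot = 2000L, n_purity = 20L,
         n_lmg_boot = 200L)
  }
  over <- list(...)
  iters[names(over)] <- over
  cfg <- c(list(seed = as.integer(seed), preset = preset,
                sim = if (is.null(sim)) sim_config(seed = seed) else sim,
                stages = stages, outdir = outdir), iters)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order: simulate the cohort, fit the
#' TF -> SRG covariance model, call differentially expressed SRGs, call
#' regulated splicing events, compute the inclusion trajectory, annotate
#' NMD-determinant exons, run the splicing-code motif analysis, screen
#' events for survival association, and sweep tumor purity. A stage
#' failure halts its dependents while independent stages continue.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results plus a `summary` data.frame of the
#'   counts at each filter and an `errors` list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(errors = list())
  on_stage <- function(name) name %in% config$stages
  run_stage <- function(name, deps, fn) {
    if (!on_stage(name)) return(invisible(NULL))
    if (any(vapply(deps, function(d) is.null(res[[d]]), logical(1)))) {
      res$errors[[name]] <<- "skipped: missing dependency"
      return(invisible(NULL))
    }
    out <- tryCatch(fn(), error = function(e) {
      res$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    res[[name]] <<- out
    invisible(NULL)
  }

  run_stage("simulate", character(0), function() {
    sim <- config$sim
    expr <- generate_expression(sim)
    psi_data <- generate_psi(sim, expr[sim$tf_names[1], ])
    clinical <- generate_survival(psi_data$psi, sim)
    benign <- generate_benign(sim)
    seq_data <- generate_sequences_and_peaks(sim)
    list(sim = sim, expr = expr, psi_data = psi_data, clinical = clinical,
         benign = benign, seq_data = seq_data)
  })
  run_stage("covariance", "simulate", function() {
    s <- res$simulate
    response <- colSums(s$expr[s$sim$srg_names, , drop = FALSE])
    covariance_analysis(response, t(s$expr[s$sim$tf_names, , drop = FALSE]),
                        n_boot = config$n_lmg_boot, seed = config$seed)
  })
  run_stage("diffexpr", "simulate", function() {
    s <- res$simulate
    diffexpr_pipeline(s$expr, s$sim$tf_names[1], mode = "tpm_only",
                      n_iter = config$n_expr_null, seed = config$seed)
  })
  run_stage("events", "simulate", function() {
    s <- res$simulate
    high <- stratify_by_expression(s$expr, s$sim$tf_names[1])
    call_splicing_events(s$psi_data$psi, s$psi_data$meta, high,
                         n_shuffle = config$n_shuffle,
                         n_downsample = config$n_downsample,
                         seed = config$seed)
  })
  run_stage("trajectory", "events", function() {
    list(curves = cumulative_curves(res$events, "delta_mu"),
         envelope = monte_carlo_envelope(res$events, "delta_mu",
                                         n_iter = config$n_trajectory,
                                         seed = config$seed),
         bins = bin_binomial_tests(res$events, "delta_mu"))
  })
  run_stage("nmd", "events", function() {
    ev <- res$events
    set.seed(substream_seed(config$seed, "nmd_probs"))
    # emulated NMD probabilities: inputs to the classifier, not predictions
    ann <- classify_by_probability(ev$event_id,
                                   stats::runif(nrow(ev)),
                                   stats::runif(nrow(ev)))
    list(annotation = ann,
         enrichment = enrichment_2x2(
           ev$event_id[ev$call == "regulated"],
           ev$event_id[ev$call == "unregulated"],
           ann, "PTC-introducing"))
  })
  run_stage("splicing_code", "simulate", function() {
    s <- res$simulate
    sd <- s$seq_data
    ref <- list()
    ref[["RBP_TRUE"]] <- list(pwm_from_occurrences(sd$truth_tetramer,
                                                   sd$regulated))
    # background candidate: uninformative PWM, no crosslink peaks
    ref[["RBP_BG"]] <- list(matrix(0.25, 4, 11,
                                   dimnames = list(c("A", "C", "G", "T"),
                                                   NULL)))
    splicing_code_analysis(sd$regulated, sd$control, sd$layout, ref,
                           sd$peaks, n_boot = config$n_motif_boot,
                           seed = config$seed)
  })
  run_stage("survival", c("simulate", "events"), function() {
    s <- res$simulate
    fl <- filter_and_impute(s$psi_data$psi, s$psi_data$meta)
    reg <- intersect(res$events$event_id[res$events$call == "regulated"],
                     rownames(fl$psi))
    out <- list()
    if (length(reg) >= 1) {
      ss <- s_statistic(fl$psi, reg)
      lab <- stratify_patients(ss$s)
      m <- match(ss$sample, s$clinical$sample)
      out$s_stat <- cox_univariate(s$clinical$time[m], s$clinical$status[m],
                                   lab)
    }
    out$per_event <- per_event_survival(
      fl$psi[intersect(rownames(fl$psi), res$events$event_id), , drop = FALSE],
      s$clinical)
    out
  })
  run_stage("purity", "simulate", function() {
    s <- res$simulate
    purity_sweep(s$expr, s$benign, s$sim$tf_names, s$sim$srg_names,
                 n_iter = config$n_purity, seed = config$seed)
  })

  res$summary <- pipeline_summary(res)
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  res
}

pipeline_summary <- function(res) {
  rows <- list()
  add <- function(stage, metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, metric = metric,
                                             value = value)
  if (!is.null(res$simulate)) {
    add("simulate", "n_samples", ncol(res$simulate$expr))
    add("simulate", "n_events", nrow(res$simulate$psi_data$psi))
  }
  if (!is.null(res$covariance)) add("covariance", "r2", res$covariance$r2)
  if (!is.null(res$diffexpr))
    add("diffexpr", "n_called", sum(res$diffexpr$call != "unchanged"))
  if (!is.null(res$events)) {
    add("events", "n_tested", sum(res$events$prefilter_pass))
    add("events", "n_regulated", sum(res$events$call == "regulated"))
  }
  if (!is.null(res$splicing_code))
    add("splicing_code", "n_enriched",
        sum(res$splicing_code$enrichment$enriched))
  if (!is.null(res$survival) && !is.null(res$survival$per_event))
    add("survival", "n_candidates", sum(res$survival$per_event$candidate))
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(res$events)) wt(res$events, "event_stats.tsv")
  if (!is.null(res$diffexpr)) wt(res$diffexpr, "diffexpr_calls.tsv")
  if (!is.null(res$trajectory)) {
    wt(res$trajectory$curves, "trajectory_curves.tsv")
    wt(res$trajectory$bins, "trajectory_bins.tsv")
  }
  if (!is.null(res$splicing_code)) {
    wt(res$splicing_code$enrichment, "tetramer_enrichment.tsv")
    if (!is.null(res$splicing_code$matching))
      wt(res$splicing_code$matching, "matching_scores.tsv")
  }
  if (!is.null(res$survival) && !is.null(res$survival$per_event))
    wt(res$survival$per_event, "per_event_survival.tsv")
  if (!is.null(res$purity)) wt(res$purity$contributions,
                               "purity_contributions.tsv")
  if (!is.null(res$summary)) wt(res$summary, "summary.tsv")
  invisible(outdir)
}
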
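#' Configuration for the synthetic-data generator
#'
#' Bundles and validates every knob of the seeded generator that emulates
#' the statistical structure of the study inputs: log-normal TPM expression
#' with a linear TF -> splicing-related-gene (SRG) dependence on the log
#' scale, Beta-distributed percent-spliced-in (PSI) values with planted
#' group-dependent mean/dispersion shifts and completely-at-random
#' missingness, PTC-introducing/preventing annotations, right-censored
#' survival times with inclusion-dependent hazards, benign expression
#' profiles for purity mixing, and sequence windows with planted tetramers
#' plus co-located synthetic crosslink peaks.
#'
#' Defaults are the desk-scale study conditions: 400 tumor samples (so the
#' top-quartile split yields 100 vs 300), four TFs with the first one
#' dominant (log-scale weight 0.8 vs 0.1), 148 SRGs, 2,000 splicing events
#' of which 10% carry a planted |delta mu(PSI)| = 0.2 at Beta concentration
#' 60, 10% missingness, and 107 benign profiles.
#'
#' @param seed integer master seed; every generator derives its own
#'   sub-stream from it.
#' @param n_samples number of tumor samples.
#' @param n_genes number of SRGs.
#' @param tf_names character vector of TF identifiers (first is the focal
#'   TF used for stratification).
#' @param srg_names character vector of SRG identifiers (default
#'   `SRG001...`).
#' @param tf_to_srg_weights numeric matrix (`n_genes` x `length(tf_names)`)
#'   of log-scale linear coefficients; default 0.8 on the first TF and 0.1
#'   on the others for every SRG.
#' @param expr_noise_sd log-scale Gaussian noise SD for SRG expression.
#' @param n_events number of splicing events.
#' @param frac_regulated fraction of events with a planted group effect.
#' @param delta_mu_effect magnitude of the planted shift in mean PSI for
#'   the high-TF group (sign drawn per event unless `inhibit_low_mu`).
#' @param delta_sigma_effect log2 concentration shift in the high-TF group
#'   for planted events (positive = more dispersed high group).
#' @param psi_concentration Beta precision (alpha + beta) of PSI draws.
#' @param missing_rate completely-at-random missingness of PSI entries.
#' @param frac_ptc_introducing,frac_ptc_preventing fractions of events
#'   annotated as PTC-introducing / PTC-preventing.
#' @param hazard_coefficients named numeric vector of per-event log-hazard
#'   coefficients (names are event ids or indices into the event table).
#' @param hazard_event_concentration Beta precision for hazard-bearing
#'   events (default 2, i.e. broad inclusion across patients, the regime
#'   in which an exon can stratify outcome; the atlas-wide
#'   `psi_concentration` would leave prognostic events with almost no
#'   between-patient spread).
#' @param censoring_rate target fraction of censored patients.
#' @param n_benign number of benign expression profiles.
#' @param inhibit_low_mu if `TRUE`, planted events with baseline mean below
#'   0.15 are forced to a negative shift (emulates inhibition of lowly
#'   included exons).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 400L,
                       n_genes = 148L,
                       tf_names = c("FOXA1", "AR", "HOXB13", "MYC"),
                       srg_names = sprintf("SRG%03d", seq_len(n_genes)),
                       tf_to_srg_weights = NULL,
                       expr_noise_sd = 0.5,
                       n_events = 2000L,
                       frac_regulated = 0.1,
                       delta_mu_effect = 0.2,
                       delta_sigma_effect = 0,
                       psi_concentration = 60,
                       missing_rate = 0.1,
                       frac_ptc_introducing = 0.15,
                       frac_ptc_preventing = 0.15,
                       hazard_coefficients = numeric(0),
                       censoring_rate = 0.3,
                       n_benign = 107L,
                       inhibit_low_mu = FALSE,
                       hazard_event_concentration = 2) {
  if (is.null(tf_to_srg_weights)) {
    tf_to_srg_weights <- matrix(0.1, nrow = n_genes, ncol = length(tf_names),
                                dimnames = list(srg_names, tf_names))
    tf_to_srg_weights[, 1] <- 0.8
  }
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes), tf_names = tf_names,
              srg_names = srg_names, tf_to_srg_weights = tf_to_srg_weights,
              expr_noise_sd = expr_noise_sd, n_events = as.integer(n_events),
              frac_regulated = frac_regulated,
              delta_mu_effect = delta_mu_effect,
              delta_sigma_effect = delta_sigma_effect,
              psi_concentration = psi_concentration,
              missing_rate = missing_rate,
              frac_ptc_introducing = frac_ptc_introducing,
              frac_ptc_preventing = frac_ptc_preventing,
              hazard_coefficients = hazard_coefficients,
              censoring_rate = censoring_rate, n_benign = as.integer(n_benign),
              inhibit_low_mu = isTRUE(inhibit_low_mu),
              hazard_event_concentration = hazard_event_concentration)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fr <- c("frac_regulated", "missing_rate", "frac_ptc_introducing",
          "frac_ptc_preventing", "censoring_rate")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$psi_concentration <= 0) stop("psi_concentration must be positive")
  if (cfg$expr_noise_sd < 0) stop("expr_noise_sd must be non-negative")
  if (abs(cfg$delta_mu_effect) > 1) stop("delta_mu_effect must be in [-1, 1]")
  if (!all(is.finite(cfg$tf_to_srg_weights)))
    stop("tf_to_srg_weights must be finite")
  w <- cfg$tf_to_srg_weights
  if (nrow(w) != cfg$n_genes || ncol(w) != length(cfg$tf_names))
    stop("tf_to_srg_weights must be n_genes x length(tf_names)")
  if (cfg$frac_ptc_introducing + cfg$frac_ptc_preventing > 1)
    stop("PTC fractions must sum to at most 1")
  invisible(cfg)
}

#' Generate TF and SRG expression (TPM-like)
#'
#' TF rows are drawn log-normal; each SRG row is
#' `exp(sum(weights * log TF) + intercept + noise)`, so the TF -> SRG
#' dependence is linear on the log scale with Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return numeric matrix (genes x samples), TFs first, all values >= 0.
#' @export
generate_expression <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "expression"))
  n <- config$n_samples
  ntf <- length(config$tf_names)
  log_tf <- matrix(stats::rnorm(ntf * n, mean = log(50), sd = 0.8),
                   nrow = ntf, dimnames = list(config$tf_names, NULL))
  noise <- matrix(stats::rnorm(config$n_genes * n, sd = config$expr_noise_sd),
                  nrow = config$n_genes)
  log_srg <- config$tf_to_srg_weights %*% log_tf + noise
  m <- exp(rbind(log_tf, log_srg))
  rownames(m) <- c(config$tf_names, config$srg_names)
  colnames(m) <- sprintf("S%03d", seq_len(n))
  m
}

#' Generate benign expression profiles
#'
#' Benign profiles share the TF/SRG gene set but lack the TF -> SRG
#' dependence: every row is independent log-normal around its own baseline,
#' emulating stromal/benign tissue without the tumor's regulatory program.
#'
#' @param config a [sim_config()].
#' @return numeric matrix (genes x `n_benign` samples).
#' @export
generate_benign <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "benign"))
  genes <- c(config$tf_names, config$srg_names)
  m <- matrix(exp(stats::rnorm(length(genes) * config$n_benign,
                               mean = log(50), sd = 0.8)),
              nrow = length(genes),
              dimnames = list(genes, sprintf("B%03d", seq_len(config$n_benign))))
  m
}

#' Generate a PSI event table with planted group effects
#'
#' Each event gets a baseline mean `mu0` in (0.02, 0.98); for planted
#' regulated events, samples in the high-TF group (>= 75th percentile of
#' `foxa1_levels`, linear-interpolation quantile — the same rule the caller
#' uses) draw PSI from a Beta with mean `mu0 + delta` (clipped to
#' (0.01, 0.99)) and/or a concentration scaled by
#' `2^(-delta_sigma_effect)`. Missingness is applied completely at random.
#'
#' @param config a [sim_config()].
#' @param foxa1_levels per-sample expression of the focal TF (length
#'   `n_samples`).
#' @return a list with
#'   \describe{
#'     \item{psi}{events x samples matrix with NAs for missing entries}
#'     \item{meta}{per-event metadata data.frame (event_id, gene, category,
#'       chrom, start, end, strand; 0-based half-open)}
#'     \item{truth}{per-event data.frame with planted status, direction and
#'       baseline mean}
#'     \item{high_group}{logical mask of high-TF samples}
#'   }
#' @export
generate_psi <- function(config, foxa1_levels) {
  validate_sim_config(config)
  if (length(foxa1_levels) != config$n_samples)
    stop("foxa1_levels must have length n_samples")
  set.seed(substream_seed(config$seed, "psi"))
  n <- config$n_samples
  ne <- config$n_events
  high <- foxa1_levels >= pctl(foxa1_levels, 75)

  mu0 <- stats::runif(ne, 0.02, 0.98)
  event_id <- sprintf("EV%04d", seq_len(ne))
  # hazard-bearing events start from a mixed isoform population (broad,
  # mid-range inclusion) -- the regime in which an exon can stratify
  # patients
  prog <- event_id %in% names(config$hazard_coefficients)
  mu0[prog] <- 0.5
  n_reg <- round(config$frac_regulated * ne)
  regulated <- rep(FALSE, ne)
  regulated[sample.int(ne, n_reg)] <- TRUE
  direction <- integer(ne)
  direction[regulated] <- sample(c(-1L, 1L), n_reg, replace = TRUE)
  if (config$inhibit_low_mu) direction[regulated & mu0 < 0.15] <- -1L

  mu_high <- mu0
  delta <- direction * config$delta_mu_effect
  mu_high[regulated] <- pmin(0.99, pmax(0.01, mu0[regulated] + delta[regulated]))
  conc <- config$psi_concentration
  conc_high <- rep(conc, ne)
  conc_high[regulated] <- conc * 2^(-config$delta_sigma_effect)

  # hazard-bearing events get a broad inclusion distribution
  conc_base <- rep(conc, ne)
  conc_base[prog] <- config$hazard_event_concentration
  conc_high[prog] <- config$hazard_event_concentration

  psi <- matrix(NA_real_, nrow = ne, ncol = n)
  for (i in seq_len(ne)) {
    m_rest <- mu0[i]; m_high <- mu_high[i]
    psi[i, !high] <- stats::rbeta(sum(!high), m_rest * conc_base[i],
                                  (1 - m_rest) * conc_base[i])
    psi[i, high] <- stats::rbeta(sum(high), m_high * conc_high[i],
                                 (1 - m_high) * conc_high[i])
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(ne * n) < config$missing_rate, nrow = ne)
    psi[miss] <- NA_real_
  }
  rownames(psi) <- event_id
  colnames(psi) <- sprintf("S%03d", seq_len(n))

  # metadata: events spread over genes (~8 per gene) and chromosomes
  genes <- sprintf("GENE%04d", ceiling(seq_len(ne) / 8))
  chrom <- paste0("chr", sample(1:22, ne, replace = TRUE))
  start <- sample.int(1e8, ne)
  len <- sample(60:300, ne, replace = TRUE)
  meta <- data.frame(event_id = event_id, gene = genes,
                     category = sample(c("CE", "A3", "A5", "IR", "MEX"), ne,
                                       replace = TRUE,
                                       prob = c(0.6, 0.1, 0.1, 0.1, 0.1)),
                     chrom = chrom, start = start, end = start + len,
                     strand = sample(c("+", "-"), ne, replace = TRUE),
                     stringsAsFactors = FALSE)
  truth <- data.frame(event_id = event_id,
                      planted = regulated,
                      direction = direction,
                      mu0 = mu0,
                      label = ifelse(regulated, "regulated", "unregulated"),
                      stringsAsFactors = FALSE)
  list(psi = psi, meta = meta, truth = truth, high_group = high)
}

#' Generate right-censored survival times with inclusion-dependent hazards
#'
#' Event times are exponential with per-patient log relative hazard
#' `sum(coefficient * PSI(patient, event))` over the planted prognostic
#' events; censoring is independent exponential with its rate tuned so the
#' expected censored fraction matches `censoring_rate`.
#'
#' @param psi events x patients PSI matrix (missing values allowed; a
#'   missing planted entry contributes the event's mean).
#' @param config a [sim_config()] whose `hazard_coefficients` name events
#'   present in `psi`.
#' @return data.frame (sample, time, status) with `status` 1 = event,
#'   0 = censored; all times > 0.
#' @export
generate_survival <- function(psi, config) {
  validate_sim_config(config)
  coefs <- config$hazard_coefficients
  if (length(coefs) > 0 && is.null(names(coefs)))
    stop("hazard_coefficients must be named by event id")
  if (!all(names(coefs) %in% rownames(psi)))
    stop("hazard_coefficients refer to unknown events")
  set.seed(substream_seed(config$seed, "survival"))
  n <- ncol(psi)
  lp <- numeric(n)
  for (ev in names(coefs)) {
    v <- psi[ev, ]
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    lp <- lp + coefs[[ev]] * v
  }
  base_rate <- 0.1
  times <- stats::rexp(n, rate = base_rate * exp(lp))
  cr <- config$censoring_rate
  if (cr > 0) {
    cens_rate <- base_rate * mean(exp(lp)) * cr / (1 - cr)
    ctimes <- stats::rexp(n, rate = cens_rate)
    status <- as.integer(times <= ctimes)
    times <- pmin(times, ctimes)
  } else {
    status <- rep(1L, n)
  }
  data.frame(sample = colnames(psi), time = times, status = status,
             stringsAsFactors = FALSE)
}

#' Generate exon sequence windows with a planted tetramer and peaks
#'
#' Builds, for a regulated and a control exon set, sequence windows laid
#' out as (upstream intron | exon | downstream intron), plants a chosen
#' tetramer in region R1 (the [-205, -5] window upstream of the 3' splice
#' site) of a configurable fraction of each set, and places synthetic
#' crosslink peaks exactly over the planted occurrences. Background is
#' uniform over {A, C, G, T}.
#'
#' @param config a [sim_config()] (supplies the seed).
#' @param tetramer 4-letter motif over {A,C,G,T} to plant.
#' @param n_regulated,n_control exon counts per set.
#' @param plant_frac_regulated,plant_frac_control planting fractions.
#' @param intron_len,exon_len window geometry in nucleotides.
#' @param peak_factor identifier for the synthetic RBP owning the peaks.
#' @param peak_pad peak half-width around each planted occurrence.
#' @return list with `regulated` / `control` (named character vectors of
#'   sequences), `layout` (region coordinate list), `peaks` (data.frame of
#'   0-based half-open peak intervals in window coordinates, with factor
#'   and set), and `truth_tetramer`.
#' @export
generate_sequences_and_peaks <- function(config,
                                         tetramer = "GCAT",
                                         n_regulated = 300L,
                                         n_control = 300L,
                                         plant_frac_regulated = 0.5,
                                         plant_frac_control = 0.02,
                                         intron_len = 1000L,
                                         exon_len = 150L,
                                         peak_factor = "RBP_TRUE",
                                         peak_pad = 10L) {
  validate_sim_config(config)
  if (nchar(tetramer) != 4) stop("tetramer must have length 4")
  if (!grepl("^[ACGT]{4}$", tetramer))
    stop("planted tetramer must be over {A,C,G,T}")
  set.seed(substream_seed(config$seed, "sequences"))
  layout <- region_layout(intron_len = intron_len, exon_len = exon_len)

  make_set <- function(n, frac, prefix) {
    total <- 2L * intron_len + exon_len
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- sprintf("%s%03d", prefix, seq_len(n))
    planted <- stats::runif(n) < frac
    pos <- rep(NA_integer_, n)
    # R1 window in 0-based window coordinates: the [-205, -5] stretch of
    # the upstream intron relative to the 3' splice site at `intron_len`.
    r1_lo <- intron_len - 205L
    r1_hi <- intron_len - 5L - 4L
    for (i in which(planted)) {
      p <- sample(r1_lo:r1_hi, 1L)
      substr(seqs[i], p + 1L, p + 4L) <- tetramer
      pos[i] <- p
    }
    list(seqs = seqs, planted = planted, pos = pos)
  }
  reg <- make_set(n_regulated, plant_frac_regulated, "REG")
  ctl <- make_set(n_control, plant_frac_control, "CTL")

  mk_peaks <- function(set, group) {
    i <- which(set$planted)
    if (length(i) == 0) return(NULL)
    data.frame(seq_id = names(set$seqs)[i], factor = peak_factor,
               start = pmax(0L, set$pos[i] - peak_pad),
               end = set$pos[i] + 4L + peak_pad,
               set = group, stringsAsFactors = FALSE)
  }
  peaks <- rbind(mk_peaks(reg, "regulated"), mk_peaks(ctl, "control"))
  list(regulated = reg$seqs, control = ctl$seqs, layout = layout,
       peaks = peaks, truth_tetramer = tetramer,
       planted_regulated = reg$planted, planted_control = ctl$planted)
}
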
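#' Per-patient S statistic over an event group
#'
#' For each patient, `n25` counts the group's events whose PSI in that
#' patient is at or below the event's 25th percentile across patients,
#' `n75` counts those at or above the 75th percentile, and
#' `S = n25 / n75` (with an infinite sentinel when `n75 = 0`, ranked
#' above every finite S). Events that are constant across patients have
#' degenerate percentiles and are skipped.
#'
#' @param psi events x patients PSI matrix (imputed).
#' @param event_group event ids defining the group.
#' @return data.frame (sample, n25, n75, s) with `s = Inf` sentinels.
#' @export
s_statistic <- function(psi, event_group) {
  if (length(event_group) == 0) stop("empty event group")
  missing_ev <- setdiff(event_group, rownames(psi))
  if (length(missing_ev) > 0)
    stop("events not in matrix: ", paste(missing_ev, collapse = ", "))
  x <- psi[event_group, , drop = FALSE]
  constant <- apply(x, 1, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    message(sum(constant), " constant events skipped in S statistic")
    x <- x[!constant, , drop = FALSE]
    if (nrow(x) == 0) stop("no usable events in group")
  }
  q25 <- apply(x, 1, pctl, 25)
  q75 <- apply(x, 1, pctl, 75)
  n25 <- colSums(x <= q25)
  n75 <- colSums(x >= q75)
  data.frame(sample = colnames(psi), n25 = n25, n75 = n75,
             s = ifelse(n75 == 0, Inf, n25 / n75),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stratify patients into low/high extreme groups
#'
#' Low = value at or below the 25th percentile, high = at or above the
#' 75th percentile (linear-interpolation quantiles); the middle half is
#' excluded from the model. Infinite sentinels always land in the high
#' stratum.
#'
#' @param values per-patient numeric values (S statistic or an event's
#'   PSI).
#' @param low_pct,high_pct percentile cutoffs.
#' @return character vector in {low, high, excluded}.
#' @export
stratify_patients <- function(values, low_pct = 25, high_pct = 75) {
  if (length(values) < 8) stop("need at least 8 patients")
  finite <- values[is.finite(values)]
  lo <- pctl(finite, low_pct)
  hi <- pctl(finite, high_pct)
  lab <- rep("excluded", length(values))
  lab[values <= lo] <- "low"
  lab[values >= hi | is.infinite(values)] <- "high"
  if (!any(lab == "low") || !any(lab == "high"))
    stop("a stratum is empty after tie handling")
  lab
}

#' Univariate Cox model between two strata
#'
#' Binary-covariate Cox proportional-hazards fit (Efron tie handling)
#' with a two-tailed log-rank test; the hazard ratio is high vs low.
#'
#' @param time follow-up times.
#' @param status event indicator (1 = event, 0 = censored).
#' @param labels stratification labels from [stratify_patients()];
#'   `excluded` patients are dropped.
#' @return list with `hr`, `ci` (Wald 95%), `logrank_p`, `n_low`,
#'   `n_high`, or `estimable = FALSE` when a stratum has no events.
#' @export
cox_univariate <- function(time, status, labels) {
  keep <- labels %in% c("low", "high")
  time <- time[keep]; status <- status[keep]
  grp <- factor(labels[keep], levels = c("low", "high"))
  if (sum(status[grp == "low"]) == 0 || sum(status[grp == "high"]) == 0)
    return(list(estimable = FALSE, hr = NA_real_, ci = c(NA_real_, NA_real_),
                logrank_p = NA_real_, n_low = sum(grp == "low"),
                n_high = sum(grp == "high")))
  fit <- survival::coxph(survival::Surv(time, status) ~ grp,
                         ties = "efron")
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  lr_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(estimable = TRUE, hr = exp(beta),
       ci = exp(beta + c(-1.96, 1.96) * se),
       logrank_p = lr_p, n_low = sum(grp == "low"),
       n_high = sum(grp == "high"))
}

#' Per-event survival screen
#'
#' Stratifies patients at the 25th/75th PSI percentiles of each event,
#' fits the univariate Cox model, BH-adjusts the log-rank p-values
#' across events, and classifies candidates as harmful (HR > 1) or
#' favorable (HR < 1). Per-event failures are recorded, not fatal.
#'
#' @param psi events x patients matrix (imputed).
#' @param clinical data.frame (sample, time, status) covering the
#'   matrix's patients.
#' @param events event ids to screen (default all rows).
#' @param fdr_max candidate threshold (strict <).
#' @return data.frame per event: hr, ci bounds, logrank_p, fdr,
#'   direction in {harmful, favorable, none}, candidate flag, n per
#'   stratum.
#' @export
per_event_survival <- function(psi, clinical, events = rownames(psi),
                               fdr_max = 0.05) {
  m <- match(colnames(psi), clinical$sample)
  if (anyNA(m)) stop("clinical table does not cover all patients")
  time <- clinical$time[m]; status <- clinical$status[m]
  rows <- lapply(events, function(ev) {
    res <- tryCatch({
      lab <- stratify_patients(psi[ev, ])
      cox_univariate(time, status, lab)
    }, error = function(e) list(estimable = FALSE, hr = NA_real_,
                                ci = c(NA_real_, NA_real_),
                                logrank_p = NA_real_, n_low = NA_integer_,
                                n_high = NA_integer_))
    data.frame(event_id = ev, hr = res$hr, ci_lo = res$ci[1],
               ci_hi = res$ci[2], logrank_p = res$logrank_p,
               n_low = res$n_low, n_high = res$n_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$logrank_p, method = "BH")
  out$candidate <- !is.na(out$fdr) & out$fdr < fdr_max
  out$direction <- ifelse(!out$candidate, "none",
                          ifelse(out$hr > 1, "harmful", "favorable"))
  out
}

#' Maximally selected log-rank cutpoint
#'
#' Scans candidate cutpoints (midpoints between consecutive unique
#' values, restricted so each side keeps at least `minprop` of the
#' patients), computes the standardized two-sample log-rank statistic at
#' each, and returns the cutpoint with the largest absolute standardized
#' statistic.
#'
#' @param values per-patient PSI (or any marker) values.
#' @param time,status survival outcome.
#' @param minprop minimum fraction of patients on each side (default
#'   0.1).
#' @return list with `cutpoint`, `statistic` (absolute standardized
#'   log-rank), and the scanned `candidates` data.frame.
#' @export
optimal_cutpoint <- function(values, time, status, minprop = 0.1) {
  n <- length(values)
  if (sum(status) == 0) stop("no events observed")
  if (n < 20) stop("need at least 20 patients")
  u <- sort(unique(values))
  mids <- (u[-1] + u[-length(u)]) / 2
  admissible <- vapply(mids, function(ct) {
    nl <- sum(values <= ct)
    nl >= minprop * n && (n - nl) >= minprop * n
  }, logical(1))
  mids <- mids[admissible]
  if (length(mids) == 0) stop("no admissible cutpoint under minprop")
  stat <- vapply(mids, function(ct) {
    g <- values > ct
    sd <- survival::survdiff(survival::Surv(time, status) ~ g)
    # standardized statistic: signed sqrt of the log-rank chi-square
    sqrt(sd$chisq)
  }, numeric(1))
  best <- which.max(stat)
  list(cutpoint = mids[best], statistic = stat[best],
       candidates = data.frame(cutpoint = mids, statistic = stat))
}
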
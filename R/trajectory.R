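
# Signed changes of regulated events for one change type, with zero
# changes dropped (they carry no direction).
trajectory_input <- function(stats, change = c("delta_mu", "delta_sigma")) {
  change <- match.arg(change)
  reg <- stats[stats$call == "regulated", , drop = FALSE]
  if (nrow(reg) == 0) stop("no regulated events")
  sgn <- sign(reg[[change]])
  if (any(sgn == 0))
    message(sum(sgn == 0), " events with exactly zero change excluded")
  keep <- sgn != 0
  data.frame(event_id = reg$event_id[keep], mu = reg$mu_all[keep],
             sgn = sgn[keep], stringsAsFactors = FALSE)
}

#' Cumulative mixed-to-dominant trajectory curves
#'
#' Counts regulated events with positive and negative splicing changes
#' cumulatively along the mean-inclusion axis, starting from mu(PSI) = 0.5
#' (mixed isoform population) and moving to the boundaries 0 and 1
#' (dominant isoform population). Events with mean inclusion below 0.5
#' populate the lower half-axis, the rest the upper one; within each
#' half-axis events are ranked by distance from 0.5 and the cumulative
#' counts are recorded at each event's mean inclusion.
#'
#' @param stats per-event stats data.frame from [call_splicing_events()]
#'   (needs `call`, `mu_all` and the change column).
#' @param change `"delta_mu"` or `"delta_sigma"`.
#' @return data.frame (half, mu, n_pos, n_neg); within each half the
#'   counts are non-decreasing with distance from 0.5.
#' @export
cumulative_curves <- function(stats, change = c("delta_mu", "delta_sigma")) {
  d <- trajectory_input(stats, change)
  one_half <- function(sub, half) {
    if (nrow(sub) == 0)
      return(data.frame(half = character(0), mu = numeric(0),
                        n_pos = integer(0), n_neg = integer(0)))
    ord <- order(abs(sub$mu - 0.5))
    sub <- sub[ord, ]
    data.frame(half = half, mu = sub$mu,
               n_pos = cumsum(sub$sgn > 0), n_neg = cumsum(sub$sgn < 0),
               stringsAsFactors = FALSE)
  }
  rbind(one_half(d[d$mu < 0.5, ], "lower"),
        one_half(d[d$mu >= 0.5, ], "upper"))
}

#' Monte Carlo random-sign null envelope for trajectory curves
#'
#' For each iteration the direction of every regulated event's change is
#' drawn +/-1 with probability 0.5 and the cumulative curves are
#' recomputed at the observed grid points; the per-point mean and the
#' 5th/95th percentile envelope are returned.
#'
#' @inheritParams cumulative_curves
#' @param n_iter number of Monte Carlo iterations (study default 1,000).
#' @param seed integer seed.
#' @return data.frame (half, mu, null_mean, lo5, hi95) for the positive
#'   count (the negative count's null is its mirror image).
#' @export
monte_carlo_envelope <- function(stats, change = c("delta_mu", "delta_sigma"),
                                 n_iter = 1000L, seed = 1L) {
  d <- trajectory_input(stats, change)
  set.seed(substream_seed(seed, "trajectory"))
  one_half <- function(sub, half) {
    m <- nrow(sub)
    if (m == 0)
      return(data.frame(half = character(0), mu = numeric(0),
                        null_mean = numeric(0), lo5 = numeric(0),
                        hi95 = numeric(0)))
    ord <- order(abs(sub$mu - 0.5))
    sub <- sub[ord, ]
    signs <- matrix(stats::runif(n_iter * m) < 0.5, nrow = n_iter)
    cums <- t(apply(signs, 1, cumsum))     # n_iter x m positive counts
    if (m == 1) cums <- matrix(cums, ncol = 1)
    data.frame(half = half, mu = sub$mu,
               null_mean = colMeans(cums),
               lo5 = apply(cums, 2, stats::quantile, 0.05, type = 7),
               hi95 = apply(cums, 2, stats::quantile, 0.95, type = 7),
               stringsAsFactors = FALSE)
  }
  rbind(one_half(d[d$mu < 0.5, ], "lower"),
        one_half(d[d$mu >= 0.5, ], "upper"))
}

#' Exact binomial tests in inclusion bins
#'
#' Splits regulated events with a nonzero change into four mean-inclusion
#' bins — [0, 0.15), [0.15, 0.5), [0.5, 0.85), [0.85, 1] — and tests, per
#' bin, whether positive and negative changes are equally abundant with a
#' two-tailed exact binomial test (p0 = 0.5; two-tailed by summing all
#' outcomes at most as probable as the observed one).
#'
#' @inheritParams cumulative_curves
#' @param cutoffs interior bin boundaries.
#' @return data.frame (bin, lo, hi, n_pos, n_neg, p); empty bins get
#'   `p = NA`.
#' @export
bin_binomial_tests <- function(stats, change = c("delta_mu", "delta_sigma"),
                               cutoffs = c(0.15, 0.50, 0.85)) {
  d <- trajectory_input(stats, change)
  edges <- c(0, cutoffs, 1 + 1e-12)   # left-closed bins; 1 falls in the last
  out <- lapply(seq_len(length(edges) - 1), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    sel <- d$mu >= lo & d$mu < hi
    np <- sum(d$sgn[sel] > 0); nn <- sum(d$sgn[sel] < 0)
    p <- if (np + nn == 0) NA_real_ else
      stats::binom.test(np, np + nn, p = 0.5)$p.value
    data.frame(bin = sprintf("[%.2f,%.2f)", lo, min(hi, 1)),
               lo = lo, hi = min(hi, 1), n_pos = np, n_neg = nn, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
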
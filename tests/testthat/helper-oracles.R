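# Independent oracle implementations used to cross-check the package's
# computations. These deliberately use naive algorithms (explicit
# enumeration, quadratic scans) and stay independent of the code paths
# they validate.

# LMG shares by explicit enumeration of all k! regressor orderings.
# Subset R^2 values are computed with lm() and cached per subset.
oracle_lmg_enumeration <- function(y, X) {
  k <- ncol(X)
  r2_cache <- new.env()
  r2_of <- function(cols) {
    key <- paste(cols, collapse = ",")
    if (!is.null(r2_cache[[key]])) return(r2_cache[[key]])
    r2 <- if (length(cols) == 0) 0 else
      summary(stats::lm(y ~ X[, cols, drop = FALSE]))$r.squared
    r2_cache[[key]] <- r2
    r2
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  shares <- numeric(k)
  all_ord <- perms(seq_len(k))
  for (ord in all_ord) {
    cols <- integer(0)
    prev <- 0
    for (j in ord) {
      cols <- sort(c(cols, j))
      r2 <- r2_of(cols)
      shares[j] <- shares[j] + (r2 - prev)
      prev <- r2
    }
  }
  shares / length(all_ord)
}

# Quadratic any-overlap scan (0-based half-open intervals).
oracle_overlap_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      out <- rbind(out, data.frame(a_idx = i, b_idx = j, overlap = ov))
    }
  }
  if (is.null(out))
    data.frame(a_idx = integer(0), b_idx = integer(0), overlap = integer(0))
  else out
}

# Union of intervals by pairwise sweep until fixpoint (alive flags avoid
# index shifts while absorbing rows).
oracle_merge <- function(df) {
  chrom <- df$chrom; start <- df$start; end <- df$end
  alive <- rep(TRUE, nrow(df))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(alive)) {
      if (!alive[i]) next
      for (j in seq_along(alive)) {
        if (i == j || !alive[j]) next
        if (chrom[i] == chrom[j] && start[i] <= end[j] &&
            start[j] <= end[i]) {
          start[i] <- min(start[i], start[j])
          end[i] <- max(end[i], end[j])
          alive[j] <- FALSE
          changed <- TRUE
        }
      }
    }
  }
  out <- data.frame(chrom = chrom[alive], start = start[alive],
                    end = end[alive])
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Exact two-tailed binomial p by summing outcomes no more probable than
# the observed one.
oracle_binom_two_tailed <- function(x, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Exact two-tailed Fisher p for a 2x2 table by hypergeometric
# enumeration (point-probability rule).
oracle_fisher_two_tailed <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Quadratic S-statistic counting with explicit loops.
oracle_s_counts <- function(psi) {
  n25 <- integer(ncol(psi)); n75 <- integer(ncol(psi))
  for (j in seq_len(ncol(psi))) {
    for (i in seq_len(nrow(psi))) {
      q25 <- stats::quantile(psi[i, ], 0.25, type = 7)
      q75 <- stats::quantile(psi[i, ], 0.75, type = 7)
      if (psi[i, j] <= q25) n25[j] <- n25[j] + 1L
      if (psi[i, j] >= q75) n75[j] <- n75[j] + 1L
    }
  }
  list(n25 = n25, n75 = n75)
}

# Small standard fixture shared across tests.
small_cohort <- function(seed = 1, n_samples = 160, n_events = 400, ...) {
  cfg <- sim_config(seed = seed, n_samples = n_samples, n_events = n_events,
                    ...)
  expr <- generate_expression(cfg)
  psi <- generate_psi(cfg, expr[cfg$tf_names[1], ])
  list(cfg = cfg, expr = expr, psi = psi,
       high = stratify_by_expression(expr, cfg$tf_names[1]))
}
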
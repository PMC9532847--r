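#' Preprocess a regressor table
#'
#' Applies the preprocessing chain used before every covariance fit:
#' near-zero-variance columns are dropped, each remaining column is
#' Yeo-Johnson power-transformed (lambda estimated by maximum likelihood),
#' then centered to mean 0 and scaled to SD 1. Delegates to
#' `caret::preProcess(method = c("center", "scale", "YeoJohnson", "nzv"))`,
#' whose near-zero-variance rule (frequency ratio > 19 and unique-value
#' fraction < 10%) is the documented default.
#'
#' @param raw data.frame or matrix (samples x regressors), numeric.
#' @return numeric matrix of preprocessed regressors (possibly fewer
#'   columns).
#' @export
preprocess_regressors <- function(raw) {
  raw <- as.data.frame(raw)
  if (nrow(raw) < 3) stop("need at least 3 samples")
  if (!all(vapply(raw, is.numeric, logical(1))))
    stop("all regressor columns must be numeric")
  if (anyNA(raw)) stop("regressors contain missing values")
  pp <- caret::preProcess(raw,
                          method = c("center", "scale", "YeoJohnson", "nzv"))
  if (length(pp$method$remove) >= ncol(raw))
    stop("no informative regressors after preprocessing")
  out <- stats::predict(pp, raw)
  if (ncol(out) == 0) stop("no informative regressors after preprocessing")
  as.matrix(out)
}

#' Ordinary least-squares fit with R-squared
#'
#' Gaussian identity-link fit of a response on a regressor matrix (with
#' intercept). Rank-deficient designs are solved via the Moore-Penrose
#' pseudo-inverse with a warning.
#'
#' @param response numeric vector.
#' @param X numeric matrix (samples x regressors), rows aligned with
#'   `response`.
#' @return list with `beta` (named, no intercept), `intercept`, `r2`.
#' @export
fit_glm <- function(response, X) {
  X <- as.matrix(X)
  if (length(response) != nrow(X)) stop("response and X are misaligned")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    warning("rank-deficient design; using pseudo-inverse solution")
    sv <- svd(Xi)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% response) / sv$d[pos])
    coefs <- drop(coefs)
  } else {
    coefs <- qr.coef(qrx, response)
  }
  names(coefs) <- colnames(Xi)
  fitted <- drop(Xi %*% coefs)
  rss <- sum((response - fitted)^2)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(beta = coefs[-1], intercept = coefs[[1]], r2 = r2)
}

# R^2 of the OLS fit on a column subset (internal; intercept always in).
subset_r2 <- function(response, X, cols) {
  if (length(cols) == 0) return(0)
  fit_glm(response, X[, cols, drop = FALSE])$r2
}

#' LMG relative-importance decomposition
#'
#' Decomposes the full-model R-squared into per-regressor contributions by
#' the averaging-over-orderings (LMG) method: regressor j's share is the
#' average, over all k! orderings of the regressors, of the increase in
#' R-squared when j enters the model. Computed by the equivalent
#' subset-sum formulation over the 2^k column subsets with combinatorial
#' weights `|S|! (k - |S| - 1)! / k!`, so shares always sum to the
#' full-model R-squared.
#'
#' @param response numeric vector.
#' @param X numeric matrix (samples x regressors); at most 15 columns
#'   (exact enumeration bound).
#' @return named numeric vector of shares with attribute `r2` (full-model
#'   R-squared).
#' @export
lmg_importance <- function(response, X) {
  X <- as.matrix(X)
  k <- ncol(X)
  if (k > 15) stop("more than 15 regressors: exact LMG enumeration refused")
  if (k == 0) stop("no regressors")
  # R^2 for every subset, indexed by bitmask
  r2s <- numeric(2^k)
  for (mask in seq_len(2^k - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0)
    r2s[mask + 1] <- subset_r2(response, X, cols)
  }
  lfact <- lfactorial(0:k)
  shares <- numeric(k)
  for (j in seq_len(k)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    others <- setdiff(seq_len(k), j)
    for (smask in 0:(2^(k - 1) - 1)) {
      # expand subset mask over the other k-1 regressors
      mask <- 0L
      s <- 0L
      for (b in seq_along(others)) {
        if (bitwAnd(smask, bitwShiftL(1L, b - 1L)) != 0) {
          mask <- bitwOr(mask, bitwShiftL(1L, others[b] - 1L))
          s <- s + 1L
        }
      }
      w <- exp(lfact[s + 1] + lfact[k - s] - lfact[k + 1])
      shares[j] <- shares[j] +
        w * (r2s[bitwOr(mask, bit_j) + 1] - r2s[mask + 1])
    }
  }
  names(shares) <- colnames(X)
  attr(shares, "r2") <- r2s[2^k]
  shares
}

#' Bootstrap confidence intervals for LMG shares
#'
#' Resamples full observation vectors (rows) with replacement, recomputes
#' the LMG decomposition each time, and reports percentile (2.5/97.5)
#' confidence intervals per share. Degenerate resamples (constant response
#' or a constant regressor column) are skipped and counted; a warning is
#' issued if more than 1% are skipped.
#'
#' @param response numeric vector.
#' @param X numeric matrix (samples x regressors).
#' @param n_boot number of bootstrap iterations (>= 100; study default
#'   1,000).
#' @param seed integer seed.
#' @return object of class `relimp_result`: list with `beta` (standardized
#'   coefficients from the full fit), `shares`, `r2`, `ci` (matrix with
#'   columns lower/upper), `n_boot`, `n_skipped`.
#' @export
bootstrap_importance <- function(response, X, n_boot = 1000L, seed = 1L) {
  X <- as.matrix(X)
  if (n_boot < 100) stop("n_boot must be at least 100")
  point <- lmg_importance(response, X)
  fit <- fit_glm(response, X)
  set.seed(substream_seed(seed, "boot_relimp"))
  n <- nrow(X)
  k <- ncol(X)
  boots <- matrix(NA_real_, nrow = n_boot, ncol = k)
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yb <- response[idx]
    Xb <- X[idx, , drop = FALSE]
    if (stats::var(yb) == 0 || any(apply(Xb, 2, stats::var) == 0)) {
      skipped <- skipped + 1L
      next
    }
    boots[b, ] <- lmg_importance(yb, Xb)
  }
  if (skipped > 0.01 * n_boot)
    warning(sprintf("%d of %d bootstrap resamples were degenerate and skipped",
                    skipped, n_boot))
  ci <- t(apply(boots, 2, function(col)
    stats::quantile(col, c(0.025, 0.975), na.rm = TRUE, type = 7)))
  dimnames(ci) <- list(colnames(X), c("lower", "upper"))
  structure(list(beta = fit$beta, shares = point,
                 r2 = attr(point, "r2"), ci = ci,
                 n_boot = n_boot, n_skipped = skipped),
            class = "relimp_result")
}

#' @export
print.relimp_result <- function(x, ...) {
  cat(sprintf("Relative importance decomposition (R^2 = %.4f, %d bootstraps)\n",
              x$r2, x$n_boot))
  df <- data.frame(beta = round(x$beta, 4),
                   share = round(as.numeric(x$shares), 4),
                   lower = round(x$ci[, "lower"], 4),
                   upper = round(x$ci[, "upper"], 4))
  print(df, ...)
  invisible(x)
}

#' One-call covariance analysis
#'
#' Convenience wrapper: preprocess regressors (and optionally the
#' response with the same chain), fit, decompose, bootstrap.
#'
#' @param response numeric vector (e.g. cumulative SRG expression).
#' @param raw_regressors samples x regressors table (e.g. TF TPMs).
#' @param preprocess_response apply the same preprocessing to the response
#'   (default TRUE).
#' @param n_boot,seed passed to [bootstrap_importance()].
#' @return a `relimp_result`.
#' @export
covariance_analysis <- function(response, raw_regressors,
                                preprocess_response = TRUE,
                                n_boot = 1000L, seed = 1L) {
  X <- preprocess_regressors(raw_regressors)
  y <- response
  if (preprocess_response) {
    y <- as.numeric(preprocess_regressors(data.frame(.response = response)))
  }
  bootstrap_importance(y, X, n_boot = n_boot, seed = seed)
}
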
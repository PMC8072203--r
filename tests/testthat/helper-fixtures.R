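# Shared fixture builders and independent oracle implementations. The
# oracles deliberately take different computational routes from the package
# (explicit matrix algebra, exhaustive scans, numerical quadrature) so they
# can certify the estimators rather than mirror them.

make_harmonized <- function(bx, sx, by, sy, snp_id = sprintf("rs%03d", seq_along(bx))) {
  tibble::tibble(
    snp_id = snp_id,
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy
  )
}

# Simulate one two-sample dataset and return it pre-harmonized (no allele
# scrambling), so estimator calibration tests skip the (separately tested)
# harmonization step.
sim_harmonized <- function(J = 20, theta = 0.3, seed = 1,
                           n_exposure = 24925, n_outcome = 63926,
                           pleiotropy = list(frac = 0, mean = 0, sd = 0, balanced = TRUE)) {
  sim <- simulate_two_sample(
    J = J, K = 1, theta = theta, seed = seed,
    n_exposure = n_exposure, n_outcome = n_outcome,
    pleiotropy = pleiotropy,
    frac_swapped = 0, frac_strand = 0, frac_palindromic = 0
  )
  ex <- sim$exposures[[1]]
  out <- sim$outcome
  make_harmonized(ex$beta, ex$se, out$beta, out$se, snp_id = ex$snp_id)
}

make_gwas_tbl <- function(n = 3, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    snp_id = sprintf("rs%d", seq_len(n)),
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e7, n),
    effect_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    other_allele = NA_character_,
    eaf = round(runif(n, 0.05, 0.95), 4),
    beta = round(rnorm(n, 0, 0.1), 6),
    se = round(runif(n, 0.005, 0.02), 6),
    pvalue = signif(runif(n, 1e-12, 0.9), 4),
    n = 24925
  ) |>
    dplyr::mutate(other_allele = purrr::map_chr(
      .data$effect_allele, ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1)
    ))
}

# --- independent oracles -------------------------------------------------

# zero-intercept weighted least squares via explicit normal equations
oracle_wls_origin <- function(bx, by, sy) {
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  list(beta = beta, se = sqrt(1 / sum(w * bx^2)))
}

# with-intercept weighted regression via explicit 2x2 normal equations,
# residual scale floored at 1
oracle_wls_intercept <- function(bx, by, sy) {
  w <- 1 / sy^2
  X <- cbind(1, bx)
  XtWX <- t(X) %*% (w * X)
  coef <- solve(XtWX, t(X) %*% (w * by))
  res <- by - X %*% coef
  sigma2 <- sum(w * res^2) / (length(by) - 2)
  se <- unname(sqrt(diag(solve(XtWX))) * max(1, sqrt(sigma2)))
  list(intercept = coef[1], slope = coef[2], se_intercept = se[1], se_slope = se[2])
}

# weighted median by exhaustive scan of every interpolation segment
oracle_weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(r[1])
  if (0.5 >= cum[length(cum)]) return(r[length(r)])
  for (i in seq_len(length(r) - 1)) {
    if (cum[i] <= 0.5 && 0.5 <= cum[i + 1]) {
      return(r[i] + (r[i + 1] - r[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i]))
    }
  }
  stop("segment scan failed")
}

# Cook's distance by brute-force delete-one refit of the weighted
# no-intercept regression: sum_i (yhat_i - yhat_i^(-j))^2 w_i / (p * s^2)
oracle_cooks <- function(X, y, w) {
  X <- as.matrix(X)
  p <- ncol(X)
  fit_coef <- function(Xs, ys, ws) solve(t(Xs) %*% (ws * Xs), t(Xs) %*% (ws * ys))
  beta_full <- fit_coef(X, y, w)
  yhat <- X %*% beta_full
  s2 <- sum(w * (y - yhat)^2) / (length(y) - p)
  vapply(seq_along(y), function(j) {
    beta_j <- fit_coef(X[-j, , drop = FALSE], y[-j], w[-j])
    sum(w * (yhat - X %*% beta_j)^2) / (p * s2)
  }, numeric(1))
}

# log marginal likelihood of a 1-exposure model by trapezoidal quadrature of
# likelihood x prior over a fine theta grid (log-sum-exp for stability)
oracle_lml_quadrature <- function(x, y, sigma2, lower = -30, upper = 30,
                                  step = 5e-4) {
  theta <- seq(lower, upper, by = step)
  logf <- vapply(theta, function(th) {
    sum(stats::dnorm(y, th * x, 1, log = TRUE)) +
      stats::dnorm(th, 0, sqrt(sigma2), log = TRUE)
  }, numeric(1))
  m <- max(logf)
  m + log(sum(exp(logf - m)) * step)
}
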
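# Univariable two-sample MR estimators and the sensitivity battery.
#
# All functions consume a harmonized data frame with columns beta_exposure,
# se_exposure, beta_outcome, se_outcome (and snp_id for the per-SNP outputs):
# bx_j per SD of exposure, by_j on the log-odds scale for a binary outcome.
# Weights are first-order (outcome variance only), w_j = bx_j^2 / sy_j^2 for
# ratio-scale statistics and 1/sy_j^2 for the regression-scale fits.

harm_cols <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")

new_mr_estimate <- function(method, beta, se, n_snp, pvalue = NULL, df = NULL,
                            q = NA_real_, q_df = NA_real_, q_p = NA_real_,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_p = NA_real_, model = NA_character_) {
  if (is.null(pvalue)) {
    z <- beta / se
    pvalue <- if (is.null(df)) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df)
  }
  ci_low <- beta - stats::qnorm(0.975) * se
  ci_high <- beta + stats::qnorm(0.975) * se
  structure(
    list(
      method = method, beta = beta, se = se,
      ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
      n_snp = n_snp,
      or_ = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
      q = q, q_df = q_df, q_p = q_p,
      intercept = intercept, intercept_se = intercept_se, intercept_p = intercept_p,
      model = model
    ),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("<mr_estimate> %s (%d SNPs)\n", x$method, x$n_snp))
  cat(sprintf("  beta = %.*f (SE %.*f), OR = %.*f [%.*f, %.*f], p = %.3g\n",
              digits, x$beta, digits, x$se, digits, x$or_,
              digits, x$or_low, digits, x$or_high, x$pvalue))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.*f on %d df, p = %.3g\n",
                digits, x$q, x$q_df, x$q_p))
  }
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept = %.*f (SE %.*f), p = %.3g\n",
                digits, x$intercept, digits, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' Tidy an MR estimate into a one-row tibble
#'
#' @param x an `mr_estimate`.
#' @param ... unused.
#' @return a one-row tibble with the estimate, CI, OR scale, heterogeneity
#'   and (for Egger) intercept columns.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::as_tibble(x[c("method", "beta", "se", "ci_low", "ci_high", "pvalue",
                        "n_snp", "or_", "or_low", "or_high", "q", "q_df", "q_p",
                        "intercept", "intercept_se", "intercept_p", "model")])
}

#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp,
                 q = x$q, q_df = x$q_df, q_p = x$q_p, model = x$model)
}

#' Wald ratio for a single instrument
#'
#' The degenerate one-SNP estimator: `beta = by/bx` with first-order standard
#' error `sy/|bx|` (exposure-side uncertainty ignored), normal-theory CI and
#' two-sided p.
#'
#' @param bx,sx exposure beta and SE.
#' @param by,sy outcome beta and SE.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (bx == 0) rlang::abort("wald_ratio(): exposure beta must be nonzero")
  new_mr_estimate("Wald ratio", beta = by / bx, se = sy / abs(bx), n_snp = 1L)
}

#' Inverse-variance-weighted MR
#'
#' The IVW estimator: the slope of the weighted regression of outcome betas on
#' exposure betas through the origin (intercept constrained to zero, encoding
#' the exclusion-restriction assumption), with weights the inverse outcome
#' variances. Equivalent to the inverse-variance meta-analysis of per-SNP
#' Wald ratios.
#'
#' @param data harmonized data frame (columns `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`).
#' @param model `"multiplicative-re"` (default): the fixed-effect SE is
#'   inflated by `max(1, sqrt(Q/(J-1)))` so heterogeneity widens the CI;
#'   `"fixed"` reports the fixed-effect SE.
#' @return an `mr_estimate` including Cochran's Q against the fixed-effect
#'   estimate. With a single SNP, delegates to [wald_ratio()].
#' @export
mr_ivw <- function(data, model = c("multiplicative-re", "fixed")) {
  model <- match.arg(model)
  assert_cols(data, harm_cols, "data")
  bx <- data$beta_exposure; by <- data$beta_outcome; sy <- data$se_outcome
  J <- length(bx)
  if (J == 0) rlang::abort("mr_ivw(): no instruments")
  if (J == 1) return(wald_ratio(bx, data$se_exposure, by, sy))
  if (all(bx == 0)) rlang::abort("mr_ivw(): all exposure betas are zero")
  w <- 1 / sy^2
  s_xx <- sum(bx^2 * w)
  beta <- sum(bx * by * w) / s_xx
  se_fe <- sqrt(1 / s_xx)
  qq <- cochran_q(data, beta_ref = beta)
  se <- if (model == "multiplicative-re") se_fe * max(1, sqrt(qq$q / qq$df)) else se_fe
  new_mr_estimate(
    "IVW", beta = beta, se = se, n_snp = J,
    q = qq$q, q_df = qq$df, q_p = qq$p, model = model
  )
}

#' MR-Egger regression
#'
#' The IVW regression with the zero-intercept constraint removed: outcome
#' betas are regressed on exposure betas with a free intercept and inverse
#' outcome-variance weights. The slope is the pleiotropy-robust causal
#' estimate (under the InSIDE assumption); the intercept estimates the mean
#' directional pleiotropic effect, with large deviations from zero taken as
#' evidence of exclusion-restriction violation. Instruments are oriented so
#' all exposure betas are non-negative before fitting (the fit is not
#' orientation-invariant otherwise). Slope and intercept SEs carry a residual
#' scale factor floored at 1; p-values use t with J-2 df.
#'
#' @inheritParams mr_ivw
#' @return an `mr_estimate` with intercept fields and Q on J-2 df.
#' @export
mr_egger <- function(data) {
  assert_cols(data, harm_cols, "data")
  J <- nrow(data)
  if (J < 3) rlang::abort("mr_egger(): at least 3 instruments required")
  flip <- sign(data$beta_exposure)
  flip[flip == 0] <- 1
  bx <- data$beta_exposure * flip
  by <- data$beta_outcome * flip
  sy <- data$se_outcome
  fit <- stats::lm(by ~ bx, weights = 1 / sy^2)
  co <- stats::coef(fit)
  df <- J - 2
  qq <- sum((by - stats::fitted(fit))^2 / sy^2)
  # SEs on the unit-variance scale, inflated by the residual scale floored
  # at 1 (under-dispersion never tightens the CI)
  xtwx_inv <- chol2inv(chol(crossprod(cbind(1, bx) / sy)))
  scale <- max(1, sqrt(qq / df))
  slope <- co[["bx"]]
  slope_se <- sqrt(xtwx_inv[2, 2]) * scale
  int <- co[["(Intercept)"]]
  int_se <- sqrt(xtwx_inv[1, 1]) * scale
  new_mr_estimate(
    "MR-Egger", beta = slope, se = slope_se, n_snp = J,
    pvalue = 2 * stats::pt(-abs(slope / slope_se), df), df = df,
    q = qq, q_df = df, q_p = stats::pchisq(qq, df, lower.tail = FALSE),
    intercept = int, intercept_se = int_se,
    intercept_p = 2 * stats::pt(-abs(int / int_se), df)
  )
}

weighted_percentile <- function(r, w, prob = 0.5) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  stats::approx(cum, r, xout = prob, rule = 2, ties = "ordered")$y
}

#' Weighted-median MR
#'
#' Per-SNP Wald ratios are ordered and the estimate taken as the 50th weighted
#' percentile (inverse-variance weights, linear interpolation of the
#' cumulative weight at interval midpoints). Consistent when at least 50% of
#' the weight comes from valid instruments. The SE comes from a parametric
#' bootstrap: exposure and outcome betas are resampled from normal
#' distributions centred on the observations, the weighted median recomputed,
#' and the SD across replicates taken.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(data, n_boot = 5000, seed = NULL) {
  assert_cols(data, harm_cols, "data")
  J <- nrow(data)
  if (J < 3) rlang::abort("mr_weighted_median(): at least 3 instruments required")
  bx <- data$beta_exposure; sx <- data$se_exposure
  by <- data$beta_outcome; sy <- data$se_outcome
  est <- weighted_percentile(by / bx, bx^2 / sy^2)
  se <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      bxs <- stats::rnorm(J, bx, sx)
      bys <- stats::rnorm(J, by, sy)
      weighted_percentile(bys / bxs, bxs^2 / sy^2)
    }, numeric(1))
    stats::sd(reps)
  })
  qq <- cochran_q(data, beta_ref = est)
  new_mr_estimate("Weighted median", beta = est, se = se, n_snp = J,
                  q = qq$q, q_df = qq$df, q_p = qq$p)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (r_j - beta_ref)^2` over per-SNP ratio estimates
#' `r_j = by_j/bx_j` with first-order inverse-variance weights
#' `w_j = bx_j^2/sy_j^2`, on J-1 df; p < 0.05 indicates significant
#' heterogeneity among instruments.
#'
#' @inheritParams mr_ivw
#' @param beta_ref reference causal estimate, typically the fixed-effect IVW
#'   estimate (computed internally when omitted).
#' @return a list with `q`, `df`, `p`.
#' @export
cochran_q <- function(data, beta_ref = NULL) {
  assert_cols(data, harm_cols, "data")
  bx <- data$beta_exposure; by <- data$beta_outcome; sy <- data$se_outcome
  w <- bx^2 / sy^2
  if (is.null(beta_ref)) {
    beta_ref <- sum(bx * by / sy^2) / sum(bx^2 / sy^2)
  }
  q <- sum(w * (by / bx - beta_ref)^2)
  df <- length(bx) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW estimate J times, each time excluding one instrument,
#' to surface influential points. A SNP is flagged when its removal moves the
#' estimate's p-value across 0.05 (in either direction) or changes the sign
#' of the estimate, relative to the all-SNP fit.
#'
#' @inheritParams mr_ivw
#' @param alpha significance line used for flagging (default 0.05).
#' @return a tibble with one row per dropped SNP: `snp_id`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `flag`.
#' @export
mr_leave_one_out <- function(data, model = c("multiplicative-re", "fixed"),
                             alpha = 0.05) {
  model <- match.arg(model)
  assert_cols(data, c("snp_id", harm_cols), "data")
  full <- mr_ivw(data, model = model)
  rows <- purrr::map(seq_len(nrow(data)), function(j) {
    fit <- mr_ivw(data[-j, , drop = FALSE], model = model)
    tibble::tibble(
      snp_id = data$snp_id[j],
      beta = fit$beta, se = fit$se,
      ci_low = fit$ci_low, ci_high = fit$ci_high, pvalue = fit$pvalue,
      flag = (fit$pvalue < alpha) != (full$pvalue < alpha) |
        sign(fit$beta) != sign(full$beta)
    )
  })
  dplyr::bind_rows(rows)
}

#' Funnel-plot table
#'
#' Per-SNP Wald ratios against their precisions (1/SE of the ratio) —
#' plot-ready; asymmetry around the pooled estimate suggests directional
#' pleiotropy. No inference is performed.
#'
#' @inheritParams mr_leave_one_out
#' @return a tibble with `snp_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(data) {
  assert_cols(data, c("snp_id", harm_cols), "data")
  tibble::tibble(
    snp_id = data$snp_id,
    ratio = data$beta_outcome / data$beta_exposure,
    precision = abs(data$beta_exposure) / data$se_outcome
  )
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' @param beta log-odds causal estimate per 1 SD of exposure.
#' @param se its standard error.
#' @return a tibble with `or_`, `ci_low`, `ci_high` (95% normal-theory CI).
#' @export
to_odds_ratio <- function(beta, se) {
  z <- stats::qnorm(0.975)
  tibble::tibble(or_ = exp(beta), ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se))
}

#' Run the univariable estimator battery
#'
#' Convenience wrapper running IVW (always), MR-Egger and the weighted median
#' on one harmonized dataset and binding the tidied results.
#'
#' @inheritParams mr_ivw
#' @param methods subset of `c("ivw", "egger", "wmedian")`.
#' @param n_boot,seed passed to [mr_weighted_median()].
#' @return a tibble with one row per method.
#' @export
mr_all_methods <- function(data, methods = c("ivw", "egger", "wmedian"),
                           model = c("multiplicative-re", "fixed"),
                           n_boot = 5000, seed = NULL) {
  model <- match.arg(model)
  fits <- list()
  if ("ivw" %in% methods) fits$ivw <- mr_ivw(data, model = model)
  if ("egger" %in% methods && nrow(data) >= 3) fits$egger <- mr_egger(data)
  if ("wmedian" %in% methods && nrow(data) >= 3) {
    fits$wmedian <- mr_weighted_median(data, n_boot = n_boot, seed = seed)
  }
  dplyr::bind_rows(purrr::map(fits, tidy))
}
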
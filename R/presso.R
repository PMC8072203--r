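# MR-PRESSO: simulation-based residual-sum-of-squares framework for
# detecting (global test), removing (outlier test) and assessing the impact
# of (distortion test) horizontally pleiotropic instruments.

loo_ivw_slopes <- function(bx, by, w) {
  # fixed-effect IVW slope excluding each SNP in turn, vectorized
  s_xy <- sum(bx * by * w)
  s_xx <- sum(bx^2 * w)
  (s_xy - bx * by * w) / (s_xx - bx^2 * w)
}

presso_rss <- function(bx, by, w) {
  slopes <- loo_ivw_slopes(bx, by, w)
  res <- w * (by - slopes * bx)^2
  list(rss = sum(res), res = res)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' The observed residual sum of squares uses predictive residuals: each SNP's
#' outcome beta is compared against the fixed-effect IVW slope fitted on the
#' other J-1 SNPs, weighted by inverse outcome variance. Its null
#' distribution is built by parametric simulation — exposure and outcome
#' betas redrawn from normals centred on the observed exposure betas and the
#' leave-one-out fitted outcome means — giving the global pleiotropy p-value
#' (add-one smoothed, so `global_p >= 1/(n_sim+1)`). Per-SNP outlier p-values
#' compare each observed residual to that SNP's simulated residual
#' distribution and are flagged at the Bonferroni level `sig/J`. When the
#' global test is significant and outliers are flagged, the outlier-corrected
#' IVW estimate is reported together with a distortion test comparing the
#' raw-vs-corrected displacement against the displacement obtained by
#' removing equally many randomly chosen SNPs.
#'
#' @inheritParams mr_ivw
#' @param n_sim simulated datasets for the null distribution (default 1000).
#' @param seed RNG seed; with a fixed seed the whole result is reproducible.
#' @param sig familywise outlier alpha, Bonferroni-split across SNPs
#'   (default 0.05).
#' @param model IVW variant used for the raw and corrected estimates.
#' @return an `mr_presso` object: `rss_observed`, `global_p`, `outlier_p`
#'   (per-SNP tibble), `outliers`, `raw_estimate`, `corrected_estimate`,
#'   `distortion_p`, `distortion_pct`.
#' @export
mr_presso <- function(data, n_sim = 1000, seed = NULL, sig = 0.05,
                      model = c("multiplicative-re", "fixed")) {
  model <- match.arg(model)
  assert_cols(data, c("snp_id", harm_cols), "data")
  J <- nrow(data)
  if (J < 4) rlang::abort("mr_presso(): at least 4 instruments required")
  bx <- data$beta_exposure; sx <- data$se_exposure
  by <- data$beta_outcome; sy <- data$se_outcome
  w <- 1 / sy^2

  obs <- presso_rss(bx, by, w)
  slopes <- loo_ivw_slopes(bx, by, w)

  sim <- with_seed(seed, {
    rss_sim <- numeric(n_sim)
    res_sim <- matrix(NA_real_, n_sim, J)
    for (t in seq_len(n_sim)) {
      bxs <- stats::rnorm(J, bx, sx)
      bys <- stats::rnorm(J, slopes * bx, sy)
      r <- presso_rss(bxs, bys, w)
      rss_sim[t] <- r$rss
      res_sim[t, ] <- r$res
    }
    list(rss = rss_sim, res = res_sim)
  })

  global_p <- (1 + sum(sim$rss >= obs$rss)) / (n_sim + 1)
  outlier_p <- (1 + colSums(sweep(sim$res, 2, obs$res, `>=`))) / (n_sim + 1)
  outliers <- data$snp_id[outlier_p < sig / J]

  raw <- mr_ivw(data, model = model)
  corrected <- NULL
  distortion_p <- NA_real_
  distortion_pct <- NA_real_
  if (global_p < sig && length(outliers) > 0) {
    keep <- !(data$snp_id %in% outliers)
    if (!any(keep)) rlang::abort("mr_presso(): all SNPs flagged as outliers; corrected estimate undefined")
    corrected <- mr_ivw(data[keep, , drop = FALSE], model = model)
    distortion_pct <- 100 * (corrected$beta - raw$beta) / abs(raw$beta)
    n_out <- length(outliers)
    disp <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
      vapply(seq_len(n_sim), function(t) {
        drop <- sample.int(J, n_out)
        b <- mr_ivw(data[-drop, , drop = FALSE], model = "fixed")$beta
        100 * (b - raw$beta) / abs(raw$beta)
      }, numeric(1))
    })
    lo <- (1 + sum(disp <= distortion_pct)) / (n_sim + 1)
    hi <- (1 + sum(disp >= distortion_pct)) / (n_sim + 1)
    distortion_p <- min(1, 2 * min(lo, hi))
  }

  structure(
    list(
      rss_observed = obs$rss,
      global_p = global_p,
      outlier_p = tibble::tibble(snp_id = data$snp_id, outlier_p = outlier_p,
                                 flagged = data$snp_id %in% outliers),
      outliers = outliers,
      raw_estimate = raw,
      corrected_estimate = corrected,
      distortion_p = distortion_p,
      distortion_pct = distortion_pct,
      settings = list(n_sim = n_sim, seed = seed, sig = sig, model = model)
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<mr_presso> RSS = %.4g, global p = %.4g (%d sims)\n",
              x$rss_observed, x$global_p, x$settings$n_sim))
  if (length(x$outliers) > 0) {
    cat(sprintf("  outliers: %s\n", paste(x$outliers, collapse = ", ")))
    cat(sprintf("  distortion: %.1f%% (p = %.3g)\n", x$distortion_pct, x$distortion_p))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) {
  x$outlier_p
}

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    rss_observed = x$rss_observed,
    global_p = x$global_p,
    n_outliers = length(x$outliers),
    beta_raw = x$raw_estimate$beta,
    beta_corrected = if (is.null(x$corrected_estimate)) NA_real_ else x$corrected_estimate$beta,
    distortion_pct = x$distortion_pct,
    distortion_p = x$distortion_p
  )
}
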
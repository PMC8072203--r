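# Effective-number-of-tests correction for correlated exposures.

#' Effective number of independent tests
#'
#' Eigenvalue-based estimate of how many effectively independent tests a set
#' of K correlated phenotypes represents. The default is the Li-Ji
#' convention: `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`
#' over the eigenvalues of the correlation matrix. The Nyholt variant
#' `Meff = 1 + (K-1) (1 - var(lambda)/K)` is available behind the `method`
#' flag.
#'
#' @param corr symmetric K x K correlation matrix (unit diagonal); must be
#'   positive semidefinite to tolerance.
#' @param method `"li-ji"` (default) or `"nyholt"`.
#' @return Meff, a positive real in `[1, K]`.
#' @examples
#' effective_tests(diag(5)) # 5 independent tests
#' @export
effective_tests <- function(corr, method = c("li-ji", "nyholt")) {
  method <- match.arg(method)
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8) {
    rlang::abort("effective_tests(): corr must be a symmetric square matrix")
  }
  lambda <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -1e-8) {
    rlang::abort("effective_tests(): correlation matrix is not positive semidefinite")
  }
  # guard the floor() against eigenvalues an ulp below an integer
  lambda <- pmax(round(lambda, 10), 0)
  K <- length(lambda)
  switch(method,
    "li-ji" = sum(ifelse(lambda >= 1, 1, 0) + (lambda - floor(lambda))),
    "nyholt" = 1 + (K - 1) * (1 - stats::var(lambda) / K)
  )
}

#' Multiplicity-adjusted significance threshold
#'
#' Divides the familywise alpha by the effective number of independent tests,
#' reporting both full precision and the two-significant-figure value used
#' in summaries.
#'
#' @param alpha familywise significance level.
#' @param meff effective number of tests (from [effective_tests()]).
#' @return a one-row tibble: `alpha`, `meff`, `threshold`, `threshold_2sf`.
#' @examples
#' adjusted_threshold(0.05, 2.45) # threshold 0.0204, reported as 0.02
#' @export
adjusted_threshold <- function(alpha, meff) {
  stopifnot(alpha > 0, alpha < 1, meff >= 1)
  thr <- alpha / meff
  tibble::tibble(alpha = alpha, meff = meff,
                 threshold = thr, threshold_2sf = signif(thr, 2))
}
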
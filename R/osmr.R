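# One-sample MR on individual-level data: metabolite preprocessing,
# risk-allele orientation, two-stage least squares with a controls-only
# first stage, and the weighted instrument-strength F-statistic.

#' Construct a one-sample MR cohort object
#'
#' @param dosages N x J numeric matrix of effect-allele dosages in `[0, 2]`,
#'   with SNP column names.
#' @param exposure length-N metabolite vector (raw or preprocessed).
#' @param outcome length-N binary vector (1 = case).
#' @param sample_ids optional N labels.
#' @param iv_betas optional per-IV exposure effects (used by
#'   [orient_risk_alleles()]).
#' @return an `mr_cohort` list.
#' @export
mr_cohort <- function(dosages, exposure, outcome, sample_ids = NULL,
                      iv_betas = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  stopifnot(length(exposure) == n, length(outcome) == n)
  if (!all(outcome %in% c(0, 1))) rlang::abort("mr_cohort(): outcome must be binary 0/1")
  if (anyNA(dosages) || anyNA(exposure) || anyNA(outcome)) {
    rlang::abort("mr_cohort(): missing cells must be resolved before analysis")
  }
  if (min(dosages) < 0 || max(dosages) > 2) {
    rlang::abort("mr_cohort(): dosages must lie in [0, 2]")
  }
  if (is.null(colnames(dosages))) colnames(dosages) <- paste0("iv", seq_len(ncol(dosages)))
  sample_ids <- sample_ids %||% paste0("s", seq_len(n))
  rownames(dosages) <- sample_ids
  structure(
    list(sample_ids = sample_ids, dosages = dosages,
         exposure = as.numeric(exposure),
         outcome = as.integer(outcome), iv_betas = iv_betas),
    class = "mr_cohort"
  )
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf("<mr_cohort> %d samples (%d cases / %d controls), %d IV(s)\n",
              length(x$outcome), sum(x$outcome), sum(1 - x$outcome),
              ncol(x$dosages)))
  invisible(x)
}

#' Read a one-sample MR cohort from delimited files
#'
#' The dosage file is samples x SNPs (first column sample id) or the
#' transposed variant-major layout (first column SNP id, one column per
#' sample), auto-detected by matching the first column against the phenotype
#' table's sample ids. The phenotype file needs columns `sample_id`,
#' `exposure`, `outcome`.
#'
#' @param dosage_path,phenotype_path tab-delimited input files.
#' @return an `mr_cohort`.
#' @export
read_cohort <- function(dosage_path, phenotype_path) {
  ph <- readr::read_tsv(phenotype_path, show_col_types = FALSE, progress = FALSE)
  assert_cols(ph, c("sample_id", "exposure", "outcome"), "phenotype table")
  d <- readr::read_tsv(dosage_path, show_col_types = FALSE, progress = FALSE)
  first <- as.character(d[[1]])
  if (!any(first %in% as.character(ph$sample_id))) {
    # variant-major: rows are SNPs, columns samples
    snps <- first
    mat <- t(as.matrix(d[, -1]))
    colnames(mat) <- snps
    rownames(mat) <- names(d)[-1]
  } else {
    mat <- as.matrix(d[, -1])
    rownames(mat) <- first
  }
  common <- intersect(as.character(ph$sample_id), rownames(mat))
  if (length(common) == 0) rlang::abort("read_cohort(): no overlapping sample ids")
  ph <- ph[match(common, as.character(ph$sample_id)), ]
  mr_cohort(mat[common, , drop = FALSE], ph$exposure, ph$outcome, sample_ids = common)
}

#' Preprocess a metabolite vector for one-sample MR
#'
#' Square-root transform (to tame right skew toward normality), then
#' standardize to mean 0 and SD 1. The reverse order (standardize first) is
#' available behind the `order` flag but generally fails on real data since
#' standardized values are negative; the report records which order ran.
#'
#' @param values non-negative metabolite measurements.
#' @param order `"sqrt_first"` (default) or `"standardize_first"`.
#' @return the transformed vector, carrying attributes `center`, `scale` and
#'   `order` so the pipeline is invertible.
#' @export
preprocess_metabolite <- function(values, order = c("sqrt_first", "standardize_first")) {
  order <- match.arg(order)
  check_sqrt <- function(v, stage) {
    neg <- which(v < 0)
    if (length(neg) > 0) {
      rlang::abort(sprintf(
        "preprocess_metabolite(): negative values %s square-root transform at sample(s) %s",
        stage, paste(utils::head(neg, 10), collapse = ", ")
      ))
    }
  }
  standardize <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      rlang::abort("preprocess_metabolite(): zero variance; cannot standardize")
    }
    list(x = (v - mean(v)) / s, center = mean(v), scale = s)
  }
  if (order == "sqrt_first") {
    check_sqrt(values, "before")
    st <- standardize(sqrt(values))
  } else {
    st0 <- standardize(values)
    check_sqrt(st0$x, "entering")
    st <- list(x = sqrt(st0$x), center = st0$center, scale = st0$scale)
    st <- c(standardize(st$x), inner = st0)
  }
  structure(st$x, center = st$center, scale = st$scale, order = order)
}

#' Orient instruments to the exposure-increasing allele
#'
#' For each IV whose per-IV exposure effect is negative, the dosage is
#' reflected (`2 - dosage`) and the effect negated, so every instrument
#' counts copies of the exposure-raising allele. Idempotent.
#'
#' @param dosages N x J dosage matrix.
#' @param per_iv_betas length-J per-IV exposure effects.
#' @return list with `dosages` (flipped matrix) and `betas` (all >= 0).
#' @export
orient_risk_alleles <- function(dosages, per_iv_betas) {
  dosages <- as.matrix(dosages)
  stopifnot(ncol(dosages) == length(per_iv_betas))
  flip <- per_iv_betas < 0
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip, drop = FALSE]
    per_iv_betas[flip] <- -per_iv_betas[flip]
  }
  list(dosages = dosages, betas = per_iv_betas)
}

first_stage_fit <- function(cohort, subset = c("controls", "all")) {
  subset <- match.arg(subset)
  idx <- if (subset == "controls") which(cohort$outcome == 0) else seq_along(cohort$outcome)
  D <- cohort$dosages[idx, , drop = FALSE]
  qr_d <- qr(cbind(1, D))
  if (qr_d$rank < ncol(D) + 1) {
    dropped <- colnames(D)[qr_d$pivot[seq(qr_d$rank + 1, ncol(D) + 1)] - 1]
    rlang::abort(sprintf("first stage design is singular; collinear IV(s): %s",
                         paste(dropped, collapse = ", ")))
  }
  df <- data.frame(exposure = cohort$exposure[idx], D)
  stats::lm(exposure ~ ., data = df)
}

#' One-sample MR by two-stage least squares
#'
#' Stage 1 regresses the (preprocessed) metabolite on all oriented instrument
#' dosages, restricted by default to controls only — using cases in the first
#' stage risks selection and reverse-causation bias when both stages come
#' from the same individuals. The fitted model then predicts the
#' genetically-instrumented exposure for every sample. Stage 2 regresses
#' case/control status on that prediction (logistic by default, reported as
#' an OR per 1 SD of genetically proxied exposure; a linear-probability
#' option exists for diagnostics). The stage-2 SE is not corrected for
#' first-stage uncertainty; the result records this.
#'
#' @param cohort an `mr_cohort`.
#' @param first_stage_subset `"controls"` (default) or `"all"`.
#' @param stage2 `"logistic"` (default) or `"linear"`.
#' @return an `mr_estimate` (odds-ratio scale for logistic stage 2) with
#'   attributes `n_cases`, `n_controls`, `weighted_f` and
#'   `se_uncorrected = TRUE`.
#' @export
mr_two_stage <- function(cohort, first_stage_subset = c("controls", "all"),
                         stage2 = c("logistic", "linear")) {
  stopifnot(inherits(cohort, "mr_cohort"))
  first_stage_subset <- match.arg(first_stage_subset)
  stage2 <- match.arg(stage2)
  s1 <- first_stage_fit(cohort, first_stage_subset)
  pred <- stats::predict(s1, newdata = data.frame(cohort$dosages))
  if (stage2 == "logistic") {
    s2 <- stats::glm(cohort$outcome ~ pred, family = stats::binomial())
  } else {
    s2 <- stats::lm(cohort$outcome ~ pred)
  }
  co <- summary(s2)$coefficients
  est <- new_mr_estimate(
    sprintf("2SLS (%s first stage, %s stage 2)", first_stage_subset, stage2),
    beta = co["pred", 1], se = co["pred", 2],
    n_snp = ncol(cohort$dosages),
    pvalue = co["pred", 4]
  )
  attr(est, "n_cases") <- sum(cohort$outcome)
  attr(est, "n_controls") <- sum(1 - cohort$outcome)
  attr(est, "weighted_f") <- weighted_f(cohort, subset = first_stage_subset)
  attr(est, "se_uncorrected") <- TRUE
  est
}

#' Weighted instrument-strength F-statistic
#'
#' Each IV's strength is measured by the F-statistic of the univariate
#' exposure-on-dosage regression in the first-stage subset; the combined F
#' is the mean of the per-IV Fs weighted by per-IV variance explained
#' (`v_j = R_j^2`). Combined F below 10 is flagged as evidence of
#' weak-instrument bias.
#'
#' @param cohort an `mr_cohort`.
#' @param subset observations used, as in [mr_two_stage()].
#' @return a list: `f` (combined weighted F), `weak` (logical, `f < 10`) and
#'   `per_iv` tibble (`iv`, `f`, `r2`).
#' @export
weighted_f <- function(cohort, subset = c("controls", "all")) {
  subset <- match.arg(subset)
  idx <- if (subset == "controls") which(cohort$outcome == 0) else seq_along(cohort$outcome)
  x <- cohort$exposure[idx]
  per <- purrr::map_dfr(seq_len(ncol(cohort$dosages)), function(j) {
    d <- cohort$dosages[idx, j]
    sm <- summary(stats::lm(x ~ d))
    tibble::tibble(iv = colnames(cohort$dosages)[j],
                   f = unname(sm$fstatistic["value"]),
                   r2 = sm$r.squared)
  })
  f <- sum(per$r2 * per$f) / sum(per$r2)
  list(f = f, weak = f < 10, per_iv = per)
}
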
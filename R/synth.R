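# Synthetic two-sample GWAS, genetic-correlation and individual-level cohort
# generators with known ground truth. These emulate the data geometry the
# pipeline was built for: NMR metabolite GWAS (~25k individuals, per-SD
# betas), a case/control disease GWAS from a much larger non-overlapping
# sample (log-odds betas), a handful of correlated lipoprotein-subfraction
# exposures sharing an instrument set, and a small clinical cohort with
# weak-ish instruments. Defaults are chosen once to mirror those conditions.

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws J independent instruments (no LD — instruments are post-clumping by
#' construction). True per-SNP exposure effects for K exposures are
#' multivariate normal across exposures with the given latent correlation, so
#' correlated exposures share instrument signal. The outcome's true per-SNP
#' effect is `sum_k theta_k bx_jk + alpha_j`, where `alpha_j` is a
#' horizontally pleiotropic direct effect carried by a configurable fraction
#' of invalid instruments (mean-zero when balanced). Observed betas add
#' sampling noise with the standard GWAS approximation
#' `se = 1/sqrt(2 maf (1-maf) n)` using each sample's size, so the two
#' samples are non-overlapping by construction. Allele pairs, frequencies and
#' a configurable fraction of allele-swapped / strand-flipped outcome rows
#' are emitted so harmonization is genuinely exercised.
#'
#' @param J instrument count (default 21, a typical curated mQTL set).
#' @param K exposure count (default 1).
#' @param n_exposure exposure GWAS sample size (default 24925).
#' @param n_outcome outcome GWAS sample size (default 63926).
#' @param theta length-K true causal effects, log-odds per SD (default 0).
#' @param exposure_corr K x K latent correlation of true instrument effects
#'   across exposures (default identity).
#' @param pleiotropy list: `frac` invalid fraction, `mean`/`sd` of the direct
#'   effects, `balanced` (TRUE forces mean 0).
#' @param effect_sd SD of true instrument-exposure effects (per SD of
#'   exposure; default 0.1, giving strong instruments at the default n).
#' @param maf_range allele-frequency interval to draw from.
#' @param frac_swapped fraction of outcome rows emitted with effect/other
#'   allele labels swapped (and beta/eaf adjusted accordingly).
#' @param frac_strand fraction of outcome rows emitted on the reverse strand.
#' @param frac_palindromic fraction of SNPs given palindromic (A/T or C/G)
#'   allele pairs.
#' @param outcome_eaf_missing emit the outcome table without allele
#'   frequencies (default FALSE).
#' @param seed RNG seed (required: the generator must be reproducible).
#' @return an `mr_sim` list: `exposures` (named list of canonical summary
#'   tibbles), `outcome` (canonical tibble), `truth` (list with `bx`, `alpha`,
#'   `theta`, `maf`, `valid`, and the emission flags per SNP).
#' @export
simulate_two_sample <- function(J = 21, K = 1,
                                n_exposure = 24925, n_outcome = 63926,
                                theta = rep(0, K),
                                exposure_corr = NULL,
                                pleiotropy = list(frac = 0, mean = 0, sd = 0, balanced = TRUE),
                                effect_sd = 0.1,
                                maf_range = c(0.05, 0.5),
                                frac_swapped = 0.2, frac_strand = 0.1,
                                frac_palindromic = 0.1,
                                outcome_eaf_missing = FALSE,
                                seed) {
  if (missing(seed)) rlang::abort("simulate_two_sample(): seed is mandatory")
  if (length(theta) != K) rlang::abort("simulate_two_sample(): theta must have length K")
  exposure_corr <- exposure_corr %||% diag(K)
  if (!all(dim(exposure_corr) == c(K, K))) {
    rlang::abort("simulate_two_sample(): exposure_corr must be K x K")
  }
  pl <- utils::modifyList(list(frac = 0, mean = 0, sd = 0, balanced = TRUE), pleiotropy)
  if (pl$frac < 0 || pl$frac > 1) rlang::abort("pleiotropy$frac must be in [0, 1]")

  with_seed(seed, {
    maf <- stats::runif(J, maf_range[1], maf_range[2])
    L <- chol(exposure_corr + diag(1e-10, K))
    bx_true <- matrix(stats::rnorm(J * K), J, K) %*% L * effect_sd
    # emit each variant oriented to the allele that raises the primary
    # exposure (curated mQTL instruments follow this convention); directional
    # pleiotropy is then directional on that same orientation
    flip_orient <- bx_true[, 1] < 0
    bx_true[flip_orient, ] <- -bx_true[flip_orient, , drop = FALSE]
    n_invalid <- round(pl$frac * J)
    valid <- rep(TRUE, J)
    alpha <- rep(0, J)
    if (n_invalid > 0) {
      inv <- sample.int(J, n_invalid)
      valid[inv] <- FALSE
      mu <- if (isTRUE(pl$balanced)) 0 else pl$mean
      alpha[inv] <- stats::rnorm(n_invalid, mu, pl$sd)
    }
    by_true <- as.numeric(bx_true %*% theta) + alpha
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_outcome)

    pal <- stats::runif(J) < frac_palindromic
    pairs_np <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                     c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pairs_p <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    alleles <- purrr::map(seq_len(J), function(j) {
      if (pal[j]) pairs_p[[sample.int(4, 1)]] else pairs_np[[sample.int(8, 1)]]
    })
    ea <- purrr::map_chr(alleles, 1)
    oa <- purrr::map_chr(alleles, 2)
    snp_id <- sprintf("rs%06d", seq_len(J))
    chrom <- as.character(sample.int(22, J, replace = TRUE))
    pos <- sample.int(5e7, J)

    exposures <- purrr::map(seq_len(K), function(k) {
      bhat <- stats::rnorm(J, bx_true[, k], se_x)
      tibble::tibble(
        snp_id = snp_id, chrom = chrom, pos = pos,
        effect_allele = ea, other_allele = oa, eaf = maf,
        beta = bhat, se = se_x,
        pvalue = 2 * stats::pnorm(-abs(bhat / se_x)),
        n = n_exposure
      )
    })
    names(exposures) <- paste0("exposure", seq_len(K))

    by_hat <- stats::rnorm(J, by_true, se_y)
    swap <- stats::runif(J) < frac_swapped
    strand <- stats::runif(J) < frac_strand
    ea_o <- ea; oa_o <- oa; beta_o <- by_hat; eaf_o <- maf
    ea_o[swap] <- oa[swap]; oa_o[swap] <- ea[swap]
    beta_o[swap] <- -beta_o[swap]; eaf_o[swap] <- 1 - eaf_o[swap]
    # strand flip relabels both alleles by their complements; for
    # palindromic SNPs that is indistinguishable from a swap, so the
    # emitted beta/eaf must flip there as well
    flip_pal <- strand & pal
    beta_o[flip_pal] <- -beta_o[flip_pal]; eaf_o[flip_pal] <- 1 - eaf_o[flip_pal]
    ea_o[strand] <- complement_alleles(ea_o[strand])
    oa_o[strand] <- complement_alleles(oa_o[strand])
    outcome <- tibble::tibble(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ea_o, other_allele = oa_o,
      eaf = if (outcome_eaf_missing) NA_real_ else eaf_o,
      beta = beta_o, se = se_y,
      pvalue = 2 * stats::pnorm(-abs(beta_o / se_y)),
      n = n_outcome
    )
    structure(
      list(exposures = exposures, outcome = outcome,
           truth = list(bx = bx_true, alpha = alpha, theta = theta, maf = maf,
                        valid = valid, swapped = swap, strand_flipped = strand,
                        palindromic = pal, by_true = by_true),
           seed = seed),
      class = "mr_sim"
    )
  })
}

#' Simulate an individual-level cohort for one-sample MR
#'
#' Hardy-Weinberg dosages, exposure built additively from the instruments
#' plus normal noise (total variance 1), and a binary outcome from a logistic
#' model with log-odds `theta` per unit exposure; the intercept is tuned
#' numerically so the expected case fraction matches `case_fraction`.
#'
#' @param n cohort size (default 894).
#' @param J instrument count (default 10).
#' @param per_iv_effects length-J per-allele exposure effects; by default
#'   each IV explains `h2_per_iv` of exposure variance.
#' @param h2_per_iv per-IV variance explained used to build default effects
#'   (default 0.02, giving deliberately weak-ish instruments as in small
#'   clinical cohorts).
#' @param theta true causal log-odds per SD of exposure (default 0).
#' @param case_fraction expected case fraction (default 515/894).
#' @param maf_range allele-frequency interval.
#' @param seed RNG seed (mandatory).
#' @return an `mr_cohort` with an extra `truth` attribute (theta, effects,
#'   maf, intercept).
#' @export
simulate_cohort <- function(n = 894, J = 10, per_iv_effects = NULL,
                            h2_per_iv = 0.02, theta = 0,
                            case_fraction = 515 / 894,
                            maf_range = c(0.1, 0.5), seed) {
  if (missing(seed)) rlang::abort("simulate_cohort(): seed is mandatory")
  with_seed(seed, {
    maf <- stats::runif(J, maf_range[1], maf_range[2])
    effects <- per_iv_effects %||% sqrt(h2_per_iv / (2 * maf * (1 - maf)))
    h2 <- sum(effects^2 * 2 * maf * (1 - maf))
    if (h2 >= 1) rlang::abort("simulate_cohort(): instrument effects explain >= 100% of exposure variance")
    D <- vapply(maf, function(p) stats::rbinom(n, 2, p), numeric(n))
    colnames(D) <- sprintf("iv%02d", seq_len(J))
    genetic <- as.numeric(D %*% effects)
    exposure <- genetic + stats::rnorm(n, 0, sqrt(1 - h2))
    exposure <- exposure - mean(exposure)
    intercept <- stats::uniroot(
      function(c0) mean(stats::plogis(c0 + theta * exposure)) - case_fraction,
      interval = c(-20, 20)
    )$root
    outcome <- stats::rbinom(n, 1, stats::plogis(intercept + theta * exposure))
    ch <- mr_cohort(D, exposure, outcome, iv_betas = effects)
    attr(ch, "truth") <- list(theta = theta, effects = effects, maf = maf,
                              intercept = intercept, h2 = h2)
    ch
  })
}

#' Simulate a block-structured genetic-correlation matrix
#'
#' Builds a factor-model correlation: exposures within a block load
#' `sqrt(within_block_rg)` on a shared factor, giving within-block
#' correlation `within_block_rg` and zero between blocks, plus optional
#' small random loadings. Positive semidefinite by construction
#' (`L L' + diag`). Emulates NMR metabolomics panels where lipoprotein
#' subfraction clusters are near-duplicated genetically (within-block rg
#' approaching 1).
#'
#' @param K number of exposures.
#' @param blocks number of independent blocks (exposures split as evenly as
#'   possible).
#' @param within_block_rg correlation within a block, in `[0, 1]`.
#' @param noise_sd SD of extra random factor loadings (default 0 = exact
#'   block structure).
#' @param seed RNG seed (mandatory when `noise_sd > 0`).
#' @return a K x K correlation matrix with exposure-id dimnames.
#' @export
simulate_rg <- function(K, blocks = K, within_block_rg = 0.9, noise_sd = 0,
                        seed = NULL) {
  stopifnot(K >= 1, blocks >= 1, blocks <= K,
            within_block_rg >= 0, within_block_rg <= 1)
  if (noise_sd > 0 && is.null(seed)) {
    rlang::abort("simulate_rg(): seed is mandatory when noise_sd > 0")
  }
  block_of <- sort(rep_len(seq_len(blocks), K))
  L <- matrix(0, K, blocks)
  L[cbind(seq_len(K), block_of)] <- sqrt(within_block_rg)
  if (noise_sd > 0) {
    L <- with_seed(seed, cbind(L, matrix(stats::rnorm(K * 2, 0, noise_sd), K, 2)))
  }
  # PSD guarantee: A = L L' + diag(1 - rowSums(L^2)); keep loadings inside
  # the unit ball so the unique variances stay non-negative
  r2 <- rowSums(L^2)
  if (max(r2) > 1) L <- L / sqrt(max(r2))
  A <- tcrossprod(L)
  diag(A) <- 1  # unique variance absorbs the remainder: A = LL' + (1 - rowSums(L^2)) I
  d <- sqrt(diag(A))
  rg <- A / tcrossprod(d)
  ids <- paste0("exposure", seq_len(K))
  dimnames(rg) <- list(ids, ids)
  rg
}
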
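sim_multi <- function(J = 21, K = 9, causal = 1, theta_val = 0.3, seed = 1,
                      blocks = 3, within = 0.9) {
  corr <- simulate_rg(K, blocks = blocks, within_block_rg = within)
  theta <- rep(0, K)
  theta[causal] <- theta_val
  sim <- simulate_two_sample(J = J, K = K, theta = theta, exposure_corr = corr,
                             seed = seed, frac_swapped = 0, frac_strand = 0,
                             frac_palindromic = 0)
  harmonize_multi(sim$exposures, sim$outcome)
}

test_that("genetic-correlation pruning keeps one exposure per tight block", {
  rg <- simulate_rg(4, blocks = 4)
  pr <- setNames(1:4, rownames(rg))
  expect_equal(prune_by_rg(rg, priority = pr), rownames(rg))

  rg2 <- matrix(c(1, 0.99, 0.99, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(prune_by_rg(rg2, priority = c(a = 3, b = 5)), "b")
  # ties break toward the lexicographically smaller id
  expect_equal(prune_by_rg(rg2, priority = c(a = 3, b = 3)), "a")

  rg3 <- simulate_rg(9, blocks = 3, within_block_rg = 0.97)
  kept <- prune_by_rg(rg3, priority = setNames(9:1, rownames(rg3)))
  expect_equal(length(kept), 3)
  sub <- rg3[kept, kept]
  diag(sub) <- 0
  expect_true(all(sub <= 0.95))
})

test_that("log marginal likelihood matches the closed-form null and quadrature", {
  hm <- sim_multi(J = 6, K = 3, seed = 11, blocks = 3)
  y <- hm$beta_outcome / hm$se_outcome
  expect_equal(log_marginal_likelihood(integer(0), hm),
               sum(dnorm(y, 0, 1, log = TRUE)))

  # 1-exposure, 3-SNP toy against numerical integration of likelihood x prior
  hm3 <- sim_multi(J = 5, K = 3, seed = 13, blocks = 3)
  small <- drop_snps(hm3, character(0))
  d_y <- small$beta_outcome / small$se_outcome
  x_raw <- small$beta_exposure[, 1] / small$se_outcome
  x_std <- x_raw / sqrt(sum(x_raw^2))
  expect_equal(log_marginal_likelihood(1, small, sigma2 = 0.25),
               oracle_lml_quadrature(x_std, d_y, 0.25),
               tolerance = 1e-4)

  # sigma2 -> 0: any model collapses to the null
  expect_equal(log_marginal_likelihood(c(1, 2), hm, sigma2 = 1e-12),
               log_marginal_likelihood(integer(0), hm),
               tolerance = 1e-4)
})

test_that("exhaustive posteriors normalize exactly and the prior behaves", {
  hm <- sim_multi(J = 10, K = 4, seed = 17, blocks = 4)
  res <- mr_bma(hm)
  expect_equal(sum(res$models$pp), 1, tolerance = 1e-12)
  expect_equal(nrow(res$models), 2^4)
  # MIP is the sum of pp over models containing the exposure
  for (k in hm$exposure_ids) {
    contains <- vapply(strsplit(res$models$model, "+", fixed = TRUE),
                       function(s) k %in% s, logical(1))
    expect_equal(res$exposures$mip[res$exposures$exposure_id == k],
                 sum(res$models$pp[contains]), tolerance = 1e-12)
  }

  # prior_p = 0.5 makes pp proportional to the marginal likelihood alone
  hm3 <- sim_multi(J = 8, K = 3, seed = 19, blocks = 3)
  res5 <- mr_bma(hm3, prior_p = 0.5)
  lml <- vapply(strsplit(res5$models$model, "+", fixed = TRUE), function(s) {
    s <- setdiff(s, "(null)")
    log_marginal_likelihood(s, hm3)
  }, numeric(1))
  expect_equal(res5$models$pp, exp(lml - max(lml)) / sum(exp(lml - max(lml))),
               tolerance = 1e-10)
})

test_that("model averaging shrinks, respects labels and is deterministic", {
  hm <- sim_multi(J = 12, K = 3, seed = 23, blocks = 3)
  res <- mr_bma(hm)
  # |MACE| never exceeds the largest conditional estimate (averaging with 0)
  for (k in hm$exposure_ids) {
    cond <- vapply(res$models$estimates, function(e) {
      if (k %in% names(e)) abs(e[[k]]) else 0
    }, numeric(1))
    expect_lte(abs(res$exposures$mace[res$exposures$exposure_id == k]),
               max(cond) + 1e-15)
  }

  # permuting exposure columns permutes the results identically
  perm <- hm
  pidx <- c(3, 1, 2)
  perm$beta_exposure <- hm$beta_exposure[, pidx]
  perm$se_exposure <- hm$se_exposure[, pidx]
  perm$exposure_ids <- hm$exposure_ids[pidx]
  res_p <- mr_bma(perm)
  expect_equal(dplyr::arrange(res_p$exposures, .data$exposure_id),
               dplyr::arrange(res$exposures, .data$exposure_id),
               tolerance = 1e-12)

  expect_identical(mr_bma(hm)$exposures, res$exposures)
})

test_that("a single causal exposure among correlated nulls ranks first", {
  hm <- sim_multi(J = 21, K = 9, causal = 1, seed = 29, blocks = 3, within = 0.9)
  res <- mr_bma(hm)
  expect_equal(res$exposures$exposure_id[1], "exposure1")
  expect_gt(res$exposures$mace[res$exposures$exposure_id == "exposure1"], 0)
})

test_that("shotgun search reproduces exhaustive inclusion probabilities", {
  hm <- sim_multi(J = 21, K = 9, causal = 1, seed = 31, blocks = 3)
  ex <- mr_bma(hm, mode = "exhaustive")
  sg <- mr_bma(hm, mode = "shotgun", z = 10000, seed = 5)
  cmp <- dplyr::inner_join(ex$exposures, sg$exposures, by = "exposure_id")
  expect_lt(max(abs(cmp$mip.x - cmp$mip.y)), 0.02)
  # fixed seed: bit-identical reruns
  sg2 <- mr_bma(hm, mode = "shotgun", z = 10000, seed = 5)
  expect_identical(sg$exposures, sg2$exposures)
})

test_that("diagnostics match the delete-one-refit Cook's oracle and flag correctly", {
  # perfect fit: all q and cd are zero
  set.seed(43)
  bx <- matrix(runif(16, 0.05, 0.3), 8, 2)
  theta <- c(0.3, -0.2)
  hm <- structure(list(
    snp_id = sprintf("rs%d", 1:8), eaf = rep(0.3, 8),
    beta_exposure = bx, se_exposure = bx * 0 + 0.01,
    beta_outcome = as.numeric(bx %*% theta), se_outcome = rep(0.05, 8),
    exposure_ids = c("e1", "e2"), drops = tibble::tibble()
  ), class = "mr_harmonized_multi")
  di <- model_diagnostics(hm, c("e1", "e2"))
  expect_equal(max(di$q), 0, tolerance = 1e-24)
  expect_equal(max(di$cd), 0, tolerance = 1e-18)

  # noisy 8-SNP fixture against the brute-force refit definition
  hm2 <- sim_multi(J = 8, K = 3, seed = 37, blocks = 3)
  di2 <- model_diagnostics(hm2, c(1, 2))
  cd_oracle <- oracle_cooks(hm2$beta_exposure[, 1:2], hm2$beta_outcome,
                            1 / hm2$se_outcome^2)
  expect_equal(di2$cd, cd_oracle, tolerance = 1e-10)
  expect_equal(attr(di2, "cd_max"), 4 / 8)
})

test_that("re-running without SNPs behaves and guards identifiability", {
  hm <- sim_multi(J = 12, K = 3, seed = 41, blocks = 3)
  base <- mr_bma(hm)
  same <- rerun_without(hm, character(0), before = base)
  expect_equal(same$exposures, base$exposures, tolerance = 1e-12)
  expect_true(!is.null(attr(same, "comparison")))
  expect_error(rerun_without(hm, hm$snp_id[1:8]), "unidentifiable")

  # dropping the most influential SNP moves MIPs more than dropping a benign one
  di <- model_diagnostics(hm, 1)
  worst <- hm$snp_id[which.max(di$cd)]
  benign <- hm$snp_id[which.min(di$cd)]
  shift <- function(r) max(abs(dplyr::arrange(r$exposures, .data$exposure_id)$mip -
                                 dplyr::arrange(base$exposures, .data$exposure_id)$mip))
  expect_gte(shift(rerun_without(hm, worst)), shift(rerun_without(hm, benign)))
})
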
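exp_row <- function(snp = "rs1", ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                    se = 0.01, p = 1e-9) {
  tibble::tibble(snp_id = snp, chrom = "1", pos = 1000L,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se, pvalue = p, n = 1000)
}

test_that("allele alignment keeps, sign-flips, strand-flips and drops correctly", {
  ex <- exp_row()
  same <- exp_row(beta = 0.2, se = 0.05)
  h <- suppressMessages(harmonize_pair(ex, same))
  expect_equal(h$beta_outcome, 0.2)
  expect_equal(h$action, "kept")

  swapped <- exp_row(ea = "G", oa = "A", beta = 0.2, eaf = 0.3)
  h <- suppressMessages(harmonize_pair(ex, swapped))
  expect_equal(h$beta_outcome, -0.2)
  expect_equal(h$eaf_outcome, 0.7)
  expect_equal(h$action, "sign-flipped")

  # reverse strand: A/G coded as T/C
  strand <- exp_row(ea = "T", oa = "C", beta = 0.2)
  h <- suppressMessages(harmonize_pair(ex, strand))
  expect_equal(h$beta_outcome, 0.2)
  expect_equal(h$action, "strand-flipped")

  # reverse strand and swapped: A/G coded as C/T
  both <- exp_row(ea = "C", oa = "T", beta = 0.2)
  h <- suppressMessages(harmonize_pair(ex, both))
  expect_equal(h$beta_outcome, -0.2)

  # irreconcilable allele sets are dropped with a tag
  bad <- exp_row(ea = "A", oa = "C")
  h <- suppressWarnings(suppressMessages(harmonize_pair(ex, bad)))
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "drops")$action, "dropped-incompatible")
})

test_that("palindromic SNPs follow the configured mode", {
  pal_ex <- exp_row(ea = "A", oa = "T", eaf = 0.45)
  pal_out <- exp_row(ea = "A", oa = "T", eaf = 0.45, beta = 0.2)

  # primary convention: assume forward strand, keep as-is
  h <- suppressMessages(harmonize_pair(pal_ex, pal_out, "assume-forward"))
  expect_equal(h$beta_outcome, 0.2)
  expect_equal(h$action, "kept")

  # sensitivity: MAF 0.45 > 0.40 is non-inferable, dropped
  h <- suppressMessages(harmonize_pair(pal_ex, pal_out, "drop-noninferable"))
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "drops")$action, "dropped-palindromic")

  # inferable palindrome oriented by frequency agreement
  ex2 <- exp_row(ea = "A", oa = "T", eaf = 0.2)
  agree <- exp_row(ea = "A", oa = "T", eaf = 0.25, beta = 0.2)
  h <- suppressMessages(harmonize_pair(ex2, agree, "drop-noninferable"))
  expect_equal(h$beta_outcome, 0.2)
  disagree <- exp_row(ea = "A", oa = "T", eaf = 0.8, beta = 0.2)
  h <- suppressMessages(harmonize_pair(ex2, disagree, "drop-noninferable"))
  expect_equal(h$beta_outcome, -0.2)

  # missing outcome frequency: exposure MAF decides inferability
  no_eaf <- exp_row(ea = "A", oa = "T", eaf = NA_real_, beta = 0.2)
  h <- suppressMessages(harmonize_pair(pal_ex, no_eaf, "drop-noninferable"))
  expect_equal(nrow(h), 0)
  h <- suppressMessages(harmonize_pair(ex2, no_eaf, "drop-noninferable"))
  expect_equal(h$beta_outcome, 0.2)
})

test_that("harmonization is an involution and conserves rows with an audit", {
  sim <- simulate_two_sample(J = 30, K = 1, theta = 0.2, seed = 21,
                             frac_swapped = 0.4, frac_strand = 0.3,
                             frac_palindromic = 0.2)
  ex <- sim$exposures[[1]]
  h1 <- suppressMessages(harmonize_pair(ex, sim$outcome))
  expect_equal(nrow(h1) + nrow(attr(h1, "drops")), nrow(ex))

  # harmonization undoes the generator's scrambling: aligned outcome betas
  # equal the truth-scale draws
  truth_idx <- match(h1$snp_id, ex$snp_id)
  expect_true(all(abs(h1$beta_exposure - ex$beta[truth_idx]) < 1e-12))

  # re-harmonizing the aligned dataset changes nothing
  out2 <- tibble::tibble(
    snp_id = h1$snp_id, chrom = "1", pos = 1L,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_outcome, beta = h1$beta_outcome, se = h1$se_outcome,
    pvalue = 0.5, n = 1000
  )
  ex2 <- ex[truth_idx, ]
  h2 <- suppressMessages(harmonize_pair(ex2, out2))
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)

  # sign coherence: swapping the outcome's allele roles and negating beta
  # yields the identical harmonized row
  out3 <- dplyr::mutate(out2,
    tmp = .data$effect_allele, effect_allele = .data$other_allele,
    other_allele = .data$tmp, beta = -.data$beta, eaf = 1 - .data$eaf
  ) |> dplyr::select(-"tmp")
  h3 <- suppressMessages(harmonize_pair(ex2, out3))
  expect_equal(h3$beta_outcome, h2$beta_outcome)
})

test_that("multi-exposure harmonization builds a complete matrix with proxies", {
  sim <- simulate_two_sample(J = 10, K = 2, theta = c(0.2, 0), seed = 31,
                             frac_swapped = 0, frac_strand = 0, frac_palindromic = 0)
  hm <- harmonize_multi(sim$exposures, sim$outcome)
  expect_equal(dim(hm$beta_exposure), c(10L, 2L))
  expect_false(anyNA(hm$beta_exposure))

  # a SNP absent from exposure 2 without a proxy is dropped ...
  ex2_short <- sim$exposures[[2]][-1, ]
  hm2 <- harmonize_multi(list(a = sim$exposures[[1]], b = ex2_short), sim$outcome)
  expect_equal(length(hm2$snp_id), 9L)
  expect_equal(hm2$drops$action, "dropped-unresolved-exposure")

  # ... but survives via a proxy substitution, matching hand assembly
  miss <- sim$exposures[[1]]$snp_id[1]
  proxy <- sim$exposures[[2]]$snp_id[5]
  hm3 <- harmonize_multi(list(a = sim$exposures[[1]], b = ex2_short), sim$outcome,
                         proxy_table = tibble::tibble(snp_id = miss, proxy_id = proxy))
  expect_equal(length(hm3$snp_id), 10L)
  expect_equal(hm3$beta_exposure[miss, "b"],
               sim$exposures[[2]]$beta[sim$exposures[[2]]$snp_id == proxy])

  # identifiability guard: J < K + 2 aborts
  tiny <- purrr::map(sim$exposures, ~ .x[1:3, ])
  expect_error(harmonize_multi(tiny, sim$outcome), "identifiability")
})
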
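test_that("Wald ratio matches first-order delta-method algebra", {
  w <- wald_ratio(0.5, 0.02, 0.25, 0.1)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)

  null <- wald_ratio(0.5, 0.02, 0, 0.1)
  expect_equal(null$beta, 0)
  expect_equal(null$pvalue, 1)

  expect_error(wald_ratio(0, 0.02, 0.1, 0.1), "nonzero")

  set.seed(13)
  for (i in 1:5) {
    bx <- rnorm(1, 0.2, 0.1); by <- rnorm(1); sy <- runif(1, 0.01, 0.2)
    w <- wald_ratio(bx, 0.01, by, sy)
    # delta method: Var(by/bx) with bx fixed = sy^2/bx^2
    expect_equal(w$se, sqrt(sy^2 / bx^2))
    expect_equal(w$beta, by / bx)
  }
})

test_that("IVW equals the zero-intercept weighted least-squares oracle", {
  two <- make_harmonized(c(0.2, 0.4), c(0.01, 0.01), c(0.1, 0.2), c(0.02, 0.03))
  fit <- mr_ivw(two)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$q, 0)

  one <- make_harmonized(0.2, 0.01, 0.1, 0.02)
  expect_equal(mr_ivw(one)$beta, wald_ratio(0.2, 0.01, 0.1, 0.02)$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(0.2, 0.01, 0.1, 0.02)$se)

  h <- sim_harmonized(J = 10, theta = 0.25, seed = 41)
  fit <- mr_ivw(h, model = "fixed")
  oracle <- oracle_wls_origin(h$beta_exposure, h$beta_outcome, h$se_outcome)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(fit$se, oracle$se, tolerance = 1e-10)

  # multiplicative random effects never undercuts the fixed-effect SE
  expect_gte(mr_ivw(h)$se, fit$se)
})

test_that("IVW is invariant to SNP order and joint sign flips, and scale-equivariant", {
  h <- sim_harmonized(J = 12, theta = 0.2, seed = 43)
  fit <- mr_ivw(h)
  expect_equal(mr_ivw(h[sample(12), ])$beta, fit$beta)
  flipped <- h
  flipped$beta_exposure[3] <- -flipped$beta_exposure[3]
  flipped$beta_outcome[3] <- -flipped$beta_outcome[3]
  expect_equal(mr_ivw(flipped)$beta, fit$beta)

  for (est in list(mr_ivw, mr_egger,
                   function(d) mr_weighted_median(d, n_boot = 200, seed = 7))) {
    a <- est(h)
    scaled <- dplyr::mutate(h, beta_outcome = 3 * .data$beta_outcome,
                            se_outcome = 3 * .data$se_outcome)
    b <- est(scaled)
    expect_equal(b$beta, 3 * a$beta, tolerance = 1e-8)
    expect_equal(b$se, 3 * a$se, tolerance = 1e-8)
  }
})

test_that("Egger recovers an exact line and matches the weighted-regression oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  exact <- make_harmonized(bx, rep(0.01, 4), 0.1 + 0.4 * bx, rep(0.05, 4))
  fit <- mr_egger(exact)
  expect_equal(fit$beta, 0.4)
  expect_equal(fit$intercept, 0.1)
  expect_equal(fit$q, 0, tolerance = 1e-20)

  h <- sim_harmonized(J = 12, theta = 0.2, seed = 47,
                      pleiotropy = list(frac = 0.5, mean = 0.05, sd = 0.02, balanced = FALSE))
  fit <- mr_egger(h)
  # orient first, as the estimator does
  s <- sign(h$beta_exposure)
  o <- oracle_wls_intercept(h$beta_exposure * s, h$beta_outcome * s, h$se_outcome)
  expect_equal(fit$beta, o$slope, tolerance = 1e-10)
  expect_equal(fit$se, o$se_slope, tolerance = 1e-10)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fit$intercept_se, o$se_intercept, tolerance = 1e-10)

  # negating one SNP jointly does not move the fit
  neg <- h
  neg$beta_exposure[5] <- -neg$beta_exposure[5]
  neg$beta_outcome[5] <- -neg$beta_outcome[5]
  expect_equal(mr_egger(neg)$beta, fit$beta)
  expect_equal(mr_egger(neg)$intercept, fit$intercept)
})

test_that("weighted median interpolates correctly and matches the segment-scan oracle", {
  const <- make_harmonized(c(0.1, 0.2, 0.4), rep(0.01, 3),
                           c(0.05, 0.1, 0.2), rep(0.03, 3))
  expect_equal(mr_weighted_median(const, n_boot = 50, seed = 1)$beta, 0.5)

  # ratios 1,2,3 with equal weights: cumulative midpoints 1/6, 1/2, 5/6
  eq <- make_harmonized(rep(1, 3), rep(0.01, 3), c(1, 2, 3), rep(0.1, 3))
  expect_equal(mr_weighted_median(eq, n_boot = 50, seed = 1)$beta, 2)

  h <- sim_harmonized(J = 9, theta = 0.3, seed = 53,
                      pleiotropy = list(frac = 0.3, mean = 0.05, sd = 0.05, balanced = FALSE))
  fit <- mr_weighted_median(h, n_boot = 100, seed = 2)
  expect_equal(fit$beta,
               oracle_weighted_median(h$beta_outcome / h$beta_exposure,
                                      h$beta_exposure^2 / h$se_outcome^2),
               tolerance = 1e-12)

  # bootstrap SE stable across seeds at full replicate count
  ses <- vapply(1:3, function(s) mr_weighted_median(h, n_boot = 5000, seed = s)$se,
                numeric(1))
  expect_lt(max(ses) / min(ses) - 1, 0.10) # pairwise within ~5% of each other
})

test_that("Cochran's Q matches hand arithmetic and flags heterogeneity", {
  same <- make_harmonized(c(0.2, 0.4), c(0.01, 0.01), c(0.1, 0.2), c(0.02, 0.03))
  qq <- cochran_q(same)
  expect_equal(qq$q, 0)
  expect_equal(qq$p, 1)

  # J=2, ratios 0 and 1, unit weights, reference 0.5 -> Q = 0.5
  h2 <- make_harmonized(c(1, 1), c(0.1, 0.1), c(0, 1), c(1, 1))
  expect_equal(cochran_q(h2, beta_ref = 0.5)$q, 0.5)
})

test_that("leave-one-out reduces to the complementary Wald ratio and finds planted outliers", {
  two <- make_harmonized(c(0.2, 0.5), c(0.01, 0.01), c(0.08, 0.31), c(0.02, 0.03))
  loo <- mr_leave_one_out(two)
  expect_equal(loo$beta[1], wald_ratio(0.5, 0.01, 0.31, 0.03)$beta)
  expect_equal(loo$beta[2], wald_ratio(0.2, 0.01, 0.08, 0.02)$beta)

  h <- sim_harmonized(J = 15, theta = 0.3, seed = 59)
  expect_false(any(mr_leave_one_out(h)$flag))

  # a grossly displaced SNP in an otherwise exactly-null set: only its
  # removal changes the sign of the pooled estimate
  out <- make_harmonized(seq(0.1, 0.8, by = 0.1), rep(0.01, 8),
                         c(0, 0, 0, 0.5, 0, 0, 0, 0), rep(0.02, 8))
  loo <- mr_leave_one_out(out)
  expect_true(loo$flag[4])
  expect_false(any(loo$flag[-4]))
})

test_that("funnel table mirrors Wald ratios and precision ordering", {
  h <- sim_harmonized(J = 7, theta = 0.2, seed = 67)
  f <- funnel_data(h)
  expect_equal(nrow(f), 7)
  expect_equal(f$ratio, h$beta_outcome / h$beta_exposure)
  ratio_se <- h$se_outcome / abs(h$beta_exposure)
  expect_equal(order(f$precision), order(1 / ratio_se))
})

test_that("odds-ratio conversion round-trips", {
  expect_equal(to_odds_ratio(0, 0.1)$or_, 1)
  no_se <- to_odds_ratio(log(2), 0)
  expect_equal(no_se$or_, 2)
  expect_equal(no_se$ci_low, 2)
  set.seed(71)
  b <- rnorm(5)
  expect_equal(log(to_odds_ratio(b, runif(5))$or_), b)
})
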
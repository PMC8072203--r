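test_that("summary statistics round-trip through write and read exactly", {
  tbl <- make_gwas_tbl(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gwas(tbl, path)
  back <- read_gwas(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("a shuffled, renamed file parses identically under a dialect", {
  tbl <- make_gwas_tbl(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  odd <- tbl |>
    dplyr::rename(marker = "snp_id", a1 = "effect_allele", a2 = "other_allele",
                  freq1 = "eaf", effect = "beta", stderr = "se", pval = "pvalue",
                  chromosome = "chrom", position = "pos", samples = "n") |>
    dplyr::select("pval", "a2", "marker", "effect", "freq1", "stderr",
                  "chromosome", "a1", "position", "samples")
  readr::write_tsv(odd, path)
  back <- read_gwas(path, dialect = c(
    snp_id = "marker", chrom = "chromosome", pos = "position",
    effect_allele = "a1", other_allele = "a2", eaf = "freq1",
    beta = "effect", se = "stderr", pvalue = "pval", n = "samples"
  ))
  expect_equal(as.data.frame(back), as.data.frame(tbl))
})

test_that("parse failures report the offending row; missing columns are named", {
  tbl <- make_gwas_tbl(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  broken <- tbl
  broken$se <- as.character(broken$se)
  broken$se[2] <- "NA"
  write_gwas(broken, path)
  expect_error(read_gwas(path), "SE.*2")

  nocol <- dplyr::select(tbl, -"se")
  write_gwas(nocol, path)
  expect_error(read_gwas(path), "SE")
})

test_that("per-SNP F statistic is the squared Wald z and matches a regression oracle", {
  expect_equal(per_snp_f_statistic(0.10, 0.05), 4)
  expect_equal(per_snp_f_statistic(0, 0.3), 0)
  expect_error(per_snp_f_statistic(0.1, 0), "se")

  # brute-force oracle: F = (n-2) R^2/(1-R^2) from an actual regression
  set.seed(7)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  y <- 0.15 * g + rnorm(n)
  sm <- summary(lm(y ~ g))
  f_wald <- per_snp_f_statistic(sm$coefficients["g", 1], sm$coefficients["g", 2])
  f_r2 <- (n - 2) * sm$r.squared / (1 - sm$r.squared)
  expect_lt(abs(f_wald - f_r2) / f_r2, 0.05)
})

test_that("instrument selection applies GWS, F and MAF filters and flags underpowered sets", {
  tbl <- make_gwas_tbl(2)
  tbl$pvalue <- c(4e-8, 6e-8)
  tbl$beta <- c(0.1, 0.1)
  tbl$se <- c(0.01, 0.01)
  out <- suppressWarnings(select_instruments(tbl))
  expect_equal(out$snp_id, "rs1")
  expect_true(attr(out, "excluded")) # 1 survivor < min_snps = 3

  # two genome-wide-significant SNPs still flag the exposure as excluded
  tbl3 <- make_gwas_tbl(2)
  tbl3$pvalue <- c(1e-10, 1e-9)
  tbl3$beta <- c(0.1, 0.1); tbl3$se <- c(0.01, 0.01)
  expect_warning(select_instruments(tbl3, exposure_id = "pyr"), "excluded")

  # 50-variant brute-force row-wise filter oracle
  set.seed(11)
  big <- make_gwas_tbl(50)
  big$pvalue <- 10^runif(50, -12, -5)
  big$beta <- rnorm(50, 0, 0.1)
  big$se <- runif(50, 0.005, 0.05)
  big$eaf <- runif(50, 0.001, 0.999)
  keep <- big$pvalue < 5e-8 & (big$beta / big$se)^2 >= 10 &
    pmin(big$eaf, 1 - big$eaf) >= 0.01
  got <- suppressWarnings(select_instruments(big))
  expect_equal(got$snp_id, big$snp_id[keep])
})

test_that("region exclusion removes a closed 1-based interval", {
  tbl <- make_gwas_tbl(3)
  tbl$chrom <- "19"
  tbl$pos <- c(4550000L, 4600000L, 4580000L)
  inst <- suppressWarnings(select_instruments(
    dplyr::mutate(tbl, pvalue = 1e-10, beta = 0.1, se = 0.01), min_snps = 1))
  r <- apoe_region("printed")
  out <- exclude_region(inst, r$chrom, r$start, r$end)
  expect_setequal(out$snp_id, "rs2")        # inside and boundary removed
  expect_true("region_excl" %in% attr(out, "filters_applied"))
  expect_error(exclude_region(inst, "19", 10, 5), "start")
})

test_that("outcome-associated instruments are removed by set difference", {
  inst <- suppressWarnings(select_instruments(
    dplyr::mutate(make_gwas_tbl(20), pvalue = 1e-10, beta = 0.1, se = 0.01),
    min_snps = 1))
  set.seed(3)
  outcome <- tibble::tibble(
    snp_id = sample(c(inst$snp_id, sprintf("rsX%d", 1:10)), 25),
    pvalue = 10^runif(25, -12, -4)
  )
  out <- exclude_outcome_associated(inst, outcome)
  sig <- outcome$snp_id[outcome$pvalue < 5e-8]
  expect_setequal(out$snp_id, setdiff(inst$snp_id, sig))
  expect_true(any(inst$snp_id %in% sig)) # the filter actually bit
})

test_that("greedy clumping keeps the best SNP per LD block", {
  two <- make_gwas_tbl(2)
  two$pvalue <- c(1e-10, 1e-9)
  ld <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(two$snp_id, two$snp_id))
  expect_equal(ld_clump(two, ld)$snp_id, "rs1")

  ld0 <- diag(2); dimnames(ld0) <- dimnames(ld)
  expect_equal(nrow(ld_clump(two, ld0)), 2)

  # 15 SNPs in random LD blocks vs an independently coded greedy loop
  set.seed(5)
  tbl <- make_gwas_tbl(15)
  tbl$pvalue <- runif(15, 1e-12, 1e-6)
  block <- sample(1:4, 15, replace = TRUE)
  r2 <- outer(block, block, function(a, b) ifelse(a == b, 0.8, 0))
  diag(r2) <- 1
  dimnames(r2) <- list(tbl$snp_id, tbl$snp_id)
  oracle <- local({
    remaining <- tbl[order(tbl$pvalue), ]
    kept <- character(0)
    while (nrow(remaining) > 0) {
      top <- remaining$snp_id[1]
      kept <- c(kept, top)
      remaining <- remaining[r2[remaining$snp_id, top] <= 0.001, , drop = FALSE]
    }
    kept
  })
  expect_setequal(ld_clump(tbl, r2)$snp_id, oracle)

  # a pair absent from the LD table counts as independent, with a warning
  r2miss <- r2[-2, -2]
  expect_warning(ld_clump(tbl, r2miss), "r2 = 0")
})

test_that("selection filters are idempotent, order-free and subsetting", {
  set.seed(9)
  tbl <- make_gwas_tbl(40)
  tbl$pvalue <- 10^runif(40, -12, -5)
  tbl$beta <- rnorm(40, 0, 0.1)
  tbl$se <- runif(40, 0.005, 0.05)
  once <- suppressWarnings(select_instruments(tbl, min_snps = 1))
  twice <- suppressWarnings(select_instruments(once, min_snps = 1))
  expect_equal(twice$snp_id, once$snp_id)
  expect_true(all(once$snp_id %in% tbl$snp_id))
  expect_false(anyDuplicated(once$snp_id) > 0)

  # row-wise predicates commute: MAF-first equals joint application
  maf_first <- tbl[pmin(tbl$eaf, 1 - tbl$eaf) >= 0.01, ]
  a <- suppressWarnings(select_instruments(maf_first, min_snps = 1))
  expect_equal(a$snp_id, once$snp_id)
})
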
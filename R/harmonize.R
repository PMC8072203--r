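# Allele harmonization between exposure and outcome summary statistics.
#
# All estimators consume the harmonized table produced here: per SNP, the
# exposure effect (per-SD units) and the outcome effect (log-odds) expressed
# for the SAME effect allele. Harmonization resolves swapped allele labels,
# reverse-strand coding, and palindromic (A/T, C/G) ambiguity.

#' Harmonize one exposure against one outcome
#'
#' Aligns outcome effect sizes to the exposure's effect allele, SNP by SNP
#' (matched on `snp_id`). Allele-label swaps negate the outcome beta and
#' complement its frequency; reverse-strand codings are base-complemented
#' first. Palindromic SNPs (A/T or C/G), whose strand cannot be resolved from
#' allele labels, are handled per `palindrome_mode`:
#'
#' * `"assume-forward"` (default, the primary-analysis convention): both
#'   GWAS are taken to be forward-strand coded, so palindromes align by
#'   allele label like any other SNP and none are excluded.
#' * `"drop-noninferable"` (the sensitivity re-run): palindromes whose
#'   minor-allele frequency exceeds `maf_noninfer` on either side are dropped
#'   (frequency cannot resolve the strand near MAF 0.5); the rest are
#'   oriented by frequency agreement.
#'
#' When the outcome file carries no allele frequency, the exposure frequency
#' is used for palindromic inference.
#'
#' @param exposure an `instrument_set` or canonical summary-statistics tibble
#'   for the exposure.
#' @param outcome canonical summary-statistics tibble for the outcome.
#' @param palindrome_mode `"assume-forward"` or `"drop-noninferable"`.
#' @param maf_noninfer MAF bound above which a palindrome is non-inferable
#'   under `"drop-noninferable"` (default 0.40).
#' @return an `mr_harmonized` tibble with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta_exposure`, `se_exposure`, `pval_exposure`,
#'   `beta_outcome`, `se_outcome`, `action`; attributes `exposure_id` and
#'   `drops` (a tibble of removed SNPs with their action tags, so input rows
#'   reconcile exactly with kept + dropped).
#' @export
harmonize_pair <- function(exposure, outcome,
                           palindrome_mode = c("assume-forward", "drop-noninferable"),
                           maf_noninfer = 0.40) {
  palindrome_mode <- match.arg(palindrome_mode)
  assert_cols(exposure, c("snp_id", "effect_allele", "other_allele", "beta", "se"), "exposure")
  assert_cols(outcome, c("snp_id", "effect_allele", "other_allele", "beta", "se"), "outcome")
  exposure <- dedupe_smallest_p(exposure, "exposure")
  outcome <- dedupe_smallest_p(outcome, "outcome")

  m <- match(exposure$snp_id, outcome$snp_id)
  rows <- purrr::map(seq_len(nrow(exposure)), function(i) {
    ex <- exposure[i, ]
    if (is.na(m[i])) {
      return(harm_row(ex, NA, NA, NA, "dropped-unmatched", keep = FALSE))
    }
    ou <- outcome[m[i], ]
    align_outcome(ex, ou, palindrome_mode, maf_noninfer)
  })
  all_rows <- dplyr::bind_rows(rows)
  kept <- all_rows[all_rows$.keep, setdiff(names(all_rows), ".keep"), drop = FALSE]
  drops <- all_rows[!all_rows$.keep, c("snp_id", "action"), drop = FALSE]
  if (nrow(drops) > 0) {
    rlang::inform(sprintf("harmonize_pair(): dropped %d SNP(s): %s",
                          nrow(drops),
                          paste(sprintf("%s(%s)", drops$snp_id, drops$action), collapse = ", ")))
  }
  structure(
    tibble::as_tibble(kept),
    exposure_id = attr(exposure, "exposure_id") %||% "exposure",
    drops = tibble::as_tibble(drops),
    class = c("mr_harmonized", class(tibble::tibble()))
  )
}

dedupe_smallest_p <- function(x, what) {
  if (nrow(x) == 0 || !anyDuplicated(x$snp_id)) return(x)
  p <- if ("pvalue" %in% names(x)) x$pvalue else rep(1, nrow(x))
  ord <- order(x$snp_id, p)
  x <- x[ord, ][!duplicated(x$snp_id[ord]), , drop = FALSE]
  rlang::warn(sprintf("harmonize: duplicated snp_id in %s resolved by smallest p", what))
  x
}

harm_row <- function(ex, beta_out, se_out, eaf_out, action, keep) {
  tibble::tibble(
    snp_id = ex$snp_id,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    eaf = if ("eaf" %in% names(ex)) ex$eaf else NA_real_,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    pval_exposure = if ("pvalue" %in% names(ex)) ex$pvalue else NA_real_,
    beta_outcome = beta_out,
    se_outcome = se_out,
    eaf_outcome = eaf_out,
    action = action,
    .keep = keep
  )
}

align_outcome <- function(ex, ou, palindrome_mode, maf_noninfer) {
  ea <- ex$effect_allele; oa <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  eaf_y <- if ("eaf" %in% names(ou)) ou$eaf else NA_real_
  pal <- is_palindromic(ea, oa)

  if (pal) {
    # strand flip is indistinguishable from an allele swap; align by label
    if (ea_y == ea && oa_y == oa) {
      beta <- ou$beta; eafo <- eaf_y; action <- "kept"
    } else if (ea == oa_y && oa == ea_y) {
      beta <- -ou$beta; eafo <- 1 - eaf_y; action <- "sign-flipped"
    } else {
      return(harm_row(ex, NA, NA, NA, "dropped-incompatible", keep = FALSE))
    }
    if (palindrome_mode == "drop-noninferable") {
      eaf_x <- if ("eaf" %in% names(ex)) ex$eaf else NA_real_
      eafo_use <- if (is.na(eafo)) eaf_x else eafo
      maf_x <- min(eaf_x, 1 - eaf_x)
      maf_y <- min(eafo_use, 1 - eafo_use)
      if ((!is.na(maf_x) && maf_x > maf_noninfer) ||
          (!is.na(maf_y) && maf_y > maf_noninfer)) {
        return(harm_row(ex, NA, NA, NA, "dropped-palindromic", keep = FALSE))
      }
      if (!is.na(eaf_x) && !is.na(eafo_use) &&
          (eaf_x < 0.5) != (eafo_use < 0.5)) {
        # frequencies disagree: the outcome is on the other strand,
        # which for a palindrome means the aligned beta must flip
        beta <- -beta
        eafo <- 1 - eafo
        action <- "strand-flipped"
      }
    }
    return(harm_row(ex, beta, ou$se, eafo, action, keep = TRUE))
  }

  if (ea_y == ea && oa_y == oa) {
    harm_row(ex, ou$beta, ou$se, eaf_y, "kept", keep = TRUE)
  } else if (ea_y == oa && oa_y == ea) {
    harm_row(ex, -ou$beta, ou$se, 1 - eaf_y, "sign-flipped", keep = TRUE)
  } else if (complement_alleles(ea_y) == ea && complement_alleles(oa_y) == oa) {
    harm_row(ex, ou$beta, ou$se, eaf_y, "strand-flipped", keep = TRUE)
  } else if (complement_alleles(ea_y) == oa && complement_alleles(oa_y) == ea) {
    harm_row(ex, -ou$beta, ou$se, 1 - eaf_y, "strand-sign-flipped", keep = TRUE)
  } else {
    rlang::warn(sprintf("harmonize: irreconcilable alleles for %s (%s/%s vs %s/%s); dropped",
                        ex$snp_id, ea, oa, ea_y, oa_y))
    harm_row(ex, NA, NA, NA, "dropped-incompatible", keep = FALSE)
  }
}

#' Harmonize several exposures and one outcome into a complete matrix
#'
#' Builds the multivariable-MR input: the candidate SNP set is the union of
#' the per-exposure instruments; every exposure must report an association for
#' every retained SNP, either directly or through a user-supplied proxy map
#' (`proxy_table`, columns `snp_id`, `proxy_id`: the proxy's association
#' substitutes where the SNP itself is absent from an exposure). SNPs
#' unresolvable in any exposure or in the outcome are dropped, so the
#' resulting J x K effect matrix has no missing cells. Alleles are aligned to
#' the first exposure reporting each SNP.
#'
#' @param exposures named list (length >= 2) of canonical summary-statistics
#'   tibbles or `instrument_set`s, one per exposure.
#' @param outcome canonical summary-statistics tibble for the outcome.
#' @param proxy_table optional two-column map (`snp_id`, `proxy_id`).
#' @inheritParams harmonize_pair
#' @return an `mr_harmonized_multi` list: `snp_id` (length J),
#'   `beta_exposure`/`se_exposure` (J x K matrices), `beta_outcome`/
#'   `se_outcome` (length J), `eaf`, `exposure_ids`, `drops`.
#' @export
harmonize_multi <- function(exposures, outcome, proxy_table = NULL,
                            palindrome_mode = c("assume-forward", "drop-noninferable"),
                            maf_noninfer = 0.40) {
  palindrome_mode <- match.arg(palindrome_mode)
  if (length(exposures) < 2) {
    rlang::abort("harmonize_multi(): need at least 2 exposures (use harmonize_pair for one)")
  }
  ids <- names(exposures) %||% paste0("exposure", seq_along(exposures))
  if (is.null(names(exposures))) names(exposures) <- ids
  ids <- purrr::imap_chr(exposures, function(x, nm) attr(x, "exposure_id") %||% nm)

  candidate <- unique(unlist(purrr::map(exposures, "snp_id")))
  K <- length(exposures)

  resolve <- function(tab, snp) {
    i <- match(snp, tab$snp_id)
    if (!is.na(i)) return(tab[i, ])
    if (!is.null(proxy_table)) {
      j <- match(snp, proxy_table$snp_id)
      if (!is.na(j)) {
        k <- match(proxy_table$proxy_id[j], tab$snp_id)
        if (!is.na(k)) return(tab[k, ])
      }
    }
    NULL
  }

  drops <- tibble::tibble(snp_id = character(0), action = character(0))
  rows <- list()
  for (snp in candidate) {
    cells <- purrr::map(exposures, resolve, snp = snp)
    if (any(purrr::map_lgl(cells, is.null))) {
      drops <- dplyr::add_row(drops, snp_id = snp, action = "dropped-unresolved-exposure")
      next
    }
    ref <- cells[[1]]
    aligned_x <- purrr::map(cells, function(cell) {
      align_outcome(ref, cell,
                    palindrome_mode = "assume-forward", maf_noninfer = maf_noninfer)
    })
    if (any(purrr::map_lgl(aligned_x, ~ !.x$.keep))) {
      drops <- dplyr::add_row(drops, snp_id = snp, action = "dropped-incompatible")
      next
    }
    oi <- match(snp, outcome$snp_id)
    if (is.na(oi)) {
      drops <- dplyr::add_row(drops, snp_id = snp, action = "dropped-unmatched")
      next
    }
    ay <- align_outcome(ref, outcome[oi, ], palindrome_mode, maf_noninfer)
    if (!ay$.keep) {
      drops <- dplyr::add_row(drops, snp_id = snp, action = ay$action)
      next
    }
    rows[[snp]] <- list(
      snp_id = snp,
      eaf = ref$eaf %||% NA_real_,
      bx = purrr::map_dbl(aligned_x, "beta_outcome"),
      sx = purrr::map_dbl(aligned_x, "se_outcome"),
      by = ay$beta_outcome,
      sy = ay$se_outcome
    )
  }
  J <- length(rows)
  if (J < K + 2) {
    rlang::abort(sprintf(
      "harmonize_multi(): only %d SNP(s) survive for %d exposures; need at least %d for identifiability",
      J, K, K + 2
    ))
  }
  out <- list(
    snp_id = purrr::map_chr(rows, "snp_id"),
    eaf = purrr::map_dbl(rows, "eaf"),
    beta_exposure = do.call(rbind, purrr::map(rows, "bx")),
    se_exposure = do.call(rbind, purrr::map(rows, "sx")),
    beta_outcome = purrr::map_dbl(rows, "by"),
    se_outcome = purrr::map_dbl(rows, "sy"),
    exposure_ids = unname(ids),
    drops = drops
  )
  dimnames(out$beta_exposure) <- list(out$snp_id, out$exposure_ids)
  dimnames(out$se_exposure) <- list(out$snp_id, out$exposure_ids)
  structure(out, class = "mr_harmonized_multi")
}

#' @export
print.mr_harmonized_multi <- function(x, ...) {
  cat(sprintf("<mr_harmonized_multi> %d SNPs x %d exposures (%s)\n",
              length(x$snp_id), length(x$exposure_ids),
              paste(x$exposure_ids, collapse = ", ")))
  invisible(x)
}

#' @method as_tibble mr_harmonized_multi
#' @export
as_tibble.mr_harmonized_multi <- function(x, ...) {
  bx <- tibble::as_tibble(x$beta_exposure, .name_repair = "minimal")
  names(bx) <- paste0("beta_", x$exposure_ids)
  sx <- tibble::as_tibble(x$se_exposure, .name_repair = "minimal")
  names(sx) <- paste0("se_", x$exposure_ids)
  dplyr::bind_cols(
    tibble::tibble(snp_id = x$snp_id),
    bx, sx,
    tibble::tibble(beta_outcome = x$beta_outcome, se_outcome = x$se_outcome)
  )
}

#' Drop SNPs from a multivariable harmonized dataset
#'
#' @param data an `mr_harmonized_multi`.
#' @param snp_ids SNPs to remove.
#' @return the reduced `mr_harmonized_multi`.
#' @export
drop_snps <- function(data, snp_ids) {
  stopifnot(inherits(data, "mr_harmonized_multi"))
  keep <- !(data$snp_id %in% snp_ids)
  out <- data
  out$snp_id <- data$snp_id[keep]
  out$eaf <- data$eaf[keep]
  out$beta_exposure <- data$beta_exposure[keep, , drop = FALSE]
  out$se_exposure <- data$se_exposure[keep, , drop = FALSE]
  out$beta_outcome <- data$beta_outcome[keep]
  out$se_outcome <- data$se_outcome[keep]
  out
}

#' Write a harmonized table and its JSON report
#'
#' @param x an `mr_harmonized` tibble from [harmonize_pair()].
#' @param path output TSV path; the JSON report lands at `<path>.report.json`.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  drops <- attr(x, "drops") %||% tibble::tibble()
  report <- list(
    exposure_id = attr(x, "exposure_id"),
    n_kept = nrow(x),
    n_dropped = nrow(drops),
    actions = as.list(table(x$action)),
    drops = drops
  )
  jsonlite::write_json(report, paste0(path, ".report.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
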
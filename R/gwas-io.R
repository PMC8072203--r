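# Reading, writing and filtering GWAS summary statistics.
#
# Canonical column names used throughout the package:
#   snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pvalue, n
# corresponding to the conventional headers SNP, CHR, BP, EA, OA, EAF, BETA,
# SE, P, N. Files in other dialects are mapped via a named `dialect` vector.

canonical_fields <- c(
  snp_id = "SNP", chrom = "CHR", pos = "BP",
  effect_allele = "EA", other_allele = "OA", eaf = "EAF",
  beta = "BETA", se = "SE", pvalue = "P", n = "N"
)
mandatory_fields <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
numeric_fields <- c("pos", "eaf", "beta", "se", "pvalue", "n")

#' Read GWAS summary statistics
#'
#' Reads a tab- or whitespace-delimited summary-statistics file with a header
#' row into the canonical per-variant table. Columns can be renamed and
#' reordered arbitrarily in the file; supply `dialect` to map them onto the
#' canonical fields.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named character vector mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the column names used in the file.
#'   Defaults to the conventional headers `SNP, CHR, BP, EA, OA, EAF, BETA,
#'   SE, P, N`.
#' @return a tibble with one row per variant and the canonical columns.
#'   Alleles are upper-cased. Optional fields absent from the file come back
#'   as `NA`.
#' @details Rows whose numeric fields fail coercion are never silently
#'   dropped: the reader aborts listing the offending line numbers (line 1 is
#'   the header, so the first data row is line 2). A missing mandatory column
#'   aborts naming the column.
#' @export
read_gwas <- function(path, dialect = canonical_fields) {
  dialect <- utils::modifyList(as.list(canonical_fields), as.list(dialect))
  raw <- readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  for (fld in mandatory_fields) {
    if (!dialect[[fld]] %in% names(raw)) {
      rlang::abort(sprintf(
        "summary-statistics file '%s' lacks mandatory column '%s' (canonical field '%s')",
        path, dialect[[fld]], fld
      ))
    }
  }
  out <- tibble::tibble(.rows = nrow(raw))
  for (fld in names(canonical_fields)) {
    col <- dialect[[fld]]
    out[[fld]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  # numeric coercion with row-level error reporting
  for (fld in numeric_fields) {
    vals <- suppressWarnings(as.numeric(out[[fld]]))
    bad <- which(!is.na(out[[fld]]) & out[[fld]] != "NA" & is.na(vals))
    if (fld %in% mandatory_fields) {
      bad <- union(bad, which(is.na(vals)))
    }
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "column '%s' of '%s' is not numeric on data row(s) %s",
        dialect[[fld]], path, paste(bad, collapse = ", ")
      ))
    }
    out[[fld]] <- vals
  }
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)
  out$chrom <- as.character(out$chrom)
  validate_assocs(out, path)
  out
}

validate_assocs <- function(x, what = "associations") {
  same <- which(x$effect_allele == x$other_allele)
  if (length(same) > 0) {
    rlang::abort(sprintf("%s: effect and other allele identical for %s",
                         what, paste(x$snp_id[same], collapse = ", ")))
  }
  bad_se <- which(!is.na(x$se) & x$se <= 0)
  if (length(bad_se) > 0) {
    rlang::abort(sprintf("%s: non-positive SE for %s",
                         what, paste(x$snp_id[bad_se], collapse = ", ")))
  }
  invisible(x)
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_gwas()]: writes the canonical table back out as a
#' tab-delimited file under the given column dialect.
#'
#' @param x canonical summary-statistics tibble.
#' @param path output file path.
#' @inheritParams read_gwas
#' @return `path`, invisibly.
#' @export
write_gwas <- function(x, path, dialect = canonical_fields) {
  dialect <- utils::modifyList(as.list(canonical_fields), as.list(dialect))
  out <- x[, intersect(names(canonical_fields), names(x))]
  names(out) <- unlist(dialect[names(out)])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-SNP instrument-strength F statistic
#'
#' The square of the Wald z, `(beta/se)^2` — the standard approximation to the
#' first-stage F when only summary statistics (no per-SNP R-squared) are
#' available. F < 10 conventionally signals a weak instrument.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return numeric vector of F statistics.
#' @examples
#' per_snp_f_statistic(0.10, 0.05) # 4
#' @export
per_snp_f_statistic <- function(beta, se) {
  if (any(!is.na(se) & se <= 0)) {
    rlang::abort("per_snp_f_statistic(): se must be > 0")
  }
  (beta / se)^2
}

new_instrument_set <- function(data, exposure_id, filters, excluded, audit) {
  structure(
    data,
    exposure_id = exposure_id,
    filters_applied = filters,
    excluded = excluded,
    audit = audit,
    class = c("instrument_set", class(tibble::as_tibble(data)))
  )
}

set_attrs <- function(data, template, ...) {
  dots <- list(...)
  for (a in c("exposure_id", "filters_applied", "excluded", "audit")) {
    attr(data, a) <- if (a %in% names(dots)) dots[[a]] else attr(template, a)
  }
  class(data) <- unique(c("instrument_set", class(tibble::as_tibble(data))))
  data
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf(
    "<instrument_set> exposure '%s': %d SNP(s)%s; filters: %s\n",
    attr(x, "exposure_id") %||% "?", nrow(x),
    if (isTRUE(attr(x, "excluded"))) " [EXCLUDED: too few instruments]" else "",
    paste(attr(x, "filters_applied"), collapse = ",")
  ))
  NextMethod()
}

#' Select genetic instruments for an exposure
#'
#' Applies the standard instrument-selection filters to a table of per-SNP
#' exposure associations: genome-wide significance, minimum per-SNP
#' F-statistic, and minimum minor-allele frequency. Exposures left with fewer
#' than `min_snps` surviving instruments are flagged excluded (kept in the
#' pipeline audit but not analysed), mirroring the removal of exposures with
#' too few genome-wide-significant SNPs for adequately powered MR.
#'
#' @param assocs canonical summary-statistics tibble for one exposure.
#' @param p_max genome-wide significance ceiling (default `5e-8`).
#' @param f_min per-SNP F floor (default 10).
#' @param maf_min minor-allele-frequency floor (default 0.01). Variants with
#'   missing `eaf` pass this filter (it cannot be assessed).
#' @param min_snps minimum surviving instruments for the exposure to remain
#'   analysable (default 3).
#' @param exposure_id label stored on the result.
#' @return an `instrument_set`: the filtered tibble carrying attributes
#'   `exposure_id`, `filters_applied`, `excluded` and a per-filter removal
#'   `audit`.
#' @export
select_instruments <- function(assocs, p_max = 5e-8, f_min = 10, maf_min = 0.01,
                               min_snps = 3, exposure_id = "exposure") {
  stopifnot(p_max > 0, f_min >= 0, maf_min >= 0)
  assert_cols(assocs, mandatory_fields, "assocs")
  audit <- list(input = nrow(assocs))
  if (nrow(assocs) > 0 && anyDuplicated(assocs$snp_id)) {
    n0 <- nrow(assocs)
    assocs <- assocs |>
      dplyr::group_by(.data$snp_id) |>
      dplyr::slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    audit$duplicates <- n0 - nrow(assocs)
    rlang::warn(sprintf("select_instruments(): %d duplicated snp_id row(s) resolved by smallest p",
                        audit$duplicates))
  }
  f <- per_snp_f_statistic(assocs$beta, assocs$se)
  maf <- pmin(assocs$eaf, 1 - assocs$eaf)
  keep_gws <- assocs$pvalue < p_max
  keep_f <- f >= f_min
  keep_maf <- is.na(maf) | maf >= maf_min
  audit$gws <- sum(!keep_gws)
  audit$f10 <- sum(keep_gws & !keep_f)
  audit$maf <- sum(keep_gws & keep_f & !keep_maf)
  out <- assocs[keep_gws & keep_f & keep_maf, , drop = FALSE]
  audit$retained <- nrow(out)
  excluded <- nrow(out) < min_snps
  if (excluded) {
    rlang::warn(sprintf(
      "exposure '%s' flagged excluded: %d instrument(s) survive selection (< %d)",
      exposure_id, nrow(out), min_snps
    ))
  }
  new_instrument_set(out, exposure_id, c("gws", "f10", "maf"), excluded, audit)
}

#' Named genomic region presets for the ApoE locus
#'
#' Two intervals on chromosome 19 are shipped: `"printed"`,
#' chr19:4,500,000-4,580,000, and `"grch37"`, the conventional ApoE locus
#' around 45.4 Mb on GRCh37 (chr19:45,380,000-45,435,000). Which one a given
#' analysis should exclude is a configuration choice; both are provided as
#' named presets rather than a single hard-coded region.
#'
#' @param preset `"printed"` (default) or `"grch37"`.
#' @return a list with `chrom`, `start`, `end` (1-based, closed interval).
#' @export
apoe_region <- function(preset = c("printed", "grch37")) {
  preset <- match.arg(preset)
  switch(preset,
    printed = list(chrom = "19", start = 4500000L, end = 4580000L),
    grch37 = list(chrom = "19", start = 45380000L, end = 45435000L)
  )
}

#' Exclude instruments inside a genomic region
#'
#' Removes variants whose position falls inside a closed interval
#' `[start, end]` (1-based) on the given chromosome — used to drop pleiotropic
#' loci such as ApoE from the instrument set.
#'
#' @param instruments an `instrument_set` (or canonical tibble).
#' @param chrom chromosome label (matched as character).
#' @param start,end interval bounds in base pairs; `start <= end`.
#' @return the filtered `instrument_set`, with a `region_excl` filter tag.
#' @export
exclude_region <- function(instruments, chrom, start, end) {
  if (start > end) rlang::abort("exclude_region(): start must be <= end")
  assert_cols(instruments, c("chrom", "pos"), "instruments")
  hit <- !is.na(instruments$chrom) & instruments$chrom == as.character(chrom) &
    !is.na(instruments$pos) & instruments$pos >= start & instruments$pos <= end
  audit <- c(attr(instruments, "audit"),
             list(region_excl = sum(hit)))
  set_attrs(instruments[!hit, , drop = FALSE], instruments,
            filters_applied = union(attr(instruments, "filters_applied"), "region_excl"),
            audit = audit)
}

#' Exclude instruments associated with the outcome
#'
#' Drops any instrument whose `snp_id` reaches `p_max` in the outcome GWAS —
#' such variants risk violating the exchangeability assumption (association
#' with the outcome through confounder pathways).
#'
#' @param instruments an `instrument_set`.
#' @param outcome_assocs canonical summary-statistics tibble for the outcome.
#' @param p_max outcome significance ceiling (default `5e-8`).
#' @return the filtered `instrument_set`, with an `outcome_excl` filter tag.
#' @export
exclude_outcome_associated <- function(instruments, outcome_assocs, p_max = 5e-8) {
  assert_cols(outcome_assocs, c("snp_id", "pvalue"), "outcome_assocs")
  sig <- outcome_assocs$snp_id[!is.na(outcome_assocs$pvalue) & outcome_assocs$pvalue < p_max]
  hit <- instruments$snp_id %in% sig
  audit <- c(attr(instruments, "audit"), list(outcome_excl = sum(hit)))
  set_attrs(instruments[!hit, , drop = FALSE], instruments,
            filters_applied = union(attr(instruments, "filters_applied"), "outcome_excl"),
            audit = audit)
}

#' Greedy LD clumping against a user-supplied r-squared table
#'
#' Orders variants by ascending p-value; the best variant is kept and all
#' others in linkage disequilibrium with it (`r^2 > r2_max`) are removed, and
#' the step repeats on the remainder. LD comes from a user-supplied matrix or
#' long table — no reference panel is queried. Pairs absent from the table are
#' treated as `r^2 = 0` with a warning.
#'
#' @param assocs canonical summary-statistics tibble (or `instrument_set`).
#' @param ld either a symmetric numeric matrix with snp_id dimnames, or a
#'   long tibble/data.frame with columns `snp1`, `snp2`, `r2`.
#' @param r2_max LD ceiling between retained variants (default 0.001).
#' @return the clumped table in the input's row order restricted to kept
#'   SNPs, with a `clumped` filter tag when the input was an `instrument_set`.
#' @export
ld_clump <- function(assocs, ld, r2_max = 0.001) {
  assert_cols(assocs, c("snp_id", "pvalue"), "assocs")
  r2_of <- ld_lookup(ld)
  ids <- assocs$snp_id[order(assocs$pvalue)]
  kept <- character(0)
  missing_pairs <- 0L
  for (id in ids) {
    r2s <- vapply(kept, function(k) {
      v <- r2_of(id, k)
      if (is.na(v)) {
        missing_pairs <<- missing_pairs + 1L
        v <- 0
      }
      v
    }, numeric(1))
    if (all(r2s <= r2_max)) kept <- c(kept, id)
  }
  if (missing_pairs > 0) {
    rlang::warn(sprintf("ld_clump(): %d SNP pair(s) absent from ld table treated as r2 = 0",
                        missing_pairs))
  }
  out <- assocs[assocs$snp_id %in% kept, , drop = FALSE]
  if (inherits(assocs, "instrument_set")) {
    out <- set_attrs(out, assocs,
                     filters_applied = union(attr(assocs, "filters_applied"), "clumped"),
                     audit = c(attr(assocs, "audit"), list(clumped = nrow(assocs) - nrow(out))))
  }
  out
}

ld_lookup <- function(ld) {
  if (is.matrix(ld)) {
    function(a, b) {
      if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b] else NA_real_
    }
  } else {
    assert_cols(ld, c("snp1", "snp2", "r2"), "ld")
    key <- c(paste(ld$snp1, ld$snp2), paste(ld$snp2, ld$snp1))
    val <- c(ld$r2, ld$r2)
    function(a, b) {
      i <- match(paste(a, b), key)
      if (is.na(i)) NA_real_ else val[i]
    }
  }
}

#' Write the per-filter removal audit as JSON
#'
#' @param instruments an `instrument_set` carrying an `audit` attribute.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_instrument_audit <- function(instruments, path) {
  audit <- attr(instruments, "audit") %||% list()
  payload <- list(
    exposure_id = attr(instruments, "exposure_id"),
    filters_applied = as.list(attr(instruments, "filters_applied")),
    excluded = isTRUE(attr(instruments, "excluded")),
    removed = audit,
    retained = nrow(instruments)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
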
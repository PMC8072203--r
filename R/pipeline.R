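# Workflow orchestration: forward MR per exposure, reverse MR, and the
# pruning + Bayesian model-averaging stage, each driven by one structured
# config (a YAML file or an equivalent named list) and emitting TSV report
# tables plus a machine-readable JSON audit.

#' Read and validate a pipeline run configuration
#'
#' The config is a named list (or YAML file) with, as applicable:
#' `exposures` (list of `{id, path, dialect}`), `outcome` (`{id, path,
#' dialect}`), `direction`, `region_exclusions` (list of `{chrom, start,
#' end}` or preset names understood by [apoe_region()]), `palindrome_mode`,
#' `methods`, `selection` (`p_max`, `f_min`, `maf_min`, `min_snps`),
#' `presso` (`enabled`, `n_sim`, `seed`), `wmedian` (`n_boot`, `seed`),
#' `bma` (`prior_p`, `sigma2`, `mode`, `z`, `seed`, `rg_path`,
#' `rg_threshold`, `pp_min`), `ld_path`, `corr_path` (phenotype correlations
#' for the effective-tests threshold), `alpha`, `out_dir`.
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated config list (class `mr_run_config`) with defaults
#'   filled in and a `hash` field identifying it.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) rlang::abort(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    direction = "forward",
    palindrome_mode = "assume-forward",
    methods = c("ivw", "egger", "wmedian"),
    selection = list(p_max = 5e-8, f_min = 10, maf_min = 0.01, min_snps = 3),
    presso = list(enabled = FALSE, n_sim = 1000, seed = NULL, sig = 0.05),
    wmedian = list(n_boot = 5000, seed = NULL),
    bma = list(prior_p = 0.1, sigma2 = 0.25, mode = "exhaustive", z = 10000,
               seed = NULL, rg_threshold = 0.95, pp_min = 0.1),
    alpha = 0.05,
    region_exclusions = list()
  )
  config <- utils::modifyList(defaults, config, keep.null = TRUE)
  for (f in c(purrr::map_chr(config$exposures %||% list(), "path"),
              config$outcome$path, config$ld_path, config$corr_path,
              config$bma$rg_path)) {
    if (!is.null(f) && !file.exists(f)) {
      rlang::abort(sprintf("configured input file '%s' does not exist", f))
    }
  }
  stochastic <- list(
    wmedian = ("wmedian" %in% config$methods) && is.null(config$wmedian$seed),
    presso = isTRUE(config$presso$enabled) && is.null(config$presso$seed),
    bma_shotgun = identical(config$bma$mode, "shotgun") && is.null(config$bma$seed)
  )
  if (any(unlist(stochastic))) {
    rlang::abort(sprintf("config enables stochastic step(s) without a seed: %s",
                         paste(names(stochastic)[unlist(stochastic)], collapse = ", ")))
  }
  # hash identifies the analytical configuration; the output location is not
  # part of it, so reruns into different directories compare equal
  config$hash <- rlang::hash(config[setdiff(names(config), c("hash", "out_dir"))])
  structure(config, class = c("mr_run_config", "list"))
}

resolve_regions <- function(region_exclusions) {
  purrr::map(region_exclusions, function(r) {
    if (is.character(r)) apoe_region(r) else r
  })
}

read_configured <- function(entry) {
  read_gwas(entry$path, dialect = unlist(entry$dialect %||% list()))
}

#' Run the forward MR workflow
#'
#' For each configured exposure: select instruments, apply region and
#' outcome-association exclusions, harmonize against the outcome, run the
#' estimator battery (plus leave-one-out, funnel and optionally MR-PRESSO),
#' convert to the OR scale, and evaluate against the effective-tests-adjusted
#' significance threshold when a phenotype correlation matrix is configured.
#' Exposures excluded at selection are recorded in the audit and skipped.
#'
#' @param config an `mr_run_config` (or something [read_run_config()]
#'   accepts).
#' @return an `mr_report` list: `results` (per exposure x method),
#'   `sensitivity` (leave-one-out + PRESSO + funnel rows), `audit`,
#'   `threshold`. When `config$out_dir` is set, writes `results.tsv`,
#'   `sensitivity.tsv`, `audit.json` and `run.log` there.
#' @export
mr_run_forward <- function(config) {
  config <- read_run_config(config)
  outcome <- read_configured(config$outcome)
  regions <- resolve_regions(config$region_exclusions)
  threshold <- forward_threshold(config)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
  }

  results <- list(); sens <- list(); audit <- list()
  for (entry in config$exposures) {
    t0 <- Sys.time()
    ex_id <- entry$id %||% entry$path
    assocs <- read_configured(entry)
    inst <- withCallingHandlers(
      select_instruments(assocs,
                         p_max = config$selection$p_max, f_min = config$selection$f_min,
                         maf_min = config$selection$maf_min, min_snps = config$selection$min_snps,
                         exposure_id = ex_id),
      warning = function(w) invokeRestart("muffleWarning")
    )
    for (r in regions) inst <- exclude_region(inst, r$chrom, r$start, r$end)
    inst <- exclude_outcome_associated(inst, outcome, p_max = config$selection$p_max)
    audit[[ex_id]] <- c(attr(inst, "audit"),
                        list(excluded = isTRUE(attr(inst, "excluded"))))
    if (isTRUE(attr(inst, "excluded")) || nrow(inst) < config$selection$min_snps) {
      note("exposure %s excluded at instrument selection (%d SNPs)", ex_id, nrow(inst))
      audit[[ex_id]]$excluded <- TRUE
      next
    }
    harm <- suppressMessages(
      harmonize_pair(inst, outcome, palindrome_mode = config$palindrome_mode)
    )
    audit[[ex_id]]$harmonized <- nrow(harm)
    audit[[ex_id]]$harmonization_drops <- nrow(attr(harm, "drops"))
    res <- mr_all_methods(harm, methods = config$methods,
                          n_boot = config$wmedian$n_boot, seed = config$wmedian$seed)
    res <- dplyr::mutate(res, exposure_id = ex_id, .before = 1)
    if (!is.null(threshold)) {
      res$adjusted_alpha <- threshold$threshold
      res$significant_adjusted <- res$pvalue < threshold$threshold
    }
    results[[ex_id]] <- res

    loo <- mr_leave_one_out(harm) |>
      dplyr::mutate(exposure_id = ex_id, analysis = "leave-one-out", .before = 1)
    fun <- funnel_data(harm) |>
      dplyr::mutate(exposure_id = ex_id, analysis = "funnel", .before = 1)
    sens[[ex_id]] <- dplyr::bind_rows(loo, fun)
    if (isTRUE(config$presso$enabled) && nrow(harm) >= 4) {
      pr <- mr_presso(harm, n_sim = config$presso$n_sim,
                      seed = config$presso$seed, sig = config$presso$sig)
      sens[[ex_id]] <- dplyr::bind_rows(
        sens[[ex_id]],
        glance(pr) |> dplyr::mutate(exposure_id = ex_id, analysis = "presso", .before = 1)
      )
      audit[[ex_id]]$presso_global_p <- pr$global_p
    }
    note("exposure %s: %d instruments, %d methods (%.2fs)",
         ex_id, nrow(harm), nrow(res),
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  report <- structure(
    list(results = dplyr::bind_rows(results),
         sensitivity = dplyr::bind_rows(sens),
         audit = audit, threshold = threshold,
         config_hash = config$hash, log = log_lines),
    class = "mr_report"
  )
  write_report(report, config)
  report
}

forward_threshold <- function(config) {
  if (is.null(config$corr_path)) return(NULL)
  corr <- as.matrix(readr::read_tsv(config$corr_path, show_col_types = FALSE,
                                    progress = FALSE)[, -1])
  meff <- effective_tests(corr)
  adjusted_threshold(config$alpha, meff)
}

#' Run the reverse MR workflow
#'
#' The configured outcome GWAS becomes the exposure (clumped against the
#' configured LD table at r^2 = 0.001, region/MAF exclusions applied) and
#' each configured "exposure" file is analysed in turn as an outcome with the
#' same instrument set and estimator battery.
#'
#' @inheritParams mr_run_forward
#' @return an `mr_report` (results rows carry `outcome_id` instead of
#'   per-exposure instruments).
#' @export
mr_run_reverse <- function(config) {
  config <- read_run_config(config)
  disease <- read_configured(config$outcome)
  dz_id <- config$outcome$id %||% "outcome"
  inst <- withCallingHandlers(
    select_instruments(disease, p_max = config$selection$p_max,
                       f_min = config$selection$f_min, maf_min = config$selection$maf_min,
                       min_snps = config$selection$min_snps, exposure_id = dz_id),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!is.null(config$ld_path)) {
    ld <- readr::read_tsv(config$ld_path, show_col_types = FALSE, progress = FALSE)
    inst <- suppressWarnings(ld_clump(inst, ld, r2_max = config$clump_r2 %||% 0.001))
  }
  for (r in resolve_regions(config$region_exclusions)) {
    inst <- exclude_region(inst, r$chrom, r$start, r$end)
  }
  audit <- list(instruments = c(attr(inst, "audit"), list(final = nrow(inst))))

  results <- list(); sens <- list()
  for (entry in config$exposures) {
    out_id <- entry$id %||% entry$path
    met <- read_configured(entry)
    harm <- suppressMessages(
      harmonize_pair(inst, met, palindrome_mode = config$palindrome_mode)
    )
    res <- mr_all_methods(harm, methods = config$methods,
                          n_boot = config$wmedian$n_boot, seed = config$wmedian$seed) |>
      dplyr::mutate(outcome_id = out_id, direction = "reverse", .before = 1)
    results[[out_id]] <- res
    sens[[out_id]] <- mr_leave_one_out(harm) |>
      dplyr::mutate(outcome_id = out_id, analysis = "leave-one-out", .before = 1)
    audit[[out_id]] <- list(harmonized = nrow(harm),
                            drops = nrow(attr(harm, "drops")))
  }
  report <- structure(
    list(results = dplyr::bind_rows(results),
         sensitivity = dplyr::bind_rows(sens),
         audit = audit, threshold = NULL,
         config_hash = config$hash, log = character(0)),
    class = "mr_report"
  )
  write_report(report, config, prefix = "reverse_")
  report
}

#' Run the pruning + model-averaging workflow
#'
#' Prunes exposures by genetic correlation (priority = univariable IVW |z|
#' against the outcome), harmonizes the survivors jointly, runs [mr_bma()],
#' computes instrument diagnostics for every model with posterior probability
#' above `config$bma$pp_min`, and, when diagnostics flag instruments,
#' re-runs the model average without them.
#'
#' @inheritParams mr_run_forward
#' @return an `mr_bma_report` list: `kept`, `bma`, `diagnostics`, `rerun`
#'   (NULL when nothing was flagged), `audit`. Writes `bma_mip_mace.tsv`,
#'   `bma_models.tsv`, `diagnostics.tsv` under `config$out_dir`.
#' @export
mr_run_bma <- function(config) {
  config <- read_run_config(config)
  outcome <- read_configured(config$outcome)
  exposures <- purrr::map(config$exposures, read_configured)
  names(exposures) <- purrr::map_chr(config$exposures, ~ .x$id %||% .x$path)

  rg <- read_rg_matrix(config$bma$rg_path)
  priority <- purrr::imap_dbl(exposures, function(tab, id) {
    inst <- withCallingHandlers(
      select_instruments(tab, p_max = config$selection$p_max,
                         f_min = config$selection$f_min,
                         maf_min = config$selection$maf_min,
                         min_snps = 1, exposure_id = id),
      warning = function(w) invokeRestart("muffleWarning")
    )
    harm <- suppressMessages(harmonize_pair(inst, outcome))
    if (nrow(harm) == 0) return(0)
    fit <- mr_ivw(harm)
    abs(fit$beta / fit$se)
  })
  kept <- prune_by_rg(rg[names(exposures), names(exposures)],
                      threshold = config$bma$rg_threshold, priority = priority)
  harm <- harmonize_multi(exposures[kept], outcome,
                          palindrome_mode = config$palindrome_mode)
  bma <- mr_bma(harm, prior_p = config$bma$prior_p, sigma2 = config$bma$sigma2,
                mode = config$bma$mode, z = config$bma$z, seed = config$bma$seed)
  top <- bma$models[bma$models$pp > config$bma$pp_min & bma$models$size > 0, ]
  diags <- purrr::map(top$model, function(m) {
    subset <- strsplit(m, "+", fixed = TRUE)[[1]]
    model_diagnostics(harm, subset) |>
      dplyr::mutate(model = m, .before = 1)
  })
  diagnostics <- dplyr::bind_rows(diags)
  flagged <- unique(diagnostics$snp_id[diagnostics$flag_q | diagnostics$flag_cd])
  rerun <- NULL
  if (length(flagged) > 0 &&
      length(harm$snp_id) - length(flagged) >= length(kept) + 2) {
    rerun <- rerun_without(harm, flagged,
                           prior_p = config$bma$prior_p, sigma2 = config$bma$sigma2,
                           mode = config$bma$mode, z = config$bma$z,
                           seed = config$bma$seed, before = bma)
  }
  report <- structure(
    list(kept = kept, bma = bma, diagnostics = diagnostics,
         rerun = rerun, flagged = flagged,
         audit = list(pruned = setdiff(names(exposures), kept),
                      priority = as.list(priority),
                      n_snp = length(harm$snp_id),
                      drops = harm$drops),
         config_hash = config$hash),
    class = "mr_bma_report"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(x) dplyr::mutate(x, config_hash = config$hash)
    readr::write_tsv(stamp(bma$exposures),
                     file.path(config$out_dir, "bma_mip_mace.tsv"), progress = FALSE)
    readr::write_tsv(stamp(bma$models[, c("model", "size", "pp")]),
                     file.path(config$out_dir, "bma_models.tsv"), progress = FALSE)
    if (nrow(diagnostics) > 0) {
      readr::write_tsv(stamp(diagnostics),
                       file.path(config$out_dir, "diagnostics.tsv"), progress = FALSE)
    }
    jsonlite::write_json(report$audit, file.path(config$out_dir, "bma_audit.json"),
                         auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
  }
  report
}

read_rg_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  rg <- as.matrix(tab[, -1])
  rownames(rg) <- as.character(tab[[1]])
  colnames(rg) <- names(tab)[-1]
  validate_rg(rg)
  rg
}

write_report <- function(report, config, prefix = "") {
  if (is.null(config$out_dir)) return(invisible(report))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(x) dplyr::mutate(x, config_hash = config$hash)
  if (nrow(report$results) > 0) {
    readr::write_tsv(stamp(report$results),
                     file.path(config$out_dir, paste0(prefix, "results.tsv")),
                     progress = FALSE)
  }
  if (nrow(report$sensitivity) > 0) {
    readr::write_tsv(stamp(report$sensitivity),
                     file.path(config$out_dir, paste0(prefix, "sensitivity.tsv")),
                     progress = FALSE)
  }
  jsonlite::write_json(
    list(config_hash = config$hash, audit = report$audit,
         threshold = report$threshold),
    file.path(config$out_dir, paste0(prefix, "audit.json")),
    auto_unbox = TRUE, pretty = TRUE, dataframe = "rows"
  )
  writeLines(report$log, file.path(config$out_dir, paste0(prefix, "run.log")))
  invisible(report)
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %d result row(s), %d sensitivity row(s) [config %s]\n",
              nrow(x$results), nrow(x$sensitivity), x$config_hash))
  invisible(x)
}
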
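# Multivariable MR by Bayesian model averaging (MR-BMA): genetic-correlation
# pruning of near-duplicate exposures, closed-form marginal likelihoods over
# exposure subsets, marginal inclusion probabilities (MIP) and model-averaged
# causal effects (MACE), and per-instrument influence diagnostics.

#' Prune exposures by genetic correlation
#'
#' Exposures whose pairwise genetic correlation exceeds `threshold` are
#' treated as non-independent (their instruments tag the same genetic
#' signal, which would induce multicollinearity in the multivariable model).
#' Iteratively, the most-correlated offending pair is found and its
#' lower-priority member dropped, until no off-diagonal correlation among the
#' kept exposures exceeds the threshold. Deterministic given the priority
#' scores; ties break lexicographically by exposure id (the smaller id is
#' kept).
#'
#' @param rg symmetric K x K genetic-correlation matrix with exposure-id
#'   dimnames (unit diagonal, entries in `[-1, 1]`).
#' @param threshold correlation bound (default 0.95).
#' @param priority named numeric vector of per-exposure scores (e.g. the
#'   univariable IVW |z| or the instrument count); higher is kept.
#' @return character vector of kept exposure ids, in the input order.
#' @export
prune_by_rg <- function(rg, threshold = 0.95, priority) {
  validate_rg(rg)
  ids <- rownames(rg)
  if (is.null(names(priority)) || !all(ids %in% names(priority))) {
    rlang::abort("prune_by_rg(): priority must be named and cover every exposure")
  }
  kept <- ids
  repeat {
    sub <- rg[kept, kept, drop = FALSE]
    off <- sub
    diag(off) <- -Inf
    if (all(off <= threshold)) break
    ij <- which(off == max(off), arr.ind = TRUE)[1, ]
    a <- kept[ij[1]]; b <- kept[ij[2]]
    drop <- if (priority[[a]] < priority[[b]]) a
    else if (priority[[b]] < priority[[a]]) b
    else max(a, b)  # tie: keep the lexicographically smaller id
    kept <- setdiff(kept, drop)
  }
  kept
}

validate_rg <- function(rg, tol = 1e-8) {
  if (!is.matrix(rg) || nrow(rg) != ncol(rg) || is.null(rownames(rg))) {
    rlang::abort("rg must be a square matrix with exposure-id dimnames")
  }
  if (max(abs(rg - t(rg))) > tol) rlang::abort("rg matrix is not symmetric")
  if (max(abs(rg)) > 1 + tol) rlang::abort("rg entries must lie in [-1, 1]")
  invisible(rg)
}

# Transform a multivariable harmonized dataset to the unit-variance scale:
# y = by/sy, X[, k] = bx[, k]/sy, columns scaled to unit norm so the effect
# prior variance is comparable across exposures. Returns y, X and the column
# scales needed to map estimates back to the per-SD scale.
bma_design <- function(data) {
  stopifnot(inherits(data, "mr_harmonized_multi"))
  y <- data$beta_outcome / data$se_outcome
  X <- data$beta_exposure / data$se_outcome
  scales <- sqrt(colSums(X^2))
  if (any(scales == 0)) rlang::abort("bma_design(): an exposure has all-zero instrument effects")
  X <- sweep(X, 2, scales, `/`)
  list(y = y, X = X, scales = scales, ids = data$exposure_ids)
}

#' Log marginal likelihood of one exposure subset
#'
#' Closed-form marginal likelihood of the weighted linear model
#' `by = X_S theta_S + eps`, `eps ~ N(0, sy^2)`, with independent normal
#' prior `theta_S ~ N(0, sigma2 I)` on the standardized scale. After scaling
#' both sides by `1/sy` the noise is unit-variance and
#' `log ML = -J/2 log(2 pi) - 1/2 log|I + sigma2 X X'| - 1/2 y'(I + sigma2 X X')^{-1} y`,
#' evaluated via the |S|-dimensional determinant/solve. The empty subset is
#' the null model `by = eps`.
#'
#' @param subset integer or character vector of exposure columns (possibly
#'   empty).
#' @param data an `mr_harmonized_multi`.
#' @param sigma2 prior effect variance (default 0.25).
#' @return the log marginal likelihood (a scalar).
#' @export
log_marginal_likelihood <- function(subset, data, sigma2 = 0.25) {
  d <- bma_design(data)
  lml_from_design(resolve_subset(subset, d$ids), d$y, d$X, sigma2)$lml
}

resolve_subset <- function(subset, ids) {
  if (length(subset) == 0) return(integer(0))
  if (is.character(subset)) {
    i <- match(subset, ids)
    if (anyNA(i)) rlang::abort("unknown exposure id in subset")
    i
  } else as.integer(subset)
}

lml_from_design <- function(s, y, X, sigma2) {
  J <- length(y)
  base <- -J / 2 * log(2 * pi)
  if (length(s) == 0) {
    return(list(lml = base - sum(y^2) / 2, theta = numeric(0)))
  }
  Xs <- X[, s, drop = FALSE]
  XtX <- crossprod(Xs)
  Xty <- crossprod(Xs, y)[, 1]
  A <- XtX + diag(1 / sigma2, length(s))
  cholA <- tryCatch(chol(A), error = function(e) {
    rlang::abort("log_marginal_likelihood(): singular penalized design (should not occur for sigma2 > 0)")
  })
  theta <- backsolve(cholA, forwardsolve(t(cholA), Xty))
  # log|I_J + sigma2 Xs Xs'| = log|A| + |S| log(sigma2)   (Sylvester)
  logdet <- 2 * sum(log(diag(cholA))) + length(s) * log(sigma2)
  quad <- sum(y^2) - sum(Xty * theta)
  list(lml = base - logdet / 2 - quad / 2, theta = theta)
}

#' Bayesian model averaging over multivariable MR models
#'
#' Iterates over candidate "true causal models" — subsets of the K exposures
#' — scoring each by its posterior probability
#' `pp(S) proportional to prior_p^|S| (1-prior_p)^(K-|S|) ML(S)`. Per
#' exposure, the marginal inclusion probability (MIP) sums pp over the models
#' containing it, and the model-averaged causal effect (MACE) averages the
#' posterior-mean conditional effect (zero when excluded), which shrinks
#' estimates toward the null. With `mode = "exhaustive"` (default for
#' `K <= 16`) all `2^K` subsets are enumerated and posterior probabilities
#' are exact; `mode = "shotgun"` runs a seeded stochastic search
#' (add/delete/swap proposals, `z` iterations) and normalizes over the
#' distinct models visited.
#'
#' @param data an `mr_harmonized_multi` with `K >= 2` exposures.
#' @param prior_p prior inclusion probability of each exposure (default 0.1).
#' @param sigma2 prior effect variance (default 0.25).
#' @param mode `"exhaustive"` or `"shotgun"`.
#' @param z stochastic-search iterations (default 10000; shotgun mode only).
#' @param seed RNG seed for the stochastic search.
#' @param max_model_size optional cap on |S| during the search.
#' @return an `mr_bma_result`: `exposures` tibble (`exposure_id`, `mip`,
#'   `mace`, ranked by descending MIP), `models` tibble (`model`, `size`,
#'   `pp`, list-column `estimates` of per-SD conditional effects), and
#'   `settings`.
#' @export
mr_bma <- function(data, prior_p = 0.1, sigma2 = 0.25,
                   mode = c("exhaustive", "shotgun"), z = 10000, seed = NULL,
                   max_model_size = NULL) {
  mode <- match.arg(mode)
  d <- bma_design(data)
  K <- ncol(d$X)
  if (K < 2) rlang::abort("mr_bma(): fewer than 2 exposures; use the univariable estimators instead")
  if (mode == "exhaustive" && K > 16) {
    rlang::abort("mr_bma(): exhaustive enumeration capped at K = 16; use mode = 'shotgun'")
  }
  score <- function(s) {
    fit <- lml_from_design(s, d$y, d$X, sigma2)
    lp <- length(s) * log(prior_p) + (K - length(s)) * log(1 - prior_p) + fit$lml
    list(logpp = lp, theta = fit$theta)
  }

  if (mode == "exhaustive") {
    subsets <- purrr::map(seq_len(2^K) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0))
    fits <- purrr::map(subsets, score)
  } else {
    visited <- new.env(parent = emptyenv())
    key_of <- function(s) paste(sort(s), collapse = ",")
    subsets <- list(); fits <- list()
    with_seed(seed, {
      cur <- integer(0)
      cur_fit <- score(cur)
      record <- function(s, f) {
        k <- paste0("m", key_of(s))
        if (!exists(k, envir = visited, inherits = FALSE)) {
          assign(k, TRUE, envir = visited)
          subsets[[length(subsets) + 1L]] <<- s
          fits[[length(fits) + 1L]] <<- f
        }
      }
      record(cur, cur_fit)
      for (it in seq_len(z)) {
        prop <- propose_subset(cur, K, max_model_size)
        if (is.null(prop)) next
        prop_fit <- score(prop)
        record(prop, prop_fit)
        if (log(stats::runif(1)) < prop_fit$logpp - cur_fit$logpp) {
          cur <- prop
          cur_fit <- prop_fit
        }
      }
    })
  }

  logpp <- purrr::map_dbl(fits, "logpp")
  pp <- exp(logpp - logsumexp(logpp))
  mip <- numeric(K)
  mace <- numeric(K)
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    if (length(s) == 0) next
    mip[s] <- mip[s] + pp[i]
    mace[s] <- mace[s] + pp[i] * fits[[i]]$theta / d$scales[s]
  }
  exposures <- tibble::tibble(exposure_id = d$ids, mip = mip, mace = mace) |>
    dplyr::arrange(dplyr::desc(.data$mip))
  ord <- order(pp, decreasing = TRUE)
  models <- tibble::tibble(
    model = purrr::map_chr(subsets[ord], ~ if (length(.x) == 0) "(null)" else paste(d$ids[.x], collapse = "+")),
    size = purrr::map_int(subsets[ord], length),
    pp = pp[ord],
    estimates = purrr::map(ord, function(i) {
      s <- subsets[[i]]
      stats::setNames(if (length(s)) fits[[i]]$theta / d$scales[s] else numeric(0),
                      d$ids[s])
    })
  )
  structure(
    list(exposures = exposures, models = models,
         settings = list(prior_p = prior_p, sigma2 = sigma2, mode = mode,
                         z = z, seed = seed, K = K, J = length(d$y),
                         n_models = length(subsets))),
    class = "mr_bma_result"
  )
}

propose_subset <- function(cur, K, max_model_size) {
  move <- sample(c("add", "delete", "swap"), 1)
  outside <- setdiff(seq_len(K), cur)
  cap <- max_model_size %||% K
  if (move == "add" && length(outside) > 0 && length(cur) < cap) {
    c(cur, outside[sample.int(length(outside), 1)])
  } else if (move == "delete" && length(cur) > 0) {
    cur[-sample.int(length(cur), 1)]
  } else if (move == "swap" && length(cur) > 0 && length(outside) > 0) {
    c(cur[-sample.int(length(cur), 1)], outside[sample.int(length(outside), 1)])
  } else NULL
}

#' @export
print.mr_bma_result <- function(x, n = 10, ...) {
  s <- x$settings
  cat(sprintf("<mr_bma_result> K = %d exposures, J = %d SNPs, %s mode (%d models scored)\n",
              s$K, s$J, s$mode, s$n_models))
  cat(sprintf("  prior_p = %g, sigma2 = %g\n", s$prior_p, s$sigma2))
  print(utils::head(x$exposures, n))
  invisible(x)
}

#' Tidy MR-BMA results: per-exposure MIP and MACE
#'
#' @param x an `mr_bma_result`.
#' @param ... unused.
#' @return the per-exposure tibble ranked by descending MIP.
#' @method tidy mr_bma_result
#' @export
tidy.mr_bma_result <- function(x, ...) x$exposures

#' @method glance mr_bma_result
#' @export
glance.mr_bma_result <- function(x, ...) {
  tibble::tibble(
    k = x$settings$K, n_snp = x$settings$J, mode = x$settings$mode,
    n_models = x$settings$n_models,
    top_model = x$models$model[1], top_pp = x$models$pp[1]
  )
}

#' Instrument diagnostics for one candidate model
#'
#' Fits the weighted (1/sy^2) linear model of outcome betas on the subset's
#' exposure betas without intercept and reports, per instrument, the
#' heterogeneity contribution `q_j = (by_j - fitted_j)^2 / sy_j^2` and the
#' leverage-based Cook's distance (equivalently the scaled shift in fitted
#' values on deleting the observation). Instruments with `q > q_max` or
#' `cd > cd_max` are flagged as outlying/influential.
#'
#' @param data an `mr_harmonized_multi`.
#' @param subset exposure ids or column indices defining the model.
#' @param q_max heterogeneity flag threshold (default 10).
#' @param cd_max Cook's-distance flag threshold; default `4/J`, the standard
#'   rule of thumb (0.19 at J = 21).
#' @return an `mr_model_diag` tibble: `snp_id`, `q`, `cd`, `flag_q`,
#'   `flag_cd`; attributes `model` and thresholds.
#' @export
model_diagnostics <- function(data, subset, q_max = 10, cd_max = NULL) {
  stopifnot(inherits(data, "mr_harmonized_multi"))
  s <- resolve_subset(subset, data$exposure_ids)
  if (length(s) == 0) rlang::abort("model_diagnostics(): subset must be non-empty")
  J <- length(data$beta_outcome)
  cd_max <- cd_max %||% (4 / J)
  df <- as.data.frame(data$beta_exposure[, s, drop = FALSE])
  names(df) <- paste0("x", seq_along(s))
  df$by <- data$beta_outcome
  fml <- stats::as.formula(paste("by ~ 0 +", paste(names(df)[seq_along(s)], collapse = " + ")))
  fit <- stats::lm(fml, data = df, weights = 1 / data$se_outcome^2)
  q <- (data$beta_outcome - stats::fitted(fit))^2 / data$se_outcome^2
  cd <- unname(stats::cooks.distance(fit))
  # Cook's distance is residual-scale-free, so a numerically exact fit
  # (residuals at machine precision) would return noise; call it zero
  if (!all(is.finite(cd)) || sum(q) < 1e-16 * sum((data$beta_outcome / data$se_outcome)^2)) {
    cd[] <- 0
  }
  out <- tibble::tibble(
    snp_id = data$snp_id, q = q, cd = cd,
    flag_q = q > q_max, flag_cd = cd > cd_max
  )
  structure(out,
            model = paste(data$exposure_ids[s], collapse = "+"),
            q_max = q_max, cd_max = cd_max,
            class = c("mr_model_diag", class(out)))
}

#' Re-run MR-BMA with instruments omitted
#'
#' Drops the given SNPs and refits; used after [model_diagnostics()] flags
#' influential instruments, to check whether rankings depend on them.
#'
#' @param data an `mr_harmonized_multi`.
#' @param snp_ids instruments to omit (empty vector reproduces the original).
#' @param ... passed to [mr_bma()].
#' @param before optional previous `mr_bma_result` to pair against.
#' @return an `mr_bma_result`; when `before` is given, an attribute
#'   `comparison` holds a tibble of before/after MIPs per exposure.
#' @export
rerun_without <- function(data, snp_ids, ..., before = NULL) {
  reduced <- drop_snps(data, snp_ids)
  K <- length(reduced$exposure_ids)
  if (length(reduced$snp_id) < K + 2) {
    rlang::abort(sprintf(
      "rerun_without(): %d SNP(s) remain for %d exposures; model unidentifiable",
      length(reduced$snp_id), K
    ))
  }
  out <- mr_bma(reduced, ...)
  if (!is.null(before)) {
    cmp <- dplyr::full_join(
      dplyr::rename(before$exposures, mip_before = "mip", mace_before = "mace"),
      dplyr::rename(out$exposures, mip_after = "mip", mace_after = "mace"),
      by = "exposure_id"
    )
    attr(out, "comparison") <- cmp
  }
  out
}
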
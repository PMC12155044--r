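# Maximum-likelihood estimation of the seroincidence rate lambda from the
# multi-biomarker cross-sectional likelihood, on the log scale.

#' Options controlling seroincidence estimation
#'
#' @param start_log_lambda Starting point of the search, natural log of the
#'   rate in events per person-year (default `log(0.1)`).
#' @param bounds Search bounds on log lambda, per person-year
#'   (default `c(log(1e-6), log(5))`).
#' @param tol Convergence tolerance on log lambda (default `1e-6`).
#' @param ci_method `"wald"` (default; symmetric interval on the log scale
#'   from the exact likelihood curvature) or `"profile"`
#'   (profile-likelihood interval by root finding).
#' @param cores Worker count for stratified estimation; results are
#'   identical for any value (cells are independent).
#' @param small_cell_n Observation count below which a small-sample warning
#'   is emitted (default 30; the estimate is still reported).
#' @param subsample_draws Optional number `K' <= K` of kinetics draws to use
#'   per antigen-isotype (seeded by `subsample_seed`), a fast path for large
#'   ensembles; default `NULL` uses all draws.
#' @param subsample_seed Seed for the draw subsample (default 1).
#' @param n_nodes,mode,include_rise Passed to [obs_model()].
#' @param verbose Emit progress messages (default `FALSE`).
#' @return A list of class `est_options`.
#' @export
est_options <- function(start_log_lambda = log(0.1),
                        bounds = c(log(1e-6), log(5)),
                        tol = 1e-6,
                        ci_method = c("wald", "profile"),
                        cores = 1L,
                        small_cell_n = 30L,
                        subsample_draws = NULL,
                        subsample_seed = 1L,
                        n_nodes = 4L,
                        mode = "full",
                        include_rise = TRUE,
                        verbose = FALSE) {
  stopifnot(length(bounds) == 2L, all(is.finite(bounds)), bounds[1] < bounds[2])
  if (start_log_lambda < bounds[1] || start_log_lambda > bounds[2])
    stop("start_log_lambda must lie within bounds")
  structure(list(
    start_log_lambda = start_log_lambda, bounds = bounds, tol = tol,
    ci_method = match.arg(ci_method), cores = as.integer(cores),
    small_cell_n = small_cell_n, subsample_draws = subsample_draws,
    subsample_seed = subsample_seed, n_nodes = n_nodes, mode = mode,
    include_rise = include_rise, verbose = verbose
  ), class = "est_options")
}

# nll, gradient and curvature in x = log(lambda per person-year), summed
# over precomputed blocks
.nll_derivs <- function(blocks, x) {
  ld <- exp(x) / 365.25
  nll <- 0; g_ld <- 0; h_ld <- 0
  ok <- TRUE
  for (b in blocks) {
    d <- .eval_block_deriv(b, ld)
    if (any(d$val <= 0) || any(!is.finite(d$val))) { ok <- FALSE; break }
    nll <- nll - sum(log(d$val))
    rat <- d$d1 / d$val
    g_ld <- g_ld - sum(rat)
    h_ld <- h_ld + sum(rat^2 - d$d2 / d$val)
  }
  if (!ok) return(list(nll = Inf, g = NaN, h = NaN))
  # chain rule: d(ld)/dx = ld
  list(nll = nll, g = ld * g_ld, h = ld^2 * h_ld + ld * g_ld)
}

# Safeguarded Newton search for the minimum of the nll in x within [lb, ub].
# Starting from x0, the bracket is grown by step doubling in the local
# descent direction until the gradient changes sign (the nll can be
# non-monotone far from the data-supported region, so the bound gradients
# are never trusted directly); Newton steps with bisection fallback then
# locate the stationary point inside the bracket. A point with
# non-finite/zero likelihood counts as uphill.
.mle_loglambda <- function(blocks, lb, ub, x0, tol = 1e-6) {
  x <- min(max(x0, lb), ub)
  d <- .nll_derivs(blocks, x)
  if (!is.finite(d$nll)) {
    for (xs in lb + (ub - lb) * c(0.25, 0.5, 0.1, 0.75)) {
      x <- xs; d <- .nll_derivs(blocks, x)
      if (is.finite(d$nll)) break
    }
    if (!is.finite(d$nll)) stop("likelihood not computable anywhere in bounds")
  }
  if (d$g < 0) {          # descend rightward
    lo <- x; d_lo <- d
    step <- 0.5
    repeat {
      if (lo >= ub - tol) return(list(x = ub, d = d_lo, boundary = "upper"))
      xr <- min(lo + step, ub)
      dr <- .nll_derivs(blocks, xr)
      uphill <- !is.finite(dr$nll) || dr$g >= 0
      if (uphill) { hi <- xr; d_hi <- dr; break }
      lo <- xr; d_lo <- dr; step <- 2 * step
    }
  } else {                # descend leftward
    hi <- x; d_hi <- d
    step <- 0.5
    repeat {
      if (hi <= lb + tol) return(list(x = lb, d = d_hi, boundary = "lower"))
      xl <- max(hi - step, lb)
      dl <- .nll_derivs(blocks, xl)
      uphill <- !is.finite(dl$nll) || dl$g <= 0
      if (uphill) { lo <- xl; d_lo <- dl; break }
      hi <- xl; d_hi <- dl; step <- 2 * step
    }
  }
  # bracket [lo, hi]: nll descends into it from both ends
  x <- if (is.finite(d_lo$g) && is.finite(d_hi$g) && d_hi$g > d_lo$g) {
    (lo * d_hi$g - hi * d_lo$g) / (d_hi$g - d_lo$g)   # secant first guess
  } else {
    (lo + hi) / 2
  }
  x <- min(max(x, lo), hi)
  for (it in seq_len(100L)) {
    d <- .nll_derivs(blocks, x)
    if (!is.finite(d$nll) || !is.finite(d$g)) {
      # shrink toward the better-behaved (lower) end
      if (d_lo$nll <= d_hi$nll) hi <- x else lo <- x
      x_new <- (lo + hi) / 2
    } else {
      if (d$g < 0) { lo <- x; d_lo <- d } else { hi <- x; d_hi <- d }
      x_new <- if (is.finite(d$h) && d$h > 0) x - d$g / d$h else (lo + hi) / 2
      if (x_new <= lo || x_new >= hi) x_new <- (lo + hi) / 2
    }
    if (abs(x_new - x) < tol || (hi - lo) < tol) { x <- x_new; break }
    x <- x_new
  }
  d <- .nll_derivs(blocks, x)
  list(x = x, d = d, boundary = "none")
}

# build one precomputed block per (antigen_iso x censoring kind)
.make_blocks <- function(pop, models) {
  blocks <- list()
  for (ai in names(models)) {
    m <- models[[ai]]
    rows <- which(pop$antigen_iso == ai)
    if (!length(rows)) next
    y <- pop$value[rows]; age <- pop$age[rows]
    i_lo <- y <= m$y_low
    i_hi <- y >= m$y_high & !i_lo
    i_mid <- !(i_lo | i_hi)
    if (any(i_mid))
      blocks[[paste0(ai, ".d")]] <-
        .pre_block("density", y[i_mid], age[i_mid], m)
    if (any(i_lo))
      blocks[[paste0(ai, ".lo")]] <-
        .pre_block("cdf", rep(m$y_low, sum(i_lo)), age[i_lo], m)
    if (any(i_hi))
      blocks[[paste0(ai, ".hi")]] <-
        .pre_block("surv", rep(m$y_high, sum(i_hi)), age[i_hi], m)
  }
  blocks
}

.subsample_sr <- function(sr, k, seed) {
  if (is.null(k)) return(sr)
  parts <- split(seq_len(nrow(sr)), sr$antigen_iso)
  set.seed(seed)
  keep <- unlist(lapply(parts, function(ix) {
    if (length(ix) <= k) ix else sort(sample(ix, k))
  }), use.names = FALSE)
  sr[sort(keep), , drop = FALSE]
}

#' Estimate the overall seroincidence rate
#'
#' Maximizes the multi-biomarker cross-sectional likelihood over
#' \eqn{x = \log \lambda} by a safeguarded Newton search within bounds,
#' using exact analytic first and second derivatives of the negative
#' log-likelihood. The standard error of \eqn{\log\hat\lambda} is
#' \eqn{1/\sqrt{d^2\mathrm{nll}/dx^2}} at the optimum and the default 95%
#' confidence interval is \eqn{\exp(\hat x \pm 1.96\,\mathrm{se})}.
#' `converged` is `FALSE` (with the estimate still reported) when the
#' optimum sits at a search bound or the curvature is non-positive --
#' typically a dataset with no signal (for example every value below the
#' biologic noise level).
#'
#' @param pop A `pop_data` object (or data frame with the same columns).
#' @param sr_params An `sr_params` object: kinetics parameter draws.
#' @param noise_params A `noise_params` object.
#' @param antigen_isos Biomarkers to combine (default: all shared between
#'   `pop` and `sr_params`). Records of the same subject for different
#'   biomarkers contribute independent likelihood terms.
#' @param opts An [est_options()] list.
#' @return A `seroincidence` object: point estimate, CI, standard error on
#'   the log scale, counts, convergence diagnostics and provenance.
#' @examples
#' cfg <- sim_config(lambda = 0.3, n_subjects = 150, seed = 11)
#' pop <- simulate_pop_data(cfg)
#' est <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params)
#' summary(est)
#' @export
est_seroincidence <- function(pop, sr_params, noise_params,
                              antigen_isos = NULL, opts = est_options()) {
  if (is.null(antigen_isos))
    antigen_isos <- intersect(unique(pop$antigen_iso),
                              unique(sr_params$antigen_iso))
  if (!length(antigen_isos)) stop("no antigen_isos to estimate from")
  suppressWarnings(validate_inputs(pop, sr_params, noise_params, antigen_isos))
  pop <- pop[pop$antigen_iso %in% antigen_isos, , drop = FALSE]
  if (nrow(pop) == 0L) stop("no observations for the requested antigen_isos")
  sr_params <- .subsample_sr(sr_params, opts$subsample_draws,
                             opts$subsample_seed)
  models <- .build_models(sr_params, noise_params, antigen_isos,
                          mode = opts$mode, include_rise = opts$include_rise,
                          n_nodes = opts$n_nodes)
  if (nrow(pop) < opts$small_cell_n)
    warning("only ", nrow(pop), " observations; estimate may be unstable",
            call. = FALSE)
  blocks <- .make_blocks(pop, models)
  fit <- .mle_loglambda(blocks, opts$bounds[1], opts$bounds[2],
                        opts$start_log_lambda, opts$tol)
  x_hat <- fit$x
  curv <- fit$d$h
  converged <- fit$boundary == "none" &&
    is.finite(curv) && curv > 0 &&
    x_hat > opts$bounds[1] + 10 * opts$tol &&
    x_hat < opts$bounds[2] - 10 * opts$tol
  se <- if (is.finite(curv) && curv > 0) 1 / sqrt(curv) else NA_real_
  ci <- if (opts$ci_method == "profile" && converged) {
    .profile_ci(blocks, x_hat, fit$d$nll, opts)
  } else if (is.finite(se)) {
    exp(x_hat + c(-1, 1) * 1.96 * se)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(
    log_lambda_hat = x_hat,
    se_log_lambda = se,
    lambda_hat = exp(x_hat),
    ci_low = ci[1], ci_high = ci[2],
    n_subjects = length(unique(pop$id)),
    n_observations = nrow(pop),
    antigen_isos = antigen_isos,
    stratum = list(),
    converged = converged,
    boundary = fit$boundary,
    nll_at_optimum = fit$d$nll,
    ci_method = opts$ci_method
  ), class = "seroincidence")
}

# profile-likelihood 95% CI by root finding on each side of the optimum
.profile_ci <- function(blocks, x_hat, nll_min, opts) {
  target <- nll_min + stats::qchisq(0.95, 1) / 2
  f <- function(x) .nll_derivs(blocks, x)$nll - target
  lo <- tryCatch(
    stats::uniroot(f, c(opts$bounds[1], x_hat), tol = opts$tol)$root,
    error = function(e) opts$bounds[1])
  hi <- tryCatch(
    stats::uniroot(f, c(x_hat, opts$bounds[2]), tol = opts$tol)$root,
    error = function(e) opts$bounds[2])
  exp(c(lo, hi))
}

#' @export
print.seroincidence <- function(x, ...) {
  cat("Seroincidence estimate",
      if (length(x$stratum)) paste0(" [",
        paste(names(x$stratum), unlist(x$stratum), sep = "=", collapse = ", "),
        "]"), "\n", sep = "")
  cat(sprintf("  biomarkers: %s\n", paste(x$antigen_isos, collapse = " + ")))
  cat(sprintf("  rate: %.1f per 1000 person-years (95%% CI %.1f-%.1f)\n",
              1000 * x$lambda_hat, 1000 * x$ci_low, 1000 * x$ci_high))
  cat(sprintf("  se(log lambda) = %.4f; n = %d subjects, %d observations\n",
              x$se_log_lambda, x$n_subjects, x$n_observations))
  if (!x$converged) cat("  WARNING: not converged (", x$boundary,
                        " boundary / curvature)\n", sep = "")
  invisible(x)
}

#' Summarize a seroincidence estimate as a one-row table
#'
#' @param object A `seroincidence` object.
#' @param ... Unused.
#' @return A tibble with the rate per 1000 person-years, CI bounds, standard
#'   error on the log scale, counts and the convergence flag.
#' @export
summary.seroincidence <- function(object, ...) {
  tibble::tibble(
    antigen_isos = paste(object$antigen_isos, collapse = "+"),
    rate_per_1000py = 1000 * object$lambda_hat,
    ci_low_per_1000py = 1000 * object$ci_low,
    ci_high_per_1000py = 1000 * object$ci_high,
    se_log_lambda = object$se_log_lambda,
    n_subjects = object$n_subjects,
    n_observations = object$n_observations,
    converged = object$converged
  )
}

#' Estimate stratified seroincidence rates
#'
#' Partitions the population data by the cross-product of the observed
#' values of one or more covariates and runs [est_seroincidence()]
#' independently in each cell. When the seroresponse ensemble carries
#' columns with the same names as strata covariates, each cell uses only its
#' matching draws (stratified kinetics); otherwise the common ensemble is
#' shared. Cells are independent, so running them on several workers gives
#' results identical to a serial run. Empty cells of the cross-product are
#' skipped with a warning.
#'
#' @inheritParams est_seroincidence
#' @param strata Character vector of covariate names present in `pop`.
#' @return A `seroincidence_by` object (list of `seroincidence` fits, in
#'   deterministic order sorted by stratum labels).
#' @export
est_seroincidence_by <- function(pop, sr_params, noise_params, strata,
                                 antigen_isos = NULL, opts = est_options()) {
  missing_cov <- setdiff(strata, names(pop))
  if (length(missing_cov))
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "))
  levs <- lapply(strata, function(s) sort(unique(as.character(pop[[s]]))))
  names(levs) <- strata
  cells <- expand.grid(levs, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[do.call(order, cells), , drop = FALSE]
  sr_strata <- intersect(strata, names(sr_params))
  run_cell <- function(i) {
    sel <- rep(TRUE, nrow(pop))
    for (s in strata) sel <- sel & as.character(pop[[s]]) == cells[i, s]
    if (!any(sel)) return(NULL)
    sr_i <- sr_params
    for (s in sr_strata) {
      keep <- as.character(sr_i[[s]]) == cells[i, s]
      if (any(keep)) sr_i <- sr_i[keep, , drop = FALSE]
    }
    est <- est_seroincidence(pop[sel, , drop = FALSE], sr_i, noise_params,
                             antigen_isos, opts)
    est$stratum <- as.list(cells[i, , drop = FALSE])
    est
  }
  idx <- seq_len(nrow(cells))
  fits <- if (opts$cores > 1L) {
    parallel::mclapply(idx, run_cell, mc.cores = opts$cores)
  } else {
    lapply(idx, run_cell)
  }
  empty <- vapply(fits, is.null, logical(1))
  if (any(empty))
    warning(sum(empty), " empty stratum cell(s) skipped", call. = FALSE)
  structure(list(estimates = fits[!empty], strata = strata),
            class = "seroincidence_by")
}

#' @export
print.seroincidence_by <- function(x, ...) {
  cat("Stratified seroincidence estimates (", length(x$estimates),
      " cells by ", paste(x$strata, collapse = " x "), ")\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' Summarize stratified estimates as a table
#'
#' One row per stratum cell, in deterministic order (sorted by stratum
#' labels); non-converged cells are flagged, not dropped.
#'
#' @param object A `seroincidence_by` object.
#' @param ... Unused.
#' @return A tibble: stratum columns, then the columns of
#'   [summary.seroincidence()].
#' @export
summary.seroincidence_by <- function(object, ...) {
  rows <- lapply(object$estimates, function(e) {
    cbind(tibble::as_tibble(e$stratum), summary(e))
  })
  do.call(rbind, rows)
}

#' Plot-ready long table of estimates
#'
#' Reshapes estimate summaries into (stratum, quantity, value) rows for
#' external plotting tools.
#'
#' @param x A `seroincidence` or `seroincidence_by` object.
#' @return A tibble with columns `stratum`, `quantity`, `value`.
#' @export
incidence_long_table <- function(x) {
  tab <- if (inherits(x, "seroincidence_by")) summary(x) else summary(x)
  strata <- if (inherits(x, "seroincidence_by")) x$strata else character(0)
  qty <- setdiff(names(tab), c(strata, "antigen_isos", "converged"))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    lab <- if (length(strata)) {
      paste(strata, vapply(strata, function(s) as.character(tab[[s]][i]),
                           character(1)), sep = "=", collapse = ",")
    } else "overall"
    tibble::tibble(stratum = lab, quantity = qty,
                   value = as.numeric(tab[i, qty]))
  })
  do.call(rbind, rows)
}
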
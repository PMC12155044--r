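# Generative model for synthetic serosurveys: the exact sampling counterpart
# of the likelihood's observation model, plus ensemble generation and
# parameter-recovery experiments. Simulator and likelihood share the
# kinetics and noise-kernel implementations, so one is the sampling form and
# the other the density form of the same model.

#' Synthetic kinetics centers emulating enteric-fever HlyE responses
#'
#' Central two-phase trajectory parameters for two synthetic biomarkers,
#' `HlyE_IgG` and `HlyE_IgA`, chosen to mimic the qualitative behaviour of
#' hemolysin E antibody responses after typhoidal infection: a rise to peak
#' within about ten days, IgG waning over several years, IgA waning faster.
#' These are this package's own synthetic stand-ins for an upstream
#' longitudinal model fit, usable as simulation defaults and in examples;
#' they are not estimates from any real cohort.
#'
#' @return A tibble with columns `antigen_iso, y0, y1, t1, alpha, r`
#'   (units: concentrations in ELISA units, times in days,
#'   `alpha` in units^(1-r)/day).
#' @export
synthetic_sr_centers <- function() {
  tibble::tibble(
    antigen_iso = c("HlyE_IgG", "HlyE_IgA"),
    y0 = c(1.0, 0.8),
    y1 = c(150, 80),
    t1 = c(10.5, 9.5),
    alpha = c(0.0012, 0.0020),
    r = c(1.30, 1.35)
  )
}

#' Synthetic noise parameters for the default simulated assay
#'
#' @return A `noise_params` tibble for the two synthetic biomarkers of
#'   [synthetic_sr_centers()]: biologic noise around 1.5-2 ELISA units,
#'   20% assay CV, quantification limits 0.2 and 5000.
#' @export
synthetic_noise_params <- function() {
  as_noise_params(tibble::tibble(
    antigen_iso = c("HlyE_IgG", "HlyE_IgA"),
    nu = c(1.5, 2.0),
    eps = c(0.2, 0.2),
    y_low = c(0.2, 0.2),
    y_high = c(5000, 5000)
  ))
}

#' Generate a synthetic seroresponse parameter ensemble
#'
#' Disperses each kinetics parameter lognormally around a central value
#' (mean-preserving, with the given coefficient of variation), emulating
#' draws from the predictive posterior of an upstream within-host model.
#' The decay shape is dispersed on the `r - 1` scale so `r >= 1` is
#' preserved exactly (a center at `r = 1` yields all draws exactly 1);
#' `y1 > y0` is enforced by rejection.
#'
#' @param center One-row data frame (or coercible) with
#'   `antigen_iso, y0, y1, t1, alpha, r`.
#' @param cv Named numeric vector of coefficients of variation for
#'   `y0, y1, t1, alpha, r` (the `r` entry disperses `r - 1`).
#' @param K Number of draws (>= 1).
#' @param seed Integer seed; fixes the ensemble exactly.
#' @return An `sr_params` tibble with `K` rows.
#' @export
simulate_sr_ensemble <- function(center,
                                 cv = c(y0 = 0.3, y1 = 0.3, t1 = 0.1,
                                        alpha = 0.3, r = 0.2),
                                 K = 50L, seed = 1L) {
  center <- as.data.frame(center)
  stopifnot(nrow(center) == 1L, K >= 1L, all(cv >= 0))
  set.seed(seed)
  ln_draw <- function(ctr, cvx, K) {
    if (cvx == 0) return(rep(ctr, K))
    s <- sqrt(log1p(cvx^2))
    ctr * exp(stats::rnorm(K, -s^2 / 2, s))
  }
  y0 <- ln_draw(center$y0, cv[["y0"]], K)
  y1 <- ln_draw(center$y1, cv[["y1"]], K)
  proposals <- K
  while (any(bad <- y1 <= y0)) {
    nb <- sum(bad)
    proposals <- proposals + nb
    y0[bad] <- ln_draw(center$y0, cv[["y0"]], nb)
    y1[bad] <- ln_draw(center$y1, cv[["y1"]], nb)
    if (proposals > 1000 && K / proposals < 0.01)
      stop("y1 > y0 rejection rate above 99%: incoherent ensemble config")
  }
  r <- if (center$r > 1) 1 + ln_draw(center$r - 1, cv[["r"]], K) else rep(1, K)
  as_sr_params(tibble::tibble(
    antigen_iso = center$antigen_iso,
    y0 = y0, y1 = y1,
    t1 = ln_draw(center$t1, cv[["t1"]], K),
    alpha = ln_draw(center$alpha, cv[["alpha"]], K),
    r = r
  ))
}

#' Configuration of a synthetic cross-sectional serosurvey
#'
#' Bundles the true seroincidence rate, sample size, age range, biomarkers
#' with their kinetics ensembles and noise parameters, and the seed. The
#' defaults describe the package's reference simulated survey: two
#' HlyE-like biomarkers, ages uniform on 2-15 years (the age span typical
#' of pediatric enteric-fever serosurveys), 50-draw ensembles.
#'
#' @param lambda True seroincidence rate, events per person-year.
#' @param n_subjects Number of surveyed subjects (>= 1).
#' @param age_range Length-2 numeric, min/max age in years (uniform ages).
#' @param antigen_isos Biomarkers to simulate.
#' @param sr_params Kinetics ensemble (`sr_params`); default: synthetic
#'   ensembles of `K` draws around [synthetic_sr_centers()].
#' @param noise_params Noise parameters; default
#'   [synthetic_noise_params()].
#' @param K Draws per biomarker for the default ensembles (ignored when
#'   `sr_params` is supplied).
#' @param seed Integer seed fixing the full simulated output.
#' @param apply_censoring Clamp simulated values to the quantification
#'   limits (default `TRUE`).
#' @param share_tau Share one infection history across a subject's
#'   biomarkers (`TRUE` mirrors one infection clock driving all antibodies;
#'   `FALSE`, the default, draws independent histories per biomarker and is
#'   exactly self-consistent with the likelihood's independence assumption).
#' @return A `sim_config` list.
#' @export
sim_config <- function(lambda = 0.2, n_subjects = 1000L,
                       age_range = c(2, 15),
                       antigen_isos = c("HlyE_IgG", "HlyE_IgA"),
                       sr_params = NULL, noise_params = NULL,
                       K = 50L, seed = 1L,
                       apply_censoring = TRUE, share_tau = FALSE) {
  stopifnot(lambda > 0, n_subjects >= 1L,
            length(age_range) == 2L, age_range[1] > 0,
            age_range[1] < age_range[2])
  if (is.null(sr_params)) {
    centers <- synthetic_sr_centers()
    centers <- centers[centers$antigen_iso %in% antigen_isos, , drop = FALSE]
    if (nrow(centers) < length(antigen_isos))
      stop("no synthetic center for: ",
           paste(setdiff(antigen_isos, centers$antigen_iso), collapse = ", "),
           " -- supply sr_params explicitly")
    parts <- lapply(seq_len(nrow(centers)), function(i)
      simulate_sr_ensemble(centers[i, ], K = K, seed = seed + 1000L + i))
    sr_params <- do.call(rbind, parts)
  }
  if (is.null(noise_params)) noise_params <- synthetic_noise_params()
  structure(list(
    lambda = lambda, n_subjects = as.integer(n_subjects),
    age_range = age_range, antigen_isos = antigen_isos,
    sr_params = sr_params, noise_params = noise_params,
    seed = as.integer(seed), apply_censoring = apply_censoring,
    share_tau = share_tau
  ), class = "sim_config")
}

# inverse-CDF sample of the time since the most recent infection, truncated
# at age (exact, no rejection)
.rtrunc_exp <- function(u, ld, a_d) -log1p(u * expm1(-ld * a_d)) / ld

#' Simulate a cross-sectional serosurvey
#'
#' Draws, for each subject: a uniform age; never-infected status with
#' probability \eqn{e^{-\lambda a}}; otherwise a time since the most recent
#' seroconversion from the exponential truncated at age (exact inverse-CDF
#' sampling). For each biomarker one kinetics draw is picked uniformly from
#' the ensemble, the trajectory evaluated at the latent time (0 when never
#' infected), and the observation composed as
#' \eqn{Y = (y_{\mathrm{model}} + B)E} with \eqn{B \sim U(0,\nu)} and
#' \eqn{E} lognormal mean-1 with CV \eqn{\epsilon}. With
#' `apply_censoring`, values are clamped to the quantification limits.
#'
#' The sampling order is fixed (ages; infection history; then per biomarker
#' in configured order: history if unshared, draw index, B, E), so a seed
#' reproduces the output exactly.
#'
#' @param config A [sim_config()] object.
#' @return A `pop_data` tibble with attributes `truth` (per id and
#'   biomarker: latent time since infection and ever-infected flag) and
#'   `n_censored_low`/`n_censored_high` (clamp counts).
#' @export
simulate_pop_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  ld <- config$lambda / 365.25
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  a_d <- age * 365.25
  draw_history <- function() {
    inf <- stats::runif(n) < -expm1(-ld * a_d)
    tau <- .rtrunc_exp(stats::runif(n), ld, a_d)
    list(inf = inf, tau = ifelse(inf, tau, NA_real_))
  }
  hist_shared <- if (config$share_tau) draw_history() else NULL
  ids <- sprintf("S%05d", seq_len(n))
  out <- vector("list", length(config$antigen_isos))
  truth <- vector("list", length(config$antigen_isos))
  ncl <- 0L; nch <- 0L
  for (j in seq_along(config$antigen_isos)) {
    ai <- config$antigen_isos[j]
    hist <- if (config$share_tau) hist_shared else draw_history()
    sr <- config$sr_params[config$sr_params$antigen_iso == ai, , drop = FALSE]
    if (nrow(sr) == 0L) stop("no kinetics draws for '", ai, "'")
    np <- config$noise_params[config$noise_params$antigen_iso == ai, ,
                              drop = FALSE]
    if (nrow(np) != 1L) stop("need one noise-parameter row for '", ai, "'")
    idx <- sample.int(nrow(sr), n, replace = TRUE)
    m <- numeric(n)
    ii <- which(hist$inf)
    if (length(ii))
      m[ii] <- antibody_level(hist$tau[ii], sr$y0[idx[ii]], sr$y1[idx[ii]],
                              sr$t1[idx[ii]], sr$alpha[idx[ii]], sr$r[idx[ii]])
    B <- stats::runif(n, 0, np$nu)
    E <- if (np$eps > 0) {
      s <- .sigma_of_eps(np$eps)
      stats::rlnorm(n, -s^2 / 2, s)
    } else rep(1, n)
    y <- (m + B) * E
    if (config$apply_censoring) {
      ncl <- ncl + sum(y < np$y_low)
      nch <- nch + sum(y > np$y_high)
      y <- pmin(pmax(y, np$y_low), np$y_high)
    }
    out[[j]] <- data.frame(id = ids, age = age, antigen_iso = ai, value = y,
                           stringsAsFactors = FALSE)
    truth[[j]] <- tibble::tibble(id = ids, antigen_iso = ai,
                                 ever_infected = hist$inf, tau = hist$tau)
  }
  pop <- as_pop_data(do.call(rbind, out))
  attr(pop, "truth") <- do.call(rbind, truth)
  attr(pop, "n_censored_low") <- ncl
  attr(pop, "n_censored_high") <- nch
  pop
}

#' Parameter-recovery and coverage experiment
#'
#' For each rate in `lambda_grid`, simulates `reps` independent surveys of
#' `n` subjects (seeds derived deterministically from the base config's
#' seed), estimates the rate from each, and tabulates the mean and SD of
#' the estimates, the relative bias, and the empirical coverage of the 95%
#' confidence interval. Estimation failures are recorded as flagged rows;
#' the grid never aborts.
#'
#' @param lambda_grid Numeric vector of true rates (events/person-year).
#' @param n Subjects per simulated survey.
#' @param reps Replicates per rate (>= 1).
#' @param base_config A [sim_config()] supplying biomarkers, ensembles,
#'   noise, ages and the base seed.
#' @param opts [est_options()] used for every fit.
#' @return A tibble with one row per rate: `lambda_true, reps, n_failed,
#'   mean_lambda_hat, sd_lambda_hat, rel_bias, coverage`; the per-replicate
#'   results are in attribute `details`.
#' @export
recovery_experiment <- function(lambda_grid, n, reps, base_config,
                                opts = est_options()) {
  if (reps < 1) stop("reps must be >= 1")
  det <- list()
  for (i in seq_along(lambda_grid)) {
    lt <- lambda_grid[i]
    for (j in seq_len(reps)) {
      cfg <- base_config
      cfg$lambda <- lt
      cfg$n_subjects <- as.integer(n)
      cfg$seed <- base_config$seed + 7919L * (i - 1L) + (j - 1L)
      row <- tryCatch({
        pop <- simulate_pop_data(cfg)
        est <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params,
                                 cfg$antigen_isos, opts)
        tibble::tibble(lambda_true = lt, rep = j,
                       lambda_hat = est$lambda_hat,
                       ci_low = est$ci_low, ci_high = est$ci_high,
                       converged = est$converged, failed = FALSE)
      }, error = function(e) {
        tibble::tibble(lambda_true = lt, rep = j, lambda_hat = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       converged = FALSE, failed = TRUE)
      })
      det[[length(det) + 1L]] <- row
    }
  }
  det <- do.call(rbind, det)
  summ <- lapply(lambda_grid, function(lt) {
    d <- det[det$lambda_true == lt & !det$failed, , drop = FALSE]
    tibble::tibble(
      lambda_true = lt,
      reps = reps,
      n_failed = sum(det$lambda_true == lt & det$failed),
      mean_lambda_hat = mean(d$lambda_hat),
      sd_lambda_hat = stats::sd(d$lambda_hat),
      rel_bias = mean(d$lambda_hat) / lt - 1,
      coverage = mean(d$ci_low <= lt & lt <= d$ci_high)
    )
  })
  out <- do.call(rbind, summ)
  attr(out, "details") <- det
  out
}
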
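#' Cross-sectional density of an observed antibody value
#'
#' Density (or censored probability mass) of one measured antibody value
#' given the seroincidence rate, marginalized over the latent time since the
#' most recent seroconversion and the kinetics parameter ensemble:
#' \deqn{p(y \mid \lambda, a) = e^{-\lambda a}\, p(y \mid m = 0)
#'   + \int_0^a \lambda e^{-\lambda \tau} \frac{1}{K} \sum_{k=1}^K
#'     p\left(y \mid f_{\theta_k}(\tau)\right)\, d\tau,}
#' where \eqn{a} is the subject's age, \eqn{f_\theta} the two-phase
#' trajectory ([antibody_level()]) and \eqn{p(y \mid m)} the closed-form
#' noise kernel of `Y = (m + B) E`. Ages are converted to days and
#' \eqn{\lambda} from per person-year to per person-day internally.
#'
#' Values at or outside the quantification limits are treated as censored:
#' for `y <= y_low` the returned quantity is the probability mass
#' \eqn{P(Y \le y_{\mathrm{low}})}, for `y >= y_high` it is
#' \eqn{P(Y \ge y_{\mathrm{high}})}.
#'
#' @param y Numeric vector of observed antibody concentrations.
#' @param age Numeric vector of ages in years (recycled against `y`).
#' @param lambda Seroincidence rate in events per person-year (positive
#'   scalar).
#' @param model An [obs_model()] object.
#' @return Numeric vector of densities / censored masses, same length as `y`.
#' @examples
#' sr <- data.frame(antigen_iso = "A", y0 = 1, y1 = 100, t1 = 10,
#'                  alpha = 0.01, r = 2)
#' np <- data.frame(antigen_iso = "A", nu = 1, eps = 0.2,
#'                  y_low = 0.1, y_high = 5000)
#' m <- obs_model(sr, np, "A")
#' obs_density(3.0, age = 10, lambda = 0.2, model = m)
#' @export
obs_density <- function(y, age, lambda, model) {
  if (!inherits(model, "obs_model")) stop("model must be an obs_model")
  if (length(lambda) != 1L || lambda <= 0) stop("lambda must be a positive scalar")
  if (any(age <= 0)) stop("age must be > 0")
  n <- length(y)
  age <- rep_len(age, n)
  out <- numeric(n)
  i_lo <- which(y <= model$y_low)
  i_hi <- which(y >= model$y_high & y > model$y_low)
  i_mid <- setdiff(seq_len(n), c(i_lo, i_hi))
  if (length(i_mid))
    out[i_mid] <- .eval_block(
      .pre_block("density", y[i_mid], age[i_mid], model), lambda)
  if (length(i_lo))
    out[i_lo] <- .eval_block(
      .pre_block("cdf", rep(model$y_low, length(i_lo)), age[i_lo], model), lambda)
  if (length(i_hi))
    out[i_hi] <- .eval_block(
      .pre_block("surv", rep(model$y_high, length(i_hi)), age[i_hi], model), lambda)
  out
}

#' Model distribution function of an observed antibody value
#'
#' \eqn{P(Y \le q \mid \lambda, a)} under the same observation model as
#' [obs_density()] (no censoring applied: the CDF of the raw measured
#' value). Useful for goodness-of-fit checks against simulated or observed
#' empirical distributions.
#'
#' @param q Numeric vector of quantile points (concentrations, > 0).
#' @inheritParams obs_density
#' @return Numeric vector of probabilities.
#' @export
obs_cdf <- function(q, age, lambda, model) {
  if (!inherits(model, "obs_model")) stop("model must be an obs_model")
  if (length(lambda) != 1L || lambda <= 0) stop("lambda must be a positive scalar")
  n <- length(q)
  age <- rep_len(age, n)
  pmin(1, pmax(0, .eval_block(.pre_block("cdf", q, age, model), lambda)))
}

#' Closed-form cross-sectional density in the noise-free, decay-only limit
#'
#' Analytic density of the observed value for a single kinetics draw when
#' there is no measurement noise, the biologic noise is negligible, and the
#' latent trajectory is restricted to the decay branch. By change of
#' variables through \eqn{dy/d\tau = -\alpha y^r},
#' \deqn{p(y \mid \lambda) = \frac{\lambda\, e^{-\lambda \tau(y)}}{\alpha y^r},}
#' with \eqn{\tau(y)} from [time_to_level()], valid on the attainable decay
#' range \eqn{f(a) < y < y_1}; outside that range the density is 0 (not an
#' error). The remaining probability is the atom \eqn{e^{-\lambda a}} on
#' "never infected" plus the rise-phase mass \eqn{1 - e^{-\lambda t_1}}.
#' This function is the independent oracle for the quadrature path of
#' [obs_density()].
#'
#' @param y Numeric vector of concentrations.
#' @param age Age in years (scalar or vector).
#' @param lambda Seroincidence rate in events per person-year.
#' @param y0,y1,t1,alpha,r Kinetics parameters of the single draw.
#' @return Numeric vector of densities (per concentration unit).
#' @export
closed_form_density_no_noise <- function(y, age, lambda, y0, y1, t1, alpha, r) {
  ld <- lambda / 365.25
  a_d <- age * 365.25
  f_a <- antibody_level(pmax(a_d, t1), y0, y1, t1, alpha, r)
  ok <- y > f_a & y < y1 & a_d > t1
  out <- numeric(length(y))
  if (any(ok)) {
    tau <- time_to_level(y[ok], y0, y1, t1, alpha, r)
    out[ok] <- ld * exp(-ld * tau) / (alpha * y[ok]^r)
  }
  out
}

# Build one obs_model per requested antigen_iso
.build_models <- function(sr_params, noise_params, antigen_isos, ...) {
  setNames(
    lapply(antigen_isos, function(ai)
      obs_model(sr_params, noise_params, ai, ...)),
    antigen_isos
  )
}

# lambda-independent precomputation for a whole population dataset:
# returns function(lambda) -> per-record densities/masses (pop row order)
.nll_factory <- function(pop, models) {
  pop <- as.data.frame(pop)
  keep <- pop$antigen_iso %in% names(models)
  pop <- pop[keep, , drop = FALSE]
  if (nrow(pop) == 0L) stop("no observations for the requested antigen_iso(s)")
  blocks <- list()
  idx <- list()
  for (ai in names(models)) {
    m <- models[[ai]]
    rows <- which(pop$antigen_iso == ai)
    if (!length(rows)) next
    y <- pop$value[rows]
    age <- pop$age[rows]
    i_lo <- rows[y <= m$y_low]
    i_hi <- rows[y >= m$y_high & y > m$y_low]
    i_mid <- setdiff(rows, c(i_lo, i_hi))
    if (length(i_mid)) {
      blocks[[paste0(ai, ".d")]] <- .pre_block(
        "density", pop$value[i_mid], pop$age[i_mid], m)
      idx[[paste0(ai, ".d")]] <- i_mid
    }
    if (length(i_lo)) {
      blocks[[paste0(ai, ".lo")]] <- .pre_block(
        "cdf", rep(m$y_low, length(i_lo)), pop$age[i_lo], m)
      idx[[paste0(ai, ".lo")]] <- i_lo
    }
    if (length(i_hi)) {
      blocks[[paste0(ai, ".hi")]] <- .pre_block(
        "surv", rep(m$y_high, length(i_hi)), pop$age[i_hi], m)
      idx[[paste0(ai, ".hi")]] <- i_hi
    }
  }
  n <- nrow(pop)
  pop_ids <- if (!is.null(pop$id)) pop$id else as.character(seq_len(n))
  pop_ai <- pop$antigen_iso
  function(lambda) {
    val <- rep(NA_real_, n)
    for (nm in names(blocks)) val[idx[[nm]]] <- .eval_block(blocks[[nm]], lambda)
    attr(val, "ids") <- pop_ids
    attr(val, "antigen_iso") <- pop_ai
    val
  }
}

#' Multi-biomarker negative log-likelihood of the seroincidence rate
#'
#' Negative sum of log [obs_density()] values over all records of a
#' cross-sectional dataset, using one observation model per antigen-isotype.
#' Records of the same subject for different biomarkers contribute
#' independent additive terms (the working independence assumption that lets
#' likelihoods from multiple antibodies and antigens be summed).
#'
#' @param lambda Seroincidence rate in events per person-year (positive
#'   scalar).
#' @param pop A `pop_data` object or data frame with columns
#'   `age, antigen_iso, value` (and optionally `id`).
#' @param models Named list of [obs_model()] objects, one per antigen-isotype
#'   to include; records with other antigen-isotypes are ignored.
#' @return The negative log-likelihood (scalar). Errors if any record has
#'   zero density under the model, naming the record: this signals
#'   model/data incompatibility (for example a value above the attainable
#'   range with no measurement noise).
#' @export
neg_log_lik <- function(lambda, pop, models) {
  dens_fun <- .nll_factory(pop, models)
  dens <- dens_fun(lambda)
  if (any(dens <= 0)) {
    bad <- which(dens <= 0)[1L]
    stop(sprintf(
      "observation id '%s' (%s) has zero density under the model at lambda = %g",
      attr(dens, "ids")[bad], attr(dens, "antigen_iso")[bad], lambda
    ))
  }
  -sum(log(dens))
}
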
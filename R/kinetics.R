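#' Two-phase antibody trajectory after seroconversion
#'
#' Deterministic antibody concentration \eqn{t} days after seroconversion for
#' one set of kinetics parameters. The trajectory rises log-linearly from the
#' baseline `y0` to the peak `y1` over `t1` days,
#' \deqn{y(t) = y_0 e^{\mu t}, \quad \mu = \log(y_1/y_0)/t_1, \quad 0 \le t \le t_1,}
#' then decays as the solution of \eqn{dy/dt = -\alpha y^r} started at
#' \eqn{y_1}:
#' \deqn{y(t) = y_1\left[1 + (r-1)\,\alpha\, y_1^{\,r-1}(t-t_1)\right]^{-1/(r-1)}}
#' for \eqn{r > 1}, and \eqn{y(t) = y_1 e^{-\alpha (t-t_1)}} for \eqn{r = 1}.
#' The two branches are continuous at `t1` (a point assigned to the rise
#' branch) and the value is strictly positive for all finite `t`.
#'
#' Note that the physical unit of `alpha` depends on `r`: it is
#' concentration\eqn{^{1-r}}/day. Rescaling concentrations by a factor
#' \eqn{s} therefore requires rescaling `alpha` by \eqn{s^{1-r}}. No
#' automatic rescaling is performed.
#'
#' @param t Numeric vector of times since seroconversion, in days
#'   (non-negative).
#' @param y0,y1,t1,alpha,r Kinetics parameters: baseline concentration,
#'   peak concentration (`y1 > y0 > 0`), time to peak in days, decay rate
#'   (concentration^(1-r)/day) and decay shape (`r >= 1`). Scalars or
#'   vectors recycled against `t`.
#' @return Numeric vector of antibody concentrations.
#' @seealso [time_to_level()] for the inverse on the decay branch.
#' @examples
#' antibody_level(c(0, 10, 110), y0 = 1, y1 = 100, t1 = 10, alpha = 0.01, r = 2)
#' @export
antibody_level <- function(t, y0, y1, t1, alpha, r) {
  if (any(t < 0)) stop("t must be >= 0")
  mu <- log(y1 / y0) / t1
  rise <- y0 * exp(mu * t)
  d <- r - 1
  dt <- pmax(t - t1, 0)
  # log1p/exp form is stable as r -> 1+; exact exponential branch at r = 1
  sel <- (dt * 0 + d) < 1e-12   # broadcast r against t
  decay <- ifelse(sel,
    y1 * exp(-alpha * dt),
    y1 * exp(-log1p(d * alpha * exp(d * log(y1)) * dt) / pmax(d, 1e-300))
  )
  ifelse(t <= t1, rise, decay)
}

#' Time at which the decay branch reaches a given antibody level
#'
#' Inverse of [antibody_level()] restricted to the decay branch: the unique
#' \eqn{\tau \ge t_1} with \eqn{y(\tau) = y}. For \eqn{r > 1},
#' \deqn{\tau = t_1 + \frac{y^{1-r} - y_1^{1-r}}{\alpha (r-1)},}
#' and for \eqn{r = 1}, \eqn{\tau = t_1 + \log(y_1/y)/\alpha}.
#'
#' @param y Numeric vector of concentrations, `0 < y <= y1`.
#' @inheritParams antibody_level
#' @return Numeric vector of times in days (`>= t1`).
#' @examples
#' time_to_level(100 / 101, y0 = 1, y1 = 100, t1 = 10, alpha = 0.01, r = 2)
#' @export
time_to_level <- function(y, y0, y1, t1, alpha, r) {
  if (any(y <= 0) || any(y > y1 * (1 + 1e-12)))
    stop("y must satisfy 0 < y <= y1 (level never attained on decay branch)")
  y <- pmin(y, y1)
  d <- r - 1
  # (y^{-d} - y1^{-d})/(alpha d) via expm1 for stability as r -> 1+
  sel <- (y * 0 + d) < 1e-12   # broadcast r against y
  ifelse(sel,
    t1 + log(y1 / y) / alpha,
    t1 + (expm1(-d * log(y)) - expm1(-d * log(y1))) / (alpha * pmax(d, 1e-300))
  )
}

# log-linear growth rate of the rise phase
.rise_rate <- function(y0, y1, t1) log(y1 / y0) / t1

#' Ensemble trajectory quantiles over a time grid
#'
#' Summarizes the predictive uncertainty of the seroresponse ensemble as
#' pointwise quantiles of the trajectory across draws, per antigen-isotype
#' -- a plot-ready long table of the modelled antibody decay curve.
#'
#' @param sr_params An `sr_params` object (see [as_sr_params()]).
#' @param times Numeric vector of days since seroconversion (default: a
#'   log-spaced grid from 0 to 5 years).
#' @param probs Quantile probabilities across draws (default median and
#'   80% band).
#' @return A tibble with columns `antigen_iso`, `time_days`, `quantile`,
#'   `value` (concentration units).
#' @examples
#' sr <- simulate_sr_ensemble(synthetic_sr_centers()[1, ], K = 20, seed = 1)
#' head(sr_curve_table(sr, times = c(0, 10, 30, 365)))
#' @export
sr_curve_table <- function(sr_params,
                           times = c(0, exp(seq(log(1), log(5 * 365.25),
                                                length.out = 60))),
                           probs = c(0.1, 0.5, 0.9)) {
  sr <- as.data.frame(sr_params)
  out <- lapply(unique(sr$antigen_iso), function(ai) {
    g <- sr[sr$antigen_iso == ai, , drop = FALSE]
    traj <- vapply(seq_len(nrow(g)), function(k)
      antibody_level(times, g$y0[k], g$y1[k], g$t1[k], g$alpha[k], g$r[k]),
      numeric(length(times)))
    qs <- apply(matrix(traj, nrow = length(times)), 1, stats::quantile,
                probs = probs)
    tibble::tibble(
      antigen_iso = ai,
      time_days = rep(times, each = length(probs)),
      quantile = rep(probs, times = length(times)),
      value = as.numeric(qs)
    )
  })
  do.call(rbind, out)
}
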
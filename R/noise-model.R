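# Closed-form observation kernel for the noise model
#
#   Y = (m + B) * E,   B ~ Uniform(0, nu),   E ~ LogNormal(-sigma^2/2, sigma)
#
# where m is the model antibody level (0 for never-infected subjects) and
# sigma^2 = log(1 + eps^2), so E has mean 1 and coefficient of variation eps.
# Both the density of Y and its CDF integrate over B in closed form:
# the inner lognormal density/CDF integrates against ds on (m, m + nu) to a
# difference of normal CDFs after completing the square. These kernels are
# the single source of truth shared by the likelihood and the simulator.

# sigma of the lognormal measurement-noise factor for a given CV
.sigma_of_eps <- function(eps) sqrt(log1p(eps^2))

# p(y | m): density of Y at y given model level m (vectorized over y, m).
# For sigma = 0 this is the uniform density 1/nu on (m, m + nu].
.pmeas_density <- function(y, m, nu, sigma) {
  if (sigma == 0) {
    return((m < y & y <= m + nu) / nu)
  }
  ly <- log(y) + 1.5 * sigma^2
  z2 <- (log(m + nu) - ly) / sigma
  z1 <- (log(m) - ly) / sigma        # -Inf at m = 0; pnorm(-Inf) = 0
  out <- pnorm(z2) - pnorm(z1)
  # midpoint form avoids catastrophic cancellation when nu << m * sigma
  narrow <- which(z2 - z1 < 1e-5)
  if (length(narrow)) {
    zm <- (z1[narrow] + z2[narrow]) / 2
    out[narrow] <- (z2[narrow] - z1[narrow]) * dnorm(zm)
  }
  exp(sigma^2) / nu * out
}

# P(Y <= L | m): distribution function (vectorized over L, m).
# sigma = 0 reduces to the uniform CDF clamp((L - m)/nu, 0, 1).
.pmeas_cdf <- function(L, m, nu, sigma) {
  if (sigma == 0) {
    return(pmin(1, pmax(0, (L - m) / nu)))
  }
  L <- pmax(L, 1e-300)   # P(Y <= 0) = 0; keeps k finite when y_low = 0
  k <- log(L) + sigma^2 / 2
  # antiderivative of Phi((k - log s)/sigma) in s; IEEE limits make the
  # m = 0 endpoint (u = -Inf) evaluate to 0 without special-casing
  A <- function(u) {
    exp(u) * pnorm((k - u) / sigma) +
      L * exp(sigma^2) * pnorm((u - k - sigma^2) / sigma)
  }
  pmin(1, pmax(0, (A(log(m + nu)) - A(log(m))) / nu))
}

#' Observation model for one antigen-isotype
#'
#' Bundles the kinetics parameter draws (the predictive ensemble), the noise
#' parameters and the numerical options that define the per-observation
#' likelihood for one biomarker. The generative model for a measured value is
#' \eqn{Y = (y_{\mathrm{model}} + B)\,E} with \eqn{B \sim U(0,\nu)} and
#' \eqn{E} lognormal with mean 1 and CV \eqn{\epsilon};
#' \eqn{y_{\mathrm{model}}} is the two-phase trajectory evaluated at the
#' latent time since infection (0 for never-infected subjects).
#'
#' @param sr_params An `sr_params` object (see [as_sr_params()]), or any data
#'   frame with columns `antigen_iso, y0, y1, t1, alpha, r`.
#' @param noise_params A `noise_params` object or data frame with columns
#'   `antigen_iso, nu, eps, y_low, y_high`.
#' @param antigen_iso Character scalar naming the biomarker; must be present
#'   in both parameter inputs.
#' @param mode Noise-composition mode: `"full"` (default) uses both noise
#'   components; `"no-measurement-noise"` switches off the lognormal factor
#'   (\eqn{\epsilon = 0}); `"noise-free"` additionally shrinks the biologic
#'   noise to a numerically negligible level, leaving the pure kinetics
#'   mixture (useful for analytic-limit checks).
#' @param include_rise Logical; include the rise phase of the trajectory in
#'   the time-since-infection integral (default `TRUE`). `FALSE` restricts
#'   the latent trajectory to the decay branch, the configuration matched by
#'   the closed-form density [closed_form_density_no_noise()].
#' @param n_nodes Gauss-Legendre nodes per quadrature panel (default 4).
#' @param z_span Half-width, in lognormal z-units, of the noise-kernel
#'   support used to place quadrature panels (default 8.5).
#' @return An object of class `obs_model`.
#' @export
obs_model <- function(sr_params, noise_params, antigen_iso,
                      mode = c("full", "no-measurement-noise", "noise-free"),
                      include_rise = TRUE, n_nodes = 4L, z_span = 8.5) {
  mode <- match.arg(mode)
  stopifnot(length(antigen_iso) == 1L)
  sr <- as.data.frame(sr_params)
  sr <- sr[sr$antigen_iso == antigen_iso, , drop = FALSE]
  if (nrow(sr) == 0L)
    stop("no kinetics draws for antigen_iso '", antigen_iso, "'")
  np <- as.data.frame(noise_params)
  np <- np[np$antigen_iso == antigen_iso, , drop = FALSE]
  if (nrow(np) != 1L)
    stop("need exactly one noise-parameter row for antigen_iso '", antigen_iso, "'")
  nu <- np$nu
  eps <- np$eps
  if (mode != "full") eps <- 0
  if (mode == "noise-free") nu <- nu * 1e-9
  structure(list(
    antigen_iso = antigen_iso,
    draws = sr[, c("y0", "y1", "t1", "alpha", "r"), drop = FALSE],
    nu = nu, eps = eps, sigma = .sigma_of_eps(eps),
    y_low = np$y_low, y_high = np$y_high,
    mode = mode, include_rise = include_rise,
    n_nodes = as.integer(n_nodes), z_span = z_span
  ), class = "obs_model")
}

#' @export
print.obs_model <- function(x, ...) {
  cat(sprintf(
    "<obs_model> %s: %d kinetics draw(s); nu=%.4g eps=%.4g limits=[%.4g, %.4g]; mode=%s\n",
    x$antigen_iso, nrow(x$draws), x$nu, x$eps, x$y_low, x$y_high, x$mode
  ))
  invisible(x)
}
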
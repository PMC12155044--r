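# Shared fixtures and independent oracles for the test suite.
#
# The oracles deliberately re-derive the model from first principles
# (explicit formulas, brute-force sampling, generic adaptive integration)
# instead of calling the package's computational path, so that agreement is
# evidence and not tautology.

# one toy kinetics draw used across tests: rise 1 -> 100 over 10 days,
# then dy/dt = -alpha y^2
toy_sr <- function(antigen_iso = "toy", y0 = 1, y1 = 100, t1 = 10,
                   alpha = 0.01, r = 2) {
  data.frame(antigen_iso = antigen_iso, y0 = y0, y1 = y1, t1 = t1,
             alpha = alpha, r = r, stringsAsFactors = FALSE)
}

toy_noise <- function(antigen_iso = "toy", nu = 1, eps = 0.2,
                      y_low = 0.1, y_high = 5000) {
  data.frame(antigen_iso = antigen_iso, nu = nu, eps = eps,
             y_low = y_low, y_high = y_high, stringsAsFactors = FALSE)
}

# trajectory re-implemented directly from the closed-form solution of the
# two-phase model (independent of antibody_level's code path)
oracle_trajectory <- function(t, y0, y1, t1, alpha, r) {
  mu <- log(y1 / y0) / t1
  vapply(t, function(tt) {
    if (tt <= t1) return(y0 * exp(mu * tt))
    if (r == 1) return(y1 * exp(-alpha * (tt - t1)))
    (y1^(1 - r) + (r - 1) * alpha * (tt - t1))^(1 / (1 - r))
  }, numeric(1))
}

# brute-force sample of N observed values under the full generative model
# (Poisson exposure truncated at age, one uniformly chosen kinetics draw,
# additive uniform biologic noise, multiplicative lognormal assay noise)
oracle_mc_sample <- function(N, lambda, age, sr, noise, seed) {
  set.seed(seed)
  ld <- lambda / 365.25
  a_d <- age * 365.25
  infected <- runif(N) < 1 - exp(-ld * a_d)
  # inverse-CDF of the exponential truncated to (0, a)
  tau <- -log(1 - runif(N) * (1 - exp(-ld * a_d))) / ld
  k <- sample.int(nrow(sr), N, replace = TRUE)
  m <- numeric(N)
  ii <- which(infected)
  m[ii] <- oracle_trajectory_rows(tau[ii], sr[k[ii], , drop = FALSE])
  sigma <- sqrt(log(1 + noise$eps^2))
  E <- if (noise$eps > 0) rlnorm(N, -sigma^2 / 2, sigma) else 1
  (m + runif(N, 0, noise$nu)) * E
}

oracle_trajectory_rows <- function(t, rows) {
  vapply(seq_along(t), function(i) {
    oracle_trajectory(t[i], rows$y0[i], rows$y1[i], rows$t1[i],
                      rows$alpha[i], rows$r[i])
  }, numeric(1))
}

# small deterministic population table for data-model tests
toy_pop_df <- function() {
  data.frame(
    id = c("p1", "p1", "p2", "p2"),
    age = c(5.5, 5.5, 9.1, 9.1),
    antigen_iso = rep(c("HlyE_IgA", "HlyE_IgG"), 2),
    value = c(1.2, 3.4, 0.5, 12.0),
    stringsAsFactors = FALSE
  )
}

write_tmp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
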
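test_that("never-infected limit: tiny lambda reduces to the biologic-noise density", {
  m <- obs_model(toy_sr(), toy_noise(nu = 2, eps = 0, y_low = 1e-12,
                                     y_high = 1e12), "toy")
  # lambda -> 0: Y = B ~ Uniform(0, 2), so p(1) = 1/2
  expect_equal(obs_density(1, age = 10, lambda = 1e-12, model = m), 0.5,
               tolerance = 1e-9)
  expect_equal(obs_density(2.5, age = 10, lambda = 1e-12, model = m), 0,
               tolerance = 1e-9)
})

test_that("obs_density validates its arguments", {
  m <- obs_model(toy_sr(), toy_noise(), "toy")
  expect_error(obs_density(1, 10, -0.1, m), "lambda")
  expect_error(obs_density(1, 10, 0, m), "lambda")
  expect_error(obs_density(1, -5, 0.2, m), "age")
  expect_error(obs_model(toy_sr(), toy_noise(), "absent"), "no kinetics draws")
})

test_that("closed-form density matches direct substitution and total probability", {
  # r = 1, y = y1: tau = t1, dy/dtau = -alpha*y1
  ld <- 0.2 / 365.25
  expect_equal(
    closed_form_density_no_noise(100 - 1e-9, age = 10, lambda = 0.2,
                                 y0 = 1, y1 = 100, t1 = 10, alpha = 0.004, r = 1),
    ld * exp(-ld * 10) / (0.004 * 100), tolerance = 1e-6)
  # integral over the attainable decay range equals the probability of being
  # on the decay branch: exp(-ld*t1) - exp(-ld*a)
  for (lam in c(3.65e-6, 0.2)) {
    ld <- lam / 365.25
    a_d <- 10 * 365.25
    f_a <- antibody_level(a_d, 1, 100, 10, 0.01, 2)
    tot <- integrate(function(y)
      closed_form_density_no_noise(y, 10, lam, 1, 100, 10, 0.01, 2),
      f_a, 100, rel.tol = 1e-10, subdivisions = 2000)$value
    expect_equal(tot, exp(-ld * 10) - exp(-ld * a_d), tolerance = 1e-6)
    # when lambda*t1 is negligible this collapses to 1 - exp(-lambda*age)
    if (lam < 1e-4)
      expect_lt(abs(tot - (-expm1(-ld * a_d))), 1e-6)
  }
})

test_that("quadrature matches the closed form in the no-noise decay-only limit", {
  m <- obs_model(toy_sr(), toy_noise(nu = 1e-9, eps = 0, y_low = 1e-12,
                                     y_high = 1e12),
                 "toy", include_rise = FALSE)
  f_a <- antibody_level(10 * 365.25, 1, 100, 10, 0.01, 2)
  ys <- exp(seq(log(f_a * 1.05), log(99), length.out = 20))
  q <- obs_density(ys, age = 10, lambda = 0.2, model = m)
  cf <- closed_form_density_no_noise(ys, 10, 0.2, 1, 100, 10, 0.01, 2)
  expect_lt(max(abs(q - cf) / cf), 1e-4)
})

test_that("density and CDF agree with a brute-force Monte Carlo oracle", {
  sr <- toy_sr(); noise <- toy_noise()
  m <- obs_model(sr, noise, "toy")
  lam <- 0.2; age <- 10
  N <- 1e6
  Y <- oracle_mc_sample(N, lam, age, sr, noise, seed = 99)
  # binned probability around y = 3 (unbiased, unlike a KDE)
  h <- 0.2
  p_emp <- mean(Y >= 3 - h & Y <= 3 + h)
  p_mod <- integrate(function(y) obs_density(y, age, lam, m),
                     3 - h, 3 + h, rel.tol = 1e-8)$value
  se <- sqrt(p_emp * (1 - p_emp) / N)
  expect_lt(abs(p_mod - p_emp), 3 * se)
  # CDF at a spread of quantile points
  qs <- c(0.5, 1, 2, 5, 20, 60)
  Fm <- obs_cdf(qs, age, lam, m)
  Fe <- vapply(qs, function(q) mean(Y <= q), numeric(1))
  se_f <- sqrt(Fe * (1 - Fe) / N)
  expect_true(all(abs(Fm - Fe) < 4 * se_f + 1e-3))
})

test_that("censoring masses are returned at the limits and move monotonically in lambda", {
  m <- obs_model(toy_sr(), toy_noise(y_low = 0.5, y_high = 50), "toy")
  lams <- c(0.02, 0.1, 0.5, 2)
  p_lo <- vapply(lams, function(l) obs_density(0.5, 10, l, m), numeric(1))
  p_hi <- vapply(lams, function(l) obs_density(50, 10, l, m), numeric(1))
  # more infections -> higher titres: mass below the floor falls, above rises
  expect_true(all(diff(p_lo) < 0))
  expect_true(all(diff(p_hi) > 0))
  # any value at or beyond a limit yields that limit's mass
  expect_equal(obs_density(0.2, 10, 0.1, m), obs_density(0.5, 10, 0.1, m))
  expect_equal(obs_density(80, 10, 0.1, m), obs_density(50, 10, 0.1, m))
})

test_that("negative log-likelihood is definitional and additive across biomarkers", {
  sr <- as_sr_params(rbind(toy_sr("a"), toy_sr("a", y0 = 1.5, y1 = 80),
                           toy_sr("b", alpha = 0.004, r = 1.5)))
  np <- as_noise_params(rbind(toy_noise("a"), toy_noise("b", nu = 2)))
  models <- list(a = obs_model(sr, np, "a"), b = obs_model(sr, np, "b"))
  pop <- as_pop_data(data.frame(
    id = c("s1", "s1", "s2"), age = c(6, 6, 11),
    antigen_iso = c("a", "b", "a"), value = c(2.5, 8, 0.7)))
  nll <- neg_log_lik(0.3, pop, models)
  by_hand <- -(
    log(obs_density(2.5, 6, 0.3, models$a)) +
    log(obs_density(8, 6, 0.3, models$b)) +
    log(obs_density(0.7, 11, 0.3, models$a)))
  expect_equal(nll, by_hand, tolerance = 1e-12)
  # exact additivity over the biomarker partition
  nll_a <- neg_log_lik(0.3, pop[pop$antigen_iso == "a", ], models["a"])
  nll_b <- neg_log_lik(0.3, pop[pop$antigen_iso == "b", ], models["b"])
  expect_equal(nll, nll_a + nll_b, tolerance = 1e-13)
})

test_that("a structurally impossible record raises an error naming it", {
  # eps = 0 and value above y1 + nu: unreachable under the model
  sr <- as_sr_params(toy_sr("a"))
  np <- as_noise_params(toy_noise("a", eps = 0, y_high = 1e9))
  models <- list(a = obs_model(sr, np, "a"))
  pop <- as_pop_data(data.frame(id = "bad", age = 8, antigen_iso = "a",
                                value = 500))
  expect_error(neg_log_lik(0.2, pop, models), "bad")
})

test_that("noise-composition modes alter the model as documented", {
  sr <- toy_sr(); np <- toy_noise(eps = 0.3)
  m_off <- obs_model(sr, np, "toy", mode = "no-measurement-noise")
  np0 <- toy_noise(eps = 0)
  m_eps0 <- obs_model(sr, np0, "toy")
  ys <- c(0.5, 2, 20)
  expect_equal(obs_density(ys, 8, 0.2, m_off), obs_density(ys, 8, 0.2, m_eps0))
  # noise-free mode concentrates all never-infected mass near zero
  m_free <- obs_model(sr, np, "toy", mode = "noise-free")
  expect_equal(obs_cdf(1e-7, 8, 0.2, m_free),
               exp(-0.2 / 365.25 * 8 * 365.25), tolerance = 1e-3)
})

test_that("the nll grid minimum tracks the generating rate over seeded replicates", {
  # 200-subject surveys; 50-point log-lambda grid spanning 1e-3..100/year
  grid <- exp(seq(log(1e-3), log(100), length.out = 50))
  step <- diff(log(grid))[1]
  lam_true <- 0.2
  hits <- 0L
  for (seed in 1:50) {
    cfg <- sim_config(lambda = lam_true, n_subjects = 200,
                      antigen_isos = "HlyE_IgG", K = 10, seed = seed)
    pop <- simulate_pop_data(cfg)
    models <- list(HlyE_IgG = obs_model(cfg$sr_params, cfg$noise_params,
                                        "HlyE_IgG"))
    blocks <- serorate:::.make_blocks(pop, models)
    nll <- vapply(log(grid), function(x) serorate:::.nll_derivs(blocks, x)$nll,
                  numeric(1))
    if (seed == 1L)   # the cached-grid path must agree with the public nll
      expect_equal(nll[25], neg_log_lik(grid[25], pop, models),
                   tolerance = 1e-10)
    x_min <- log(grid[which.min(nll)])
    if (abs(x_min - log(lam_true)) <= step + 1e-12) hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90% of 50 replicates
})
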
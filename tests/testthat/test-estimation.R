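test_that("the rate is recovered from the reference simulated survey", {
  cfg <- sim_config(lambda = 0.2, n_subjects = 5000, K = 50, seed = 42)
  pop <- simulate_pop_data(cfg)
  est <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params)
  expect_true(est$converged)
  expect_gt(est$lambda_hat, 0.17)
  expect_lt(est$lambda_hat, 0.23)
  expect_true(est$ci_low < est$lambda_hat && est$lambda_hat < est$ci_high)
  expect_equal(est$lambda_hat, exp(est$log_lambda_hat))
  expect_equal(est$ci_low, exp(est$log_lambda_hat - 1.96 * est$se_log_lambda))
  expect_equal(est$n_subjects, 5000)
  expect_equal(est$n_observations, 10000)
})

test_that("a survey with no serologic signal pins the estimate at the lower bound", {
  sr <- as_sr_params(toy_sr("a"))
  np <- as_noise_params(toy_noise("a", nu = 2, eps = 0, y_low = 1e-4))
  set.seed(5)
  pop <- as_pop_data(data.frame(
    id = sprintf("s%03d", 1:150), age = runif(150, 3, 12),
    antigen_iso = "a", value = runif(150, 0.01, 0.3)))
  est <- suppressWarnings(
    est_seroincidence(pop, sr, np, "a"))
  expect_false(est$converged)
  expect_equal(est$boundary, "lower")
  expect_equal(est$log_lambda_hat, log(1e-6), tolerance = 1e-3)
})

test_that("stratified estimation on a single-cell partition equals the subset fit", {
  cfg <- sim_config(lambda = 0.3, n_subjects = 300, antigen_isos = "HlyE_IgG",
                    K = 10, seed = 8)
  pop <- simulate_pop_data(cfg)
  pop$site <- "only"
  by <- est_seroincidence_by(pop, cfg$sr_params, cfg$noise_params, "site")
  single <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params)
  expect_equal(length(by$estimates), 1L)
  e <- by$estimates[[1]]
  expect_identical(e$log_lambda_hat, single$log_lambda_hat)
  expect_identical(e$se_log_lambda, single$se_log_lambda)
  expect_identical(e$nll_at_optimum, single$nll_at_optimum)
})

test_that("two strata with different true rates are both recovered", {
  mk <- function(lam, seed, country) {
    cfg <- sim_config(lambda = lam, n_subjects = 3000,
                      antigen_isos = "HlyE_IgG", K = 20, seed = seed)
    pop <- simulate_pop_data(cfg)
    pop$country <- country
    list(pop = pop, cfg = cfg)
  }
  a <- mk(0.1, 7, "A"); b <- mk(0.5, 7007, "B")
  da <- as.data.frame(a$pop); da$id <- paste0("A", da$id)
  db <- as.data.frame(b$pop); db$id <- paste0("B", db$id)
  pop <- as_pop_data(rbind(da, db))
  by <- est_seroincidence_by(pop, a$cfg$sr_params, a$cfg$noise_params,
                             "country")
  tab <- summary(by)
  expect_equal(tab$country, c("A", "B"))
  expect_lt(abs(tab$rate_per_1000py[1] / 100 - 1), 0.15)
  expect_lt(abs(tab$rate_per_1000py[2] / 500 - 1), 0.15)
})

test_that("stratified cells match per-cell ensembles when the ensemble is stratified", {
  cfg <- sim_config(lambda = 0.25, n_subjects = 200,
                    antigen_isos = "HlyE_IgG", K = 8, seed = 12)
  pop <- simulate_pop_data(cfg)
  pop$grp <- rep(c("u", "v"), length.out = nrow(pop))
  sr_u <- cfg$sr_params; sr_u$grp <- "u"
  sr_v <- cfg$sr_params; sr_v$alpha <- sr_v$alpha * 2; sr_v$grp <- "v"
  sr_strat <- as_sr_params(rbind(as.data.frame(sr_u), as.data.frame(sr_v)))
  by <- est_seroincidence_by(pop, sr_strat, cfg$noise_params, "grp")
  # cell u must equal a plain fit with only the u draws
  direct_u <- est_seroincidence(pop[pop$grp == "u", ], sr_u,
                                cfg$noise_params)
  expect_identical(by$estimates[[1]]$log_lambda_hat, direct_u$log_lambda_hat)
  # the two cells use genuinely different kinetics
  expect_false(isTRUE(all.equal(by$estimates[[1]]$log_lambda_hat,
                                by$estimates[[2]]$log_lambda_hat)))
})

test_that("parallel and serial stratified estimation are identical", {
  cfg <- sim_config(lambda = 0.3, n_subjects = 240, antigen_isos = "HlyE_IgG",
                    K = 6, seed = 31)
  pop <- simulate_pop_data(cfg)
  pop$region <- rep(c("N", "S", "E"), length.out = nrow(pop))
  serial <- est_seroincidence_by(pop, cfg$sr_params, cfg$noise_params,
                                 "region", opts = est_options(cores = 1))
  par2 <- est_seroincidence_by(pop, cfg$sr_params, cfg$noise_params,
                               "region", opts = est_options(cores = 2))
  expect_identical(summary(serial), summary(par2))
})

test_that("unknown covariates and empty cross-product cells are handled", {
  cfg <- sim_config(lambda = 0.3, n_subjects = 50, antigen_isos = "HlyE_IgG",
                    K = 5, seed = 2)
  pop <- simulate_pop_data(cfg)
  expect_error(
    est_seroincidence_by(pop, cfg$sr_params, cfg$noise_params, "nope"),
    "unknown covariate")
  # construct an unobserved (x2, z1) cross-product cell
  pop$x <- c("x1", "x2")[1 + (seq_len(nrow(pop)) > 25)]
  pop$z <- ifelse(pop$x == "x1", c("z1", "z2")[1 + seq_len(nrow(pop)) %% 2],
                  "z2")
  expect_warning(
    by <- est_seroincidence_by(pop, cfg$sr_params, cfg$noise_params,
                               c("x", "z"),
                               opts = est_options(small_cell_n = 1)),
    "empty stratum")
  expect_lt(length(by$estimates), 4L)
})

test_that("summaries scale to events per 1000 person-years and keep flagged rows", {
  est <- structure(list(
    log_lambda_hat = log(0.128), se_log_lambda = 0.1,
    lambda_hat = 0.128, ci_low = 0.128 * exp(-0.196),
    ci_high = 0.128 * exp(0.196), n_subjects = 500, n_observations = 1000,
    antigen_isos = c("HlyE_IgA", "HlyE_IgG"), stratum = list(),
    converged = FALSE, boundary = "none", nll_at_optimum = 1234,
    ci_method = "wald"), class = "seroincidence")
  tab <- summary(est)
  expect_equal(tab$rate_per_1000py, 128)
  expect_false(tab$converged)       # flagged, not dropped
  long <- incidence_long_table(est)
  expect_true(all(c("stratum", "quantity", "value") %in% names(long)))
  expect_equal(long$value[long$quantity == "rate_per_1000py"], 128)
})

test_that("profile-likelihood intervals bracket the Wald interval sensibly", {
  cfg <- sim_config(lambda = 0.3, n_subjects = 500, antigen_isos = "HlyE_IgG",
                    K = 10, seed = 77)
  pop <- simulate_pop_data(cfg)
  w <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params)
  p <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params,
                         opts = est_options(ci_method = "profile"))
  expect_equal(p$lambda_hat, w$lambda_hat)
  expect_true(p$ci_low < p$lambda_hat && p$lambda_hat < p$ci_high)
  # near-quadratic log-likelihood: the two intervals should be close
  expect_equal(p$ci_low, w$ci_low, tolerance = 0.05)
  expect_equal(p$ci_high, w$ci_high, tolerance = 0.05)
})

test_that("rescaling all concentrations leaves the estimate unchanged", {
  cfg <- sim_config(lambda = 0.25, n_subjects = 400, antigen_isos = "HlyE_IgG",
                    K = 8, seed = 21)
  pop <- simulate_pop_data(cfg)
  est1 <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params)
  s <- 40
  pop2 <- pop; pop2$value <- pop2$value * s
  sr2 <- cfg$sr_params
  sr2$y0 <- sr2$y0 * s; sr2$y1 <- sr2$y1 * s
  sr2$alpha <- sr2$alpha * s^(1 - sr2$r)   # alpha has units conc^(1-r)/day
  np2 <- cfg$noise_params
  np2$nu <- np2$nu * s; np2$y_low <- np2$y_low * s; np2$y_high <- np2$y_high * s
  est2 <- est_seroincidence(pop2, sr2, np2)
  expect_equal(est2$log_lambda_hat, est1$log_lambda_hat, tolerance = 1e-5)
})

test_that("ensemble subsampling is seeded and reduces the draw count", {
  cfg <- sim_config(lambda = 0.3, n_subjects = 200, antigen_isos = "HlyE_IgG",
                    K = 20, seed = 14)
  pop <- simulate_pop_data(cfg)
  e1 <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params,
                          opts = est_options(subsample_draws = 5))
  e2 <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params,
                          opts = est_options(subsample_draws = 5))
  expect_identical(e1$log_lambda_hat, e2$log_lambda_hat)
  full <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params)
  expect_equal(e1$lambda_hat, full$lambda_hat, tolerance = 0.2)
})
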
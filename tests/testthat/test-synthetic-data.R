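test_that("generation is bit-reproducible under a fixed seed", {
  sc <- simulation_scenario(n_derivation = 120, n_validation = 80, seed = 7)
  expect_identical(generate_samples(sc), generate_samples(sc))
  sc2 <- simulation_scenario(n_derivation = 120, n_validation = 80, seed = 8)
  expect_false(identical(generate_samples(sc), generate_samples(sc2)))
})

test_that("a null model reproduces the closed-form Weibull survival", {
  sc <- simulation_scenario(n_derivation = 6000, n_validation = 50,
                            coefficients = c(0, 0, 0),
                            admin_censoring = NULL, seed = 51)
  d <- generate_samples(sc)$derivation
  km <- kaplan_meier(d$time, d$event)
  qs <- quantile(d$time, seq(0.1, 0.9, 0.1))
  truth <- exp(-0.18 * qs^0.9)
  expect_equal(evaluate_step(km, qs), unname(truth), tolerance = 0.025)
})

test_that("Cox regression recovers the generating coefficients", {
  sc <- simulation_scenario(n_derivation = 2000, n_validation = 50,
                            covariates = list(
                              list(dist = "normal", mean = 0, sd = 1),
                              list(dist = "binary", prevalence = 0.4)),
                            coefficients = c(0.5, -0.3),
                            admin_censoring = NULL, seed = 52)
  d <- generate_samples(sc)$derivation
  fit <- fit_cox(d, c("x1", "x2"))
  se <- sqrt(diag(fit$covariance))
  expect_true(all(abs(fit$coefficients - c(0.5, -0.3)) <= 2 * se))
})

test_that("administrative censoring matches its analytic target", {
  # P(censored) = S(horizon) for a null Weibull model
  sc <- simulation_scenario(n_derivation = 10000, n_validation = 50,
                            coefficients = c(0, 0, 0), admin_censoring = 3,
                            seed = 53)
  d <- generate_samples(sc)$derivation
  expect_equal(mean(d$event == 0), exp(-0.18 * 3^0.9), tolerance = 0.02)
})

test_that("exchangeable arms agree; perturbed arms differ as specified", {
  sc <- simulation_scenario(n_derivation = 2500, n_validation = 2500,
                            seed = 54)
  arms <- generate_samples(sc)
  km_d <- kaplan_meier(arms$derivation$time, arms$derivation$event)
  km_v <- kaplan_meier(arms$validation$time, arms$validation$event)
  qs <- quantile(arms$derivation$time, c(0.25, 0.5, 0.75))
  expect_equal(evaluate_step(km_d, qs), evaluate_step(km_v, qs),
               tolerance = 0.05)

  shr <- simulation_scenario(n_derivation = 500, n_validation = 500,
                             case_mix_shrinkage = 0.5, seed = 55)
  arms2 <- generate_samples(shr)
  expect_lt(sd(arms2$validation$true_lp), 0.75 * sd(arms2$derivation$true_lp))
})

test_that("the piecewise-exponential baseline inverts correctly", {
  sc <- simulation_scenario(
    n_derivation = 8000, n_validation = 50,
    baseline = list(times = c(1, 3), rates = c(0.4, 0.1, 0.25)),
    coefficients = c(0, 0, 0), admin_censoring = NULL, seed = 56)
  d <- generate_samples(sc)$derivation
  km <- kaplan_meier(d$time, d$event)
  H_true <- function(t) 0.4 * pmin(t, 1) + 0.1 * pmax(pmin(t, 3) - 1, 0) +
    0.25 * pmax(t - 3, 0)
  for (t0 in c(0.5, 2, 4))
    expect_equal(evaluate_step(km, t0), exp(-H_true(t0)), tolerance = 0.02)
})

test_that("apparent_scenario packages a coherent published-model bundle", {
  sc <- simulation_scenario(n_derivation = 800, n_validation = 400, seed = 57)
  arms <- generate_samples(sc)
  app <- apparent_scenario(arms$derivation)
  expect_s3_class(app$model, "published_model")
  expect_s3_class(app$grouping, "risk_grouping")
  expect_s3_class(app$baseline, "fp2_fit")
  # centering makes the derivation PI mean zero
  pi_d <- compute_pi(app$model, arms$derivation)
  expect_equal(mean(pi_d), 0, tolerance = 1e-10)
  # slope on the derivation arm is 1 by construction; validation near 1
  v <- arms$validation
  v$pi <- compute_pi(app$model, v)
  expect_equal(calibration_slope(v)$slope, 1, tolerance = 0.35)
  # case-mix shrinkage lowers R2_PM in the validation arm
  shr <- simulation_scenario(n_derivation = 800, n_validation = 800,
                             case_mix_shrinkage = 0.5, seed = 58)
  arms2 <- generate_samples(shr)
  app2 <- apparent_scenario(arms2$derivation)
  expect_lt(r2_pm(sd(compute_pi(app2$model, arms2$validation))),
            r2_pm(sd(compute_pi(app2$model, arms2$derivation))))
  expect_error(apparent_scenario(arms$derivation[1:20, ]),
               class = "coxval_data_error")
})

test_that("scenarios round-trip through YAML", {
  sc <- simulation_scenario(n_derivation = 300, n_validation = 100,
                            slope_multiplier = 0.8, dropout = c(1, 10),
                            seed = 59)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2, sc)
  expect_identical(generate_samples(sc2), generate_samples(sc))
})
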
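test_that("FP2 basis follows the fractional-polynomial conventions", {
  expect_equal(unname(fp2_basis(4, c(-0.5, -0.5))),
               matrix(c(0.5, 0.5 * log(4)), 1))
  expect_equal(unname(fp2_basis(1, c(0, 1))), matrix(c(0, 1), 1))
  expect_equal(unname(fp2_basis(exp(1), c(0, 0))), matrix(c(1, 1), 1))
  expect_error(fp2_basis(-1, c(0, 1)), class = "coxval_config_error")

  # repeated-power basis is the derivative limit of distinct powers:
  # (t^(p+h) - t^p)/h -> t^p ln t, so (p, p+h) spans (t^p, ~t^p ln t)
  t <- seq(0.5, 6, length.out = 20)
  h <- 1e-6
  num <- (t^(0.5 + h) - t^0.5) / h
  rep_basis <- fp2_basis(t, c(0.5, 0.5))
  expect_equal(num, rep_basis[, 2], tolerance = 1e-5)
})

test_that("an exact FP2 curve is recovered to numerical precision", {
  t <- seq(0.25, 7, length.out = 40)
  lnH <- 1.727 - 3.759 * t^-0.5 - 0.356 * t^-0.5 * log(t)
  curve <- step_curve(t, exp(lnH), flavour = "cumhaz")
  fit <- fit_fp2_log_cumhaz(curve)
  expect_equal(fit$powers, c(-0.5, -0.5))
  expect_equal(fit$coefficients, c(1.727, -3.759, -0.356), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # the winning pair beats every other pair by exhaustive re-enumeration
  expect_true(all(fit$search$rss >= fit$rss - 1e-12))
})

test_that("a Weibull baseline is recovered through the log basis", {
  lambda <- 0.2; nu <- 0.9
  t <- seq(0.2, 7, length.out = 30)
  curve <- step_curve(t, lambda * t^nu, flavour = "cumhaz")
  fit <- fit_fp2_log_cumhaz(curve, powers = 0)   # basis: ln t, (ln t)^2
  expect_equal(exp(fit$coefficients[1]), lambda, tolerance = 1e-3)
  expect_equal(fit$coefficients[2], nu, tolerance = 1e-3)
  expect_equal(fit$coefficients[3], 0, tolerance = 1e-6)
})

test_that("evaluation composes to survival and guards extrapolation", {
  t <- seq(0.5, 5, length.out = 20)
  curve <- step_curve(t, 0.3 * t, flavour = "cumhaz")
  fit <- fit_fp2_log_cumhaz(curve)
  # where ln H0 = 0, S0 = exp(-1)
  t0 <- uniroot(function(u) evaluate_log_cumhaz(fit, u), c(0.5, 5),
                tol = 1e-12)$root
  expect_equal(evaluate_s0(fit, t0), exp(-1), tolerance = 1e-8)
  # monotone: non-increasing survival whenever ln H0 is non-decreasing
  s <- evaluate_s0(fit, t)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s > 0 & s < 1))
  expect_error(evaluate_s0(fit, 10), class = "coxval_config_error")
  expect_warning(evaluate_s0(fit, 10, extrapolate = TRUE), "xtrapolat")
  expect_error(evaluate_log_cumhaz(fit, -2), class = "coxval_config_error")
})

test_that("too few event times are refused", {
  t <- c(1, 2, 3)
  expect_error(fit_fp2_log_cumhaz(step_curve(t, 0.1 * t, flavour = "cumhaz")),
               class = "coxval_data_error")
})

test_that("the bootstrap band is reproducible, ordered and centred", {
  set.seed(41)
  d <- random_surv(150, cens_rate = 0.2)
  d$pi <- 0.7 * d$x
  b1 <- bootstrap_band(d$time, d$event, d$pi, n_boot = 30, seed = 99)
  b2 <- bootstrap_band(d$time, d$event, d$pi, n_boot = 30, seed = 99)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$upper))
  expect_true(all(b1$lower > 0))
  expect_true(all(b1$center >= b1$lower & b1$center <= b1$upper))
  expect_error(bootstrap_band(d$time, d$event, d$pi, n_boot = 30),
               class = "coxval_config_error")   # seed is required

  # duplicated subjects: resampling variability collapses, band narrows
  dd <- d[rep(1:150, 8), ]
  b3 <- bootstrap_band(dd$time, dd$event, dd$pi, n_boot = 15, seed = 5)
  mid <- seq(20, 80)
  expect_lt(mean(log(b3$upper[mid] / b3$lower[mid])),
            0.6 * mean(log(b1$upper[mid] / b1$lower[mid])))
})

test_that("FP2 fits and look-up baselines round-trip through files", {
  t <- seq(0.25, 7, length.out = 30)
  curve <- step_curve(t, 0.2 * t^0.9, flavour = "cumhaz")
  fit <- fit_fp2_log_cumhaz(curve)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_baseline(fit, path)
  fit2 <- read_baseline(path)
  expect_equal(fit2$powers, fit$powers)
  expect_equal(fit2$coefficients, fit$coefficients)
  expect_equal(evaluate_s0(fit2, 3), evaluate_s0(fit, 3))

  lk <- baseline_lookup(c(1, 2, 5), c(0.9, 0.8, 0.55))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_baseline_lookup(lk, p2)
  lk2 <- read_baseline_lookup(p2)
  expect_equal(evaluate_s0(lk2, c(1, 1.5, 5)), evaluate_s0(lk, c(1, 1.5, 5)))
  expect_equal(evaluate_s0(lk, 2), 0.8)
  # interpolation is on the log cumulative-hazard scale
  expected_mid <- exp(-exp(mean(log(-log(c(0.9, 0.8))))))
  expect_equal(evaluate_s0(lk, 1.5), expected_mid)
})

test_that("the published breast-cancer baseline reads on a year scale", {
  path <- system.file("extdata", "breast_fp2_baseline.yaml",
                      package = "coxval")
  fit <- read_baseline(path)
  expect_equal(fit$powers, c(-0.5, -0.5))
  # 2- and 5-year baseline survival sit where the published risk-group
  # predictions bracket them (the cohort mean PI is ~0)
  expect_equal(round(evaluate_s0(fit, 5), 2), 0.44)
  expect_equal(round(evaluate_s0(fit, 2), 2), 0.72)
  s <- evaluate_s0(fit, seq(0.1, 7, by = 0.1))
  expect_true(all(diff(s) <= 0))
  expect_true(all(s > 0 & s < 1))
})
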
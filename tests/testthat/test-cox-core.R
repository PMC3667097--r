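test_that("Cox coefficient matches a grid-search partial-likelihood maximizer", {
  d6 <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 0, 1, 1, 0, 1),
                   x = c(0.5, -1, 2, 0, 1, -0.5))
  for (ties in c("efron", "breslow")) {
    fit <- fit_cox(d6, "x", ties = ties)
    expect_equal(unname(fit$coefficients[[1]]),
                 oracle_cox_grid(d6$time, d6$event, d6$x, ties = ties),
                 tolerance = 1e-4)
  }
  # tied event times exercise the tie corrections
  d_tie <- data.frame(time = c(1, 1, 1, 2, 2, 3, 4, 5),
                      event = c(1, 1, 0, 1, 1, 0, 1, 1),
                      x = c(1, 0.2, -1, 0.8, -0.3, 1.5, -2, 0.1))
  for (ties in c("efron", "breslow")) {
    fit <- fit_cox(d_tie, "x", ties = ties)
    expect_equal(unname(fit$coefficients[[1]]),
                 oracle_cox_grid(d_tie$time, d_tie$event, d_tie$x,
                                 ties = ties),
                 tolerance = 1e-4)
  }
})

test_that("symmetric groups give a zero coefficient and offsets are exact", {
  d <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = rep(c(1, 1, 0, 1), 2),
                  g = rep(0:1, each = 4))
  fit <- fit_cox(d, "g")
  expect_equal(unname(fit$coefficients[[1]]), 0, tolerance = 1e-8)

  # offset-only fit returns the partial log-likelihood at that offset
  set.seed(5)
  d2 <- random_surv(40)
  d2$off <- 0.6 * d2$x
  fit0 <- fit_cox(d2, offset = "off")
  expect_equal(fit0$log_likelihood,
               oracle_partial_loglik(d2$time, d2$event, d2$off),
               tolerance = 1e-8)
  expect_length(fit0$coefficients, 0)
  expect_true(fit0$offset_used)
})

test_that("fit_cox rejects event-free data and separation", {
  d <- data.frame(time = 1:5, event = rep(0, 5), x = rnorm(5))
  expect_error(fit_cox(d, "x"), class = "coxval_data_error")
  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 1, 1, 1), x = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox(sep, "x"), class = "coxval_numeric_error")
})

test_that("Kaplan-Meier matches the hand product-limit estimator", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$times, c(1, 2))
  expect_equal(km$values, c(2 / 3, 1 / 3))
  expect_equal(evaluate_step(km, 3), 1 / 3)

  set.seed(6)
  d <- random_surv(60)
  km2 <- kaplan_meier(d$time, d$event)
  orc <- oracle_km(d$time, d$event)
  expect_equal(km2$times, orc$times)
  expect_equal(km2$values, orc$surv, tolerance = 1e-12)

  # all censored: survival stays at 1 (no event times on the curve)
  km3 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_length(km3$times, 0)
  expect_equal(evaluate_step(km3, 2.5), 1)

  # with no censoring the estimate is the empirical survival function
  t <- c(4, 1, 3, 2, 5)
  km4 <- kaplan_meier(t, rep(1, 5))
  expect_equal(km4$values, 1 - (1:5) / 5)
})

test_that("offset baseline reduces to Nelson-Aalen and is offset-equivariant", {
  d4 <- data.frame(time = c(1, 2, 2, 4), event = c(1, 1, 1, 0))
  H <- baseline_cumhaz(d4$time, d4$event, rep(0, 4))
  orc <- oracle_na(d4$time, d4$event)
  expect_equal(H$times, orc$times)
  expect_equal(H$values, orc$cumhaz)           # 1/4, then + 2/3

  set.seed(7)
  d <- random_surv(80)
  pi <- 0.8 * d$x
  H1 <- baseline_cumhaz(d$time, d$event, pi)
  H2 <- baseline_cumhaz(d$time, d$event, pi + 1.5)
  expect_equal(H2$values, H1$values * exp(-1.5), tolerance = 1e-12)

  # increments positive, total finite; exp(-H) close to the product-limit
  # form while risk sets are large
  inc <- diff(c(0, H1$values))
  expect_true(all(inc > 0) && is.finite(sum(inc)))
  S_exp <- cumhaz_to_survival(H1, "exp")
  S_pl <- cumhaz_to_survival(H1, "product-limit")
  big <- H1$at_risk > 20
  expect_lt(max(abs(S_exp$values[big] - S_pl$values[big])), 0.01)
})

test_that("baseline agrees with survival::basehaz on an estimated model", {
  set.seed(8)
  d <- random_surv(100)
  cox <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "breslow")
  bh <- survival::basehaz(cox, centered = TRUE)
  eta <- unname(coef(cox)) * (d$x - mean(d$x))
  H <- baseline_cumhaz(d$time, d$event, eta)
  expect_equal(H$values, bh$hazard[bh$time %in% H$times], tolerance = 1e-8)
})

test_that("logrank test matches the hand computation and is label-invariant", {
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)),
               class = "coxval_config_error")

  d <- data.frame(time = c(1, 3, 5, 2, 4, 6), event = c(1, 1, 0, 1, 1, 1),
                  g = rep(c("A", "B"), each = 3))
  lt <- logrank_test(d$time, d$event, d$g)
  expect_equal(lt$statistic, oracle_logrank2(d$time, d$event, d$g),
               tolerance = 1e-10)
  expect_equal(lt$df, 1)
  relabel <- c(A = "z2", B = "z1")[d$g]
  expect_equal(logrank_test(d$time, d$event, relabel)$statistic,
               lt$statistic)

  # identical groups: statistic exactly 0
  d2 <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 0), 2),
                   g = rep(1:2, each = 3))
  expect_equal(logrank_test(d2$time, d2$event, d2$g)$statistic, 0)
  expect_match(lt$caveat, "[Dd]eprecated")
})

test_that("step curves serialize to delimited text and back", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 0, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_step_curve(km, path)
  expect_equal(read_step_curve(path), km)
  expect_error(step_curve(c(1, 2), c(0.5, 0.9), "survival"),
               class = "coxval_config_error")
  expect_error(step_curve(c(1, 2), c(0.5, 0.2), "cumhaz"),
               class = "coxval_config_error")
})
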
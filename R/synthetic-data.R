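# Simulation of derivation/validation dataset pairs with known
# proportional-hazards structure. Event times come from a Weibull baseline by
# the inversion method, T = (-ln U / (lambda * exp(lp)))^(1/nu), which keeps
# closed-form survival available for oracle checks; a piecewise-exponential
# baseline is available for non-smooth hazards. The validation arm can be
# perturbed (slope multiplier on the linear predictor, baseline hazard
# multiplier, case-mix shrinkage, a time-varying coefficient) so every
# validation method can be exercised against a known truth.

#' Define a simulation scenario
#'
#' The defaults emulate a node-positive breast-cancer setting on a time scale
#' of years: a derivation cohort of 1546 and a validation cohort of 686
#' subjects, a Weibull baseline with rate 0.18 and shape 0.9 (median
#' event-free time around 4.5 years at average risk), three prognostic
#' covariates giving a linear-predictor spread of about 0.6, and
#' administrative censoring at 7 years.
#'
#' @param n_derivation,n_validation cohort sizes.
#' @param baseline Weibull parameters `c(rate = , shape = )` (both positive),
#'   or a `piecewise` list with elements `times` and `rates` for a
#'   piecewise-exponential baseline.
#' @param covariates list of per-covariate distributions: each element either
#'   `list(dist = "normal", mean = , sd = )` or
#'   `list(dist = "binary", prevalence = )`.
#' @param coefficients true log hazard-ratio per covariate.
#' @param slope_multiplier gamma applied to the linear predictor in the
#'   validation arm (1 = calibrated).
#' @param hazard_multiplier rho applied to the baseline rate in the
#'   validation arm (1 = calibrated).
#' @param case_mix_shrinkage factor multiplying the covariate SDs in the
#'   validation arm; < 1 gives a narrower case mix.
#' @param admin_censoring administrative censoring horizon (same time unit),
#'   or `NULL` for none.
#' @param dropout `c(min, max)` of a uniform random censoring window, or
#'   `NULL`.
#' @param tv_effect optional `list(covariate = index, delta = )` making one
#'   coefficient time-varying, `beta * (1 + delta * ln(1 + t))`, to break
#'   proportional hazards in a controlled way (the shift inside the logarithm
#'   keeps the hazard integrable near `t = 0`).
#' @param seed integer seed.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_derivation = 1546, n_validation = 686,
                                baseline = c(rate = 0.18, shape = 0.9),
                                covariates = list(
                                  list(dist = "normal", mean = 0, sd = 1),
                                  list(dist = "normal", mean = 0, sd = 1),
                                  list(dist = "binary", prevalence = 0.5)),
                                coefficients = c(0.4, -0.3, 0.5),
                                slope_multiplier = 1, hazard_multiplier = 1,
                                case_mix_shrinkage = 1,
                                admin_censoring = 7, dropout = NULL,
                                tv_effect = NULL, seed = 1L) {
  if (is.numeric(baseline)) {
    if (any(!is.finite(baseline)) || any(baseline <= 0))
      stop_config("Weibull rate and shape must be positive")
  } else if (!is.list(baseline) || is.null(baseline$times) ||
             is.null(baseline$rates)) {
    stop_config("baseline must be c(rate, shape) or list(times, rates)")
  }
  if (length(coefficients) != length(covariates))
    stop_config("one coefficient per covariate is required")
  if (!is.finite(slope_multiplier))
    stop_config("slope_multiplier must be finite")
  if (hazard_multiplier <= 0 || case_mix_shrinkage <= 0)
    stop_config("hazard_multiplier and case_mix_shrinkage must be positive")
  for (cv in covariates) {
    if (identical(cv$dist, "binary") &&
        (cv$prevalence <= 0 || cv$prevalence >= 1))
      stop_config("binary prevalence must lie in (0, 1)")
  }
  structure(list(n_derivation = n_derivation, n_validation = n_validation,
                 baseline = baseline, covariates = covariates,
                 coefficients = coefficients,
                 slope_multiplier = slope_multiplier,
                 hazard_multiplier = hazard_multiplier,
                 case_mix_shrinkage = case_mix_shrinkage,
                 admin_censoring = admin_censoring, dropout = dropout,
                 tv_effect = tv_effect, seed = as.integer(seed)),
            class = "simulation_scenario")
}

draw_covariates <- function(scenario, n, shrink = 1) {
  X <- matrix(0, n, length(scenario$covariates))
  for (k in seq_along(scenario$covariates)) {
    cv <- scenario$covariates[[k]]
    X[, k] <- if (identical(cv$dist, "binary")) {
      stats::rbinom(n, 1, cv$prevalence)
    } else {
      stats::rnorm(n, cv$mean %||% 0, (cv$sd %||% 1) * shrink)
    }
  }
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# Inverse of the cumulative hazard. Weibull: H0(t) = rate * t^shape.
# Piecewise exponential: H0 piecewise linear in t.
invert_cumhaz <- function(scenario, h, rate_mult = 1) {
  b <- scenario$baseline
  if (is.numeric(b)) {
    (h / (rate_mult * b[["rate"]]))^(1 / b[["shape"]])
  } else {
    cuts <- c(0, b$times)
    rates <- rate_mult * b$rates
    width <- diff(cuts)
    Hcum <- c(0, cumsum(rates[seq_along(width)] * width))
    vapply(h, function(hh) {
      j <- findInterval(hh, Hcum)
      if (j > length(width)) {
        cuts[length(cuts)] + (hh - Hcum[length(Hcum)]) / rates[length(rates)]
      } else {
        cuts[j] + (hh - Hcum[j]) / rates[j]
      }
    }, numeric(1))
  }
}

draw_times <- function(scenario, lp, rate_mult, tv = NULL) {
  u <- stats::runif(length(lp))
  target <- -log(u) / exp(lp)          # required baseline cumulative hazard
  if (is.null(tv)) return(invert_cumhaz(scenario, target, rate_mult))
  # time-varying effect on one covariate, beta(t) = beta * (1 + delta *
  # ln(1 + t)): the +1 keeps the hazard integrable at t -> 0. Solve
  # H(t | x) = -log(u) numerically per subject.
  b <- scenario$baseline
  if (!is.numeric(b))
    stop_config("tv_effect requires the Weibull baseline")
  rate <- rate_mult * b[["rate"]]; shape <- b[["shape"]]
  beta_k <- scenario$coefficients[tv$covariate]
  cap <- 1e4   # beyond any realistic follow-up; treated as never failing
  vapply(seq_along(lp), function(i) {
    xk <- tv$x[i]
    f <- function(t) {
      integrand <- function(s)
        rate * shape * s^(shape - 1) *
          exp(lp[i] + tv$delta * beta_k * xk * log1p(s))
      stats::integrate(integrand, 0, t, rel.tol = 1e-8,
                       subdivisions = 500L)$value + log(u[i])
    }
    hi <- 1
    while (hi < cap && f(hi) < 0) hi <- hi * 2
    if (f(min(hi, cap)) < 0) return(cap)
    stats::uniroot(f, c(1e-12, min(hi, cap)), tol = 1e-10)$root
  }, numeric(1))
}

apply_censoring <- function(scenario, t_event) {
  cens <- rep(Inf, length(t_event))
  if (!is.null(scenario$dropout))
    cens <- stats::runif(length(t_event), scenario$dropout[1],
                         scenario$dropout[2])
  if (!is.null(scenario$admin_censoring))
    cens <- pmin(cens, scenario$admin_censoring)
  data.frame(time = pmin(t_event, cens),
             event = as.numeric(t_event <= cens))
}

#' Generate a derivation/validation dataset pair
#'
#' Both arms share the covariate distributions and true coefficients; the
#' validation arm additionally applies the scenario's slope multiplier,
#' baseline hazard multiplier and case-mix shrinkage. Each returned data
#' frame carries `time`, `event`, the covariate columns and `true_lp`, the
#' (uncentered) true linear predictor.
#'
#' @param scenario a [simulation_scenario()].
#' @return list with elements `derivation` and `validation`.
#' @export
generate_samples <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  arms <- list()
  for (arm in c("derivation", "validation")) {
    valid <- arm == "validation"
    n <- if (valid) scenario$n_validation else scenario$n_derivation
    X <- draw_covariates(scenario, n,
                         shrink = if (valid) scenario$case_mix_shrinkage else 1)
    lp <- drop(X %*% scenario$coefficients)
    if (valid) lp <- scenario$slope_multiplier * lp
    tv <- scenario$tv_effect
    if (!is.null(tv)) tv$x <- X[, tv$covariate]
    t_event <- draw_times(scenario, lp,
                          rate_mult = if (valid) scenario$hazard_multiplier
                                      else 1, tv = tv)
    d <- cbind(apply_censoring(scenario, t_event), as.data.frame(X))
    d$true_lp <- lp
    if (sum(d$event) == 0)
      stop_data("scenario produced no events in the %s arm (n = %d, censoring too heavy?)",
                arm, n)
    arms[[arm]] <- d
  }
  arms
}

#' Build a published-model facsimile from a derivation sample
#'
#' Fits a Cox model to the named covariates of the derivation arm and
#' packages the result the way a publication would: the coefficients as a
#' [published_model()] centered on the derivation mean linear predictor
#' ("level 1"), risk-group cutpoints at the Cox centiles ("level 2"), and an
#' FP2-smoothed baseline cumulative hazard ("level 3"). This lets the entire
#' validation pipeline run end-to-end on synthetic data.
#'
#' @param data derivation-arm data frame (at least 50 events).
#' @param covariates covariate column names; default all `x*` columns.
#' @param n_groups number of risk groups.
#' @param time_unit label for the time scale.
#' @param ties tie handling for the Cox fit.
#' @return list with elements `model` ([published_model()]), `grouping`
#'   ([cox_cutpoints()] result), `baseline` (`fp2_fit`) and `fit` (the
#'   derivation `cox_fit`).
#' @export
apparent_scenario <- function(data, covariates = grep("^x[0-9]+$",
                                                      names(data),
                                                      value = TRUE),
                              n_groups = 4, time_unit = "years",
                              ties = "efron") {
  if (sum(data$event) < 50)
    stop_data("apparent_scenario needs at least 50 events in the derivation arm")
  fit <- fit_cox(data, covariates = covariates, ties = ties)
  coefs <- fit$coefficients
  ses <- sqrt(diag(fit$covariance))
  names(coefs) <- names(ses) <- gsub("`", "", names(coefs))
  terms <- lapply(covariates, function(nm)
    cov_term(nm, unname(coefs[[nm]]), se = unname(ses[[nm]])))
  lp <- drop(as.matrix(data[, covariates]) %*%
               vapply(terms, function(t) t$coefficient, numeric(1)))
  model <- published_model(terms, centering = mean(lp),
                           time_unit = time_unit,
                           max_followup = max(data$time))
  pi <- lp - mean(lp)
  grouping <- cox_cutpoints(pi, n_groups = n_groups)
  baseline <- fit_fp2_log_cumhaz(baseline_cumhaz(data$time, data$event, pi),
                                 time_unit = time_unit)
  list(model = model, grouping = grouping, baseline = baseline, fit = fit)
}

#' Read or write a simulation scenario (YAML)
#'
#' @param scenario a [simulation_scenario()].
#' @param path file path.
#' @return `read_scenario()` returns a [simulation_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  s <- unclass(scenario)
  if (is.numeric(s$baseline))
    s$baseline <- as.list(s$baseline)   # keep rate/shape names in the YAML
  yaml::write_yaml(s, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  spec <- yaml::read_yaml(path)
  args <- spec[intersect(names(spec), names(formals(simulation_scenario)))]
  if (is.list(args$baseline) && !is.null(args$baseline$rate))
    args$baseline <- unlist(args$baseline)     # Weibull read back as a list
  if (!is.null(args$dropout)) args$dropout <- as.numeric(args$dropout)
  do.call(simulation_scenario, args)
}
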
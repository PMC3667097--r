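# Cox machinery used by every validation method. Partial-likelihood fitting
# is delegated to survival::coxph; the offset-constrained Breslow baseline is
# computed here because it must accept an externally supplied prognostic
# index with its coefficient fixed at 1.

#' Fit a Cox model, optionally with a fixed offset
#'
#' Thin wrapper around [survival::coxph()] exposing the pieces the validation
#' methods need: coefficients, their covariance (inverse observed
#' information), and the partial log-likelihood at the optimum. The offset is
#' an exact linear term with coefficient fixed at 1. The zero-covariate case
#' (offset only, or null model) is supported and returns the log-likelihood,
#' which the likelihood-ratio tests use.
#'
#' @param data data frame with follow-up time, event indicator and covariates.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param offset optional name of a column held fixed with coefficient 1.
#' @param ties tie handling for the partial likelihood, `"efron"` (default)
#'   or `"breslow"`.
#' @param time,event names of the time and event columns.
#' @return object of class `cox_fit` with elements `coefficients`,
#'   `covariance`, `log_likelihood`, `n_subjects`, `n_events`, `offset_used`,
#'   `ties_method` and the underlying `coxph` fit (`NULL` for covariate-free
#'   models).
#' @examples
#' d <- data.frame(time = rexp(50), event = rbinom(50, 1, 0.7), x = rnorm(50))
#' fit_cox(d, "x")
#' @export
fit_cox <- function(data, covariates = character(), offset = NULL,
                    ties = c("efron", "breslow"),
                    time = "time", event = "event") {
  ties <- match.arg(ties)
  check_surv_cols(data, time, event)
  if (sum(data[[event]]) < 1) stop_data("no events in the data")
  for (nm in c(covariates, offset)) {
    if (!nm %in% names(data)) stop_config("column '%s' not found", nm)
    if (any(!is.finite(as.numeric(data[[nm]]))))
      stop_data("column '%s' contains non-finite values", nm)
  }
  rhs <- c(sprintf("`%s`", covariates),
           if (!is.null(offset)) sprintf("offset(`%s`)", offset))
  if (!length(rhs)) rhs <- "1"
  fml <- stats::as.formula(sprintf("survival::Surv(`%s`, `%s`) ~ %s",
                                   time, event, paste(rhs, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties, model = FALSE,
                    x = length(covariates) > 0),
    warning = function(w) {
      if (grepl("did not converge|infinite|singular|out of iterations",
                conditionMessage(w))) {
        stop_numeric("Cox fit failed: %s", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  coefs <- stats::coef(fit)
  if (length(coefs) && any(!is.finite(coefs) | abs(coefs) > 20))
    stop_numeric("Cox fit appears not to have converged (monotone likelihood?); coefficients: %s",
                 paste(format(coefs, digits = 3), collapse = ", "))
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(coefficients = coefs,
                 covariance = if (length(coefs)) stats::vcov(fit) else NULL,
                 log_likelihood = ll,
                 log_likelihood_null = fit$loglik[1L],
                 n_subjects = fit$n, n_events = fit$nevent,
                 offset_used = !is.null(offset), ties_method = ties,
                 fit = if (length(coefs)) fit else NULL),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit:", x$n_subjects, "subjects,", x$n_events, "events (ties:",
      paste0(x$ties_method, if (x$offset_used) ", with offset" else "", ")\n"))
  if (length(x$coefficients)) {
    se <- sqrt(diag(x$covariance))
    print(data.frame(coef = x$coefficients, se = se,
                     z = x$coefficients / se))
  } else cat("(no covariates)\n")
  cat("partial log-likelihood:", format(x$log_likelihood), "\n")
  invisible(x)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate with Greenwood standard errors. Subjects censored
#' at an event time are treated as still at risk at that time (the usual
#' convention of [survival::survfit()]).
#'
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return [step_curve()] (survival flavour) at the distinct event times.
#' @export
kaplan_meier <- function(time, event) {
  d <- data.frame(time = time, event = event)
  check_surv_cols(d, "time", "event")
  if (!nrow(d)) stop_data("no subjects")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                          conf.type = "none")
  sm <- summary(sf, censored = FALSE)
  keep <- sm$n.event > 0
  step_curve(sm$time[keep], sm$surv[keep], flavour = "survival",
             se = sm$std.err[keep], at_risk = sm$n.risk[keep],
             n_events = sm$n.event[keep])
}

#' Baseline cumulative hazard with the prognostic index as a fixed offset
#'
#' Breslow-type estimator of the baseline cumulative hazard \eqn{H_0(t)} under
#' the model \eqn{\ln h(t) = \ln h_0(t) + PI} with the PI coefficient
#' constrained to 1 (no coefficient is estimated). Because the PI is centered
#' on the derivation mean, the curve is the cumulative hazard at the mean
#' prognostic index. With all PI values equal to zero it reduces to the
#' Nelson-Aalen estimator.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param pi centered prognostic index per subject.
#' @return [step_curve()] (cumulative-hazard flavour) with pointwise standard
#'   errors, risk-set sizes and event counts.
#' @export
baseline_cumhaz <- function(time, event, pi) {
  d <- data.frame(time = time, event = event)
  check_surv_cols(d, "time", "event")
  if (length(pi) != length(time) || any(!is.finite(pi)))
    stop_data("pi must be a finite value per subject")
  if (sum(event) < 1) stop_data("no events in the data")
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; w <- exp(pi[ord])
  # risk-set sums of exp(pi): reverse cumulative sums over sorted times
  rev_w <- rev(cumsum(rev(w)))
  rev_n <- rev(cumsum(rev(rep(1, length(w)))))
  et <- unique(t_s[e_s == 1])
  first_idx <- match(et, t_s)           # first subject with time >= et
  denom <- rev_w[first_idx]
  nrisk <- rev_n[first_idx]
  dvec <- vapply(et, function(u) sum(e_s[t_s == u]), numeric(1))
  dH <- dvec / denom
  H <- cumsum(dH)
  se <- sqrt(cumsum(dvec / denom^2))
  step_curve(et, H, flavour = "cumhaz", se = se, at_risk = nrisk,
             n_events = dvec)
}

#' Baseline survival from a cumulative-hazard curve
#'
#' Converts a baseline cumulative hazard to a baseline survival curve, either
#' as \eqn{\exp(-H_0)} (default, consistent with the fractional-polynomial
#' smooth of \eqn{\ln H_0}) or by the product-limit form
#' \eqn{\prod (1 - \Delta H_0)}, the "Kaplan-Meier-like" estimate, which
#' reduces to the Kaplan-Meier curve when all PI values are zero.
#'
#' @param curve cumulative-hazard [step_curve()] from [baseline_cumhaz()].
#' @param method `"exp"` or `"product-limit"`.
#' @return survival-flavour [step_curve()].
#' @export
cumhaz_to_survival <- function(curve, method = c("exp", "product-limit")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "step_curve"), curve$flavour == "cumhaz")
  dH <- diff(c(0, curve$values))
  s <- if (method == "exp") exp(-curve$values) else cumprod(pmax(1 - dH, 0))
  se <- if (!is.null(curve$se)) s * curve$se else NULL  # delta method
  step_curve(curve$times, s, flavour = "survival", se = se,
             at_risk = curve$at_risk, n_events = curve$n_events)
}

#' Logrank test between risk groups (deprecated as a validation check)
#'
#' Standard logrank chi-squared test that the risk groups' survival curves
#' coincide. Provided for completeness only: a significant result does not
#' quantify discrimination, it merely rejects the null hypothesis that the
#' groups do not differ at all, which is rarely in doubt. Reports carry this
#' caveat.
#'
#' @param time follow-up times.
#' @param event event indicators.
#' @param group group labels (factor or vector), at least two non-empty
#'   groups.
#' @return object of class `logrank_test` with `statistic`, `df`, `p_value`
#'   and the deprecation `caveat`.
#' @export
logrank_test <- function(time, event, group) {
  d <- data.frame(time = time, event = event, group = factor(group))
  check_surv_cols(d, "time", "event")
  d <- droplevels(d)
  if (nlevels(d$group) < 2L)
    stop_config("logrank test needs at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- nlevels(d$group) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp,
                 caveat = .caveats$logrank),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Logrank test: chi-squared = %.3f on %d df, P = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat("Note:", x$caveat, "\n")
  invisible(x)
}
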
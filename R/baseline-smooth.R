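# Fractional-polynomial (FP2) smoothing of the baseline log cumulative
# hazard. The smooth form is the transportable "level 3" information: three
# coefficients and two powers reproduce the whole baseline survival curve, so
# a publication can carry it and a validation study can reconstruct absolute
# survival predictions.

#' The fractional-polynomial power set
#'
#' The standard FP power set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, power 0
#' denoting the logarithm.
#'
#' @return numeric vector of powers.
#' @export
fp2_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' FP2 basis functions of time
#'
#' Two basis columns for a pair of powers \eqn{(p_1, p_2)}: \eqn{t^{p_1}} and
#' \eqn{t^{p_2}}, with power 0 meaning \eqn{\ln t} and a repeated power
#' \eqn{(p, p)} giving \eqn{t^p} and \eqn{t^p \ln t}.
#'
#' @param t strictly positive times.
#' @param powers numeric pair of powers.
#' @return matrix with two columns.
#' @examples
#' fp2_basis(4, c(-0.5, -0.5))  # (0.5, 0.5 * log(4))
#' @export
fp2_basis <- function(t, powers) {
  if (length(powers) != 2L || any(!is.finite(powers)))
    stop_config("powers must be a pair of finite numbers")
  if (any(!is.finite(t)) || any(t <= 0))
    stop_config("FP basis requires strictly positive times")
  p <- sort(powers)
  one <- function(p) if (p == 0) log(t) else t^p
  b1 <- one(p[1])
  b2 <- if (p[1] == p[2]) b1 * log(t) else one(p[2])
  cbind(b1, b2)
}

#' Fit an FP2 approximation to the log baseline cumulative hazard
#'
#' For every pair of powers from the FP2 power set, regresses
#' \eqn{\ln H_0(t_i)} on the FP2 basis at the event times by ordinary least
#' squares, and keeps the pair with the smallest residual sum of squares.
#' The model is
#' \deqn{\ln H_0(t) = \gamma_0 + \gamma_1 t^{p_1} + \gamma_2 t^{p_2},}
#' with the usual FP conventions for power 0 and repeated powers. A fitted
#' curve that is not non-decreasing over the observed time range earns a
#' monotonicity warning (a cumulative hazard cannot decrease).
#'
#' @param baseline cumulative-hazard [step_curve()], e.g. from
#'   [baseline_cumhaz()].
#' @param powers optional power set; defaults to [fp2_powers()].
#' @param time_unit label stored with the fit.
#' @return object of class `fp2_fit` with `powers`, `coefficients`
#'   (\eqn{\gamma_0, \gamma_1, \gamma_2}), `r_squared`, `rss`, `time_range`,
#'   `time_unit`, `monotone`, and the per-pair search table `search`.
#' @export
fit_fp2_log_cumhaz <- function(baseline, powers = fp2_powers(),
                               time_unit = "years") {
  stopifnot(inherits(baseline, "step_curve"))
  if (baseline$flavour != "cumhaz")
    stop_config("fit_fp2_log_cumhaz needs a cumulative-hazard curve")
  keep <- baseline$values > 0 & baseline$times > 0
  t <- baseline$times[keep]
  y <- log(baseline$values[keep])
  if (length(t) < 8L)
    stop_data("need at least 8 event times with positive cumulative hazard (have %d)",
              length(t))
  pairs <- expand.grid(p1 = powers, p2 = powers)
  pairs <- pairs[pairs$p1 <= pairs$p2, ]
  tss <- sum((y - mean(y))^2)
  best <- NULL
  search <- data.frame(p1 = pairs$p1, p2 = pairs$p2, rss = NA_real_)
  for (k in seq_len(nrow(pairs))) {
    B <- cbind(1, fp2_basis(t, c(pairs$p1[k], pairs$p2[k])))
    fit <- stats::lm.fit(B, y)
    rss <- sum(fit$residuals^2)
    search$rss[k] <- rss
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, powers = c(pairs$p1[k], pairs$p2[k]),
                   coefficients = unname(fit$coefficients))
  }
  out <- structure(list(powers = best$powers,
                        coefficients = best$coefficients,
                        r_squared = if (tss > 0) 1 - best$rss / tss else 1,
                        rss = best$rss,
                        time_range = range(t), time_unit = time_unit,
                        monotone = NA, search = search),
                   class = "fp2_fit")
  grid <- seq(out$time_range[1], out$time_range[2], length.out = 200)
  lh <- evaluate_log_cumhaz(out, grid)
  out$monotone <- all(diff(lh) >= -1e-8)
  if (!out$monotone)
    warning("fitted log cumulative hazard is not monotone over the observed time range")
  out
}

#' @export
print.fp2_fit <- function(x, digits = 4, ...) {
  g <- format(x$coefficients, digits = digits)
  cat(sprintf("FP2 fit to ln H0(t), powers (%g, %g):\n", x$powers[1],
              x$powers[2]))
  cat(sprintf("  ln H0(t) = %s + %s * B1(t) + %s * B2(t)\n", g[1], g[2], g[3]))
  cat(sprintf("  R-squared %.4f over t in [%s, %s] %s%s\n", x$r_squared,
              format(x$time_range[1], digits = 3),
              format(x$time_range[2], digits = 3), x$time_unit,
              if (isFALSE(x$monotone)) " [non-monotone!]" else ""))
  invisible(x)
}

check_times <- function(fit, times, extrapolate) {
  if (any(!is.finite(times)) || any(times <= 0))
    stop_config("evaluation times must be strictly positive")
  outside <- times < fit$time_range[1] - 1e-12 |
    times > fit$time_range[2] + 1e-12
  if (any(outside)) {
    if (!extrapolate)
      stop_config("evaluation outside the fitted time range [%s, %s]; truncate the follow-up or pass extrapolate = TRUE",
                  format(fit$time_range[1]), format(fit$time_range[2]))
    warning("extrapolating the baseline beyond the fitted time range")
  }
  invisible(TRUE)
}

#' Evaluate a fitted FP2 baseline
#'
#' `evaluate_log_cumhaz()` returns \eqn{\ln H_0(t)};
#' `evaluate_s0()` returns the baseline survival
#' \eqn{S_0(t) = \exp[-\exp(\ln H_0(t))]}. Evaluation outside the fitted
#' time range is refused unless `extrapolate = TRUE`, because the FP2 form
#' has no support there.
#'
#' @param fit an `fp2_fit` (for `evaluate_s0()`, alternatively a
#'   [baseline_lookup()]).
#' @param times strictly positive evaluation times.
#' @param extrapolate allow evaluation outside the fitted range.
#' @return numeric vector.
#' @export
evaluate_log_cumhaz <- function(fit, times, extrapolate = FALSE) {
  stopifnot(inherits(fit, "fp2_fit"))
  check_times(fit, times, extrapolate)
  drop(cbind(1, fp2_basis(times, fit$powers)) %*% fit$coefficients)
}

#' @rdname evaluate_log_cumhaz
#' @export
evaluate_s0 <- function(fit, times, extrapolate = FALSE) {
  UseMethod("evaluate_s0")
}

#' @export
evaluate_s0.fp2_fit <- function(fit, times, extrapolate = FALSE) {
  exp(-exp(evaluate_log_cumhaz(fit, times, extrapolate)))
}

#' Bootstrap confidence band for the smoothed baseline cumulative hazard
#'
#' Resamples subjects with replacement; in each replicate fits a Cox model to
#' the prognostic index, computes the Breslow baseline cumulative hazard at
#' the replicate's mean linear predictor, fits the best FP2 approximation to
#' its logarithm, and evaluates it on a fixed time grid. The pointwise band
#' is the replicate mean plus/minus 1.96 standard deviations on the log
#' cumulative-hazard scale, back-transformed. Replicates that end up with no
#' events are redrawn (and counted).
#'
#' @param time,event,pi subject-level follow-up, event indicator and
#'   prognostic index.
#' @param n_boot number of bootstrap replicates (the default, 100, is usually
#'   adequate for a pointwise band).
#' @param seed integer seed; required so the band is reproducible.
#' @param grid_length number of equally spaced grid times between the first
#'   and last event time.
#' @return object of class `bootstrap_band` with `times`, `lower`, `upper`,
#'   `center` (back-transformed replicate mean), `n_boot`, `seed`,
#'   `n_redrawn`.
#' @export
bootstrap_band <- function(time, event, pi, n_boot = 100, seed,
                           grid_length = 100) {
  if (missing(seed) || !is.finite(seed))
    stop_config("bootstrap_band requires an integer seed")
  if (n_boot < 2) stop_config("n_boot must be at least 2")
  d <- data.frame(time = time, event = event, pi = pi)
  check_surv_cols(d, "time", "event")
  et <- sort(unique(time[event == 1]))
  grid <- seq(min(et), max(et), length.out = grid_length)
  set.seed(as.integer(seed))
  n <- nrow(d)
  mat <- matrix(NA_real_, nrow = n_boot, ncol = grid_length)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      db <- d[idx, ]
      if (sum(db$event) >= 8 &&
          length(unique(db$time[db$event == 1])) >= 8) break
      n_redrawn <- n_redrawn + 1L
    }
    fit_b <- fit_cox(db, covariates = "pi")
    eta <- unname(fit_b$coefficients[[1]]) * db$pi
    eta <- eta - mean(eta)                # baseline at the mean PI
    H_b <- baseline_cumhaz(db$time, db$event, eta)
    fp_b <- suppressWarnings(fit_fp2_log_cumhaz(H_b))
    # replicate event ranges differ slightly from the fixed grid; the mild
    # extrapolation at the ends is intended here
    mat[b, ] <- suppressWarnings(
      evaluate_log_cumhaz(fp_b, grid, extrapolate = TRUE))
  }
  m <- colMeans(mat)
  s <- apply(mat, 2, stats::sd)
  structure(list(times = grid, lower = exp(m - 1.96 * s),
                 upper = exp(m + 1.96 * s), center = exp(m),
                 n_boot = n_boot, seed = as.integer(seed),
                 n_redrawn = n_redrawn),
            class = "bootstrap_band")
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("Bootstrap band for H0(t): %d replicates (seed %d, %d redrawn), grid of %d times on [%s, %s]\n",
              x$n_boot, x$seed, x$n_redrawn, length(x$times),
              format(min(x$times), digits = 3),
              format(max(x$times), digits = 3)))
  invisible(x)
}

# ---- serialization: the transportable L3 information ----

#' Read or write a fitted FP2 baseline
#'
#' Serializes the powers, coefficients, fit diagnostics and validity range to
#' the same YAML dialect as the model specification; this is the "level 3"
#' information a publication would carry.
#'
#' @param fit an `fp2_fit`.
#' @param path file path.
#' @return `read_baseline()` returns an `fp2_fit`.
#' @export
write_baseline <- function(fit, path) {
  stopifnot(inherits(fit, "fp2_fit"))
  yaml::write_yaml(list(powers = fit$powers, coefficients = fit$coefficients,
                        r_squared = fit$r_squared,
                        time_range = fit$time_range,
                        time_unit = fit$time_unit),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  spec <- yaml::read_yaml(path)
  for (f in c("powers", "coefficients", "time_range"))
    if (length(spec[[f]]) < 2L) stop_config("baseline spec '%s' lacks '%s'",
                                            path, f)
  structure(list(powers = as.numeric(spec$powers),
                 coefficients = as.numeric(spec$coefficients),
                 r_squared = spec$r_squared %||% NA_real_, rss = NA_real_,
                 time_range = as.numeric(spec$time_range),
                 time_unit = spec$time_unit %||% "years",
                 monotone = NA, search = NULL),
            class = "fp2_fit")
}

#' Baseline survival published as a look-up table
#'
#' Some models are published with baseline survival values at a few time
#' points rather than a smooth function. Between tabulated times, evaluation
#' interpolates linearly on the \eqn{\ln H_0} scale (which keeps survival
#' inside (0, 1) and monotone).
#'
#' @param times strictly increasing positive times.
#' @param s0 baseline survival values in (0, 1), non-increasing.
#' @param time_unit label.
#' @return object of class `baseline_lookup` (also answers [evaluate_s0()]).
#' @export
baseline_lookup <- function(times, s0, time_unit = "years") {
  if (length(times) != length(s0) || length(times) < 2L)
    stop_config("need at least two (time, s0) pairs")
  if (any(times <= 0) || any(diff(times) <= 0))
    stop_config("times must be positive and strictly increasing")
  if (any(s0 <= 0 | s0 >= 1) || any(diff(s0) > 0))
    stop_config("s0 must be non-increasing values in (0, 1)")
  structure(list(times = times, s0 = s0, log_cumhaz = log(-log(s0)),
                 time_range = range(times), time_unit = time_unit),
            class = "baseline_lookup")
}

#' @export
evaluate_s0.baseline_lookup <- function(fit, times, extrapolate = FALSE) {
  check_times(fit, times, extrapolate)
  lh <- stats::approx(fit$times, fit$log_cumhaz, xout = times,
                      rule = 2)$y
  exp(-exp(lh))
}

#' Read or write a look-up-table baseline (CSV with columns time, s0)
#'
#' @param lookup a [baseline_lookup()].
#' @param path file path.
#' @return `read_baseline_lookup()` returns a [baseline_lookup()].
#' @export
write_baseline_lookup <- function(lookup, path) {
  stopifnot(inherits(lookup, "baseline_lookup"))
  utils::write.csv(data.frame(time = lookup$times, s0 = lookup$s0), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline_lookup
#' @export
read_baseline_lookup <- function(path) {
  tab <- utils::read.csv(path)
  baseline_lookup(tab$time, tab$s0)
}
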
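# Discrimination measures for a prognostic index under right censoring.
# c, D and R2_D depend on the PI only through its ranks; K depends on the
# spacing of PI values but not on the outcome at all, which is what makes it
# unbiased under censoring.

#' Constants used by the discrimination measures
#'
#' \eqn{\sigma^2 = \pi^2/6 \approx 1.645} plays the role of the residual
#' variance on the log relative-hazard scale of a proportional-hazards model;
#' \eqn{\kappa = \sqrt{8/\pi} \approx 1.596} is the scaling factor in the
#' rankit construction of the D statistic.
#'
#' @return named numeric vector with elements `sigma2` and `kappa`.
#' @export
discrim_constants <- function() {
  c(sigma2 = pi^2 / 6, kappa = sqrt(8 / pi))
}

#' Harrell's c-index of concordance
#'
#' The proportion of evaluable patient pairs in which predictions and
#' outcomes are concordant: the member with the higher prognostic index has
#' the shorter survival. Under right censoring a pair is evaluable when the
#' shorter follow-up time ends in an event; pairs tied on time are evaluable
#' only when exactly one member has an event (the event member is taken to
#' fail first). Pairs tied on the PI contribute 1/2. The standard error is
#' the exact delete-one jackknife over subjects.
#'
#' Note that c is biased away from 0.5 by heavy right-censoring.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param pi prognostic-index values.
#' @return list with `estimate`, `se`, `n_pairs` (evaluable pairs),
#'   `concordant`, `tied_pi`.
#' @export
harrell_c <- function(time, event, pi) {
  d <- data.frame(time = time, event = event)
  check_surv_cols(d, "time", "event")
  if (length(pi) != length(time) || any(!is.finite(pi)))
    stop_data("pi must be a finite value per subject")
  n <- length(time)
  U <- numeric(n)  # per-subject concordance score sum over pairs
  V <- numeric(n)  # per-subject evaluable-pair count
  for (i in seq_len(n)) {
    dt <- time - time[i]
    # pair (i, j) with i the earlier failure: i has event and t_i < t_j,
    # or t_i == t_j with i the only event
    i_first <- event[i] == 1 & (dt > 0 | (dt == 0 & event == 0))
    j_first <- event == 1 & (dt < 0 | (dt == 0 & event[i] == 0))
    ev <- i_first | j_first
    ev[i] <- FALSE
    if (!any(ev)) next
    dpi <- pi - pi[i]
    score <- numeric(n)
    # concordant: the earlier failure has the higher pi
    score[i_first & dpi < 0] <- 1
    score[j_first & dpi > 0] <- 1
    score[ev & dpi == 0] <- 0.5
    U[i] <- sum(score[ev])
    V[i] <- sum(ev)
  }
  D_tot <- sum(V)                      # each pair counted twice
  if (D_tot == 0) stop_data("no evaluable pairs under this censoring pattern")
  est <- sum(U) / D_tot
  loo <- (sum(U) - 2 * U) / (D_tot - 2 * V)
  loo[!is.finite(loo)] <- est
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, n_pairs = D_tot / 2,
       concordant = sum(U) / 2)
}

#' Gonen and Heller's concordance probability K
#'
#' An analogue of the area under the ROC curve for time-to-event models that
#' uses only the distribution of the prognostic index, not the outcome: under
#' the proportional-hazards model the probability that the member of a pair
#' with the lower PI outlives the other is a logistic function of the PI
#' difference. Averaging over all pairs gives
#' \deqn{K = \binom{n}{2}^{-1} \sum_{i<j} \frac{1}{1 + \exp(-|PI_i - PI_j|)}.}
#' Because the outcome is not used, K is unaffected by censoring.
#'
#' @param pi prognostic-index values (at least 2 subjects).
#' @param se_method `"jackknife"` (delete-one over subjects, default) or
#'   `"bootstrap"`.
#' @param n_boot bootstrap replicates when `se_method = "bootstrap"`.
#' @param seed optional seed for the bootstrap.
#' @return list with `estimate` and `se`.
#' @export
gonen_heller_k <- function(pi, se_method = c("jackknife", "bootstrap"),
                           n_boot = 200, seed = NULL) {
  se_method <- match.arg(se_method)
  if (length(pi) < 2L || any(!is.finite(pi)))
    stop_data("K needs at least two finite pi values")
  n <- length(pi)
  if (length(unique(pi)) == 1L) {
    warning("all pi values are equal; K is 0.5 by convention")
    return(list(estimate = 0.5, se = 0))
  }
  U <- vapply(seq_len(n), function(i)
    sum(stats::plogis(abs(pi[i] - pi[-i]))), numeric(1))
  est <- sum(U) / (n * (n - 1))
  if (se_method == "jackknife") {
    loo <- (sum(U) - 2 * U) / ((n - 1) * (n - 2))
    se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  } else {
    if (!is.null(seed)) set.seed(seed)
    reps <- replicate(n_boot, {
      b <- sample(pi, n, replace = TRUE)
      Ub <- vapply(seq_len(n), function(i)
        sum(stats::plogis(abs(b[i] - b[-i]))), numeric(1))
      sum(Ub) / (n * (n - 1))
    })
    se <- stats::sd(reps)
  }
  list(estimate = est, se = se)
}

#' Royston-Sauerbrei D statistic of prognostic separation
#'
#' D is obtained by ordering the PI, replacing each value by its rankit (the
#' expected standard-Normal order statistic, here Blom's approximation
#' \eqn{\Phi^{-1}((i - 3/8)/(n + 1/4))}, with tied PI values receiving the
#' average of their rankits), dividing by \eqn{\kappa = \sqrt{8/\pi}}, and
#' fitting a Cox model to the scaled rankits. The coefficient is D, on the
#' log hazard-ratio scale: the log hazard ratio between the prognostic halves
#' of an idealised Normal prognostic index.
#'
#' @inheritParams harrell_c
#' @param ties tie handling passed to the Cox fit.
#' @return list with `estimate`, `se` and the underlying `cox_fit`.
#' @export
d_statistic <- function(time, event, pi, ties = "efron") {
  d <- data.frame(time = time, event = event)
  check_surv_cols(d, "time", "event")
  if (length(pi) != length(time) || any(!is.finite(pi)))
    stop_data("pi must be a finite value per subject")
  if (length(unique(pi)) == 1L) {
    warning("pi is constant; D is 0")
    return(list(estimate = 0, se = NA_real_, fit = NULL))
  }
  d$z <- scaled_rankits(pi)
  fit <- fit_cox(d, "z", ties = ties)
  list(estimate = unname(fit$coefficients["z"]),
       se = sqrt(diag(fit$covariance))[["z"]], fit = fit)
}

scaled_rankits <- function(pi) {
  n <- length(pi)
  blom <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  ord <- order(pi)
  z <- numeric(n)
  z[ord] <- blom
  # average rankits within ties
  z <- stats::ave(z, match(pi, pi))
  z / discrim_constants()[["kappa"]]
}

#' Explained variation R2_D from the D statistic
#'
#' \deqn{R^2_D = \frac{D^2/\kappa^2}{\sigma^2 + D^2/\kappa^2}}
#' with \eqn{\kappa^2 = 8/\pi} and \eqn{\sigma^2 = \pi^2/6}.
#'
#' @param d D statistic value(s).
#' @return explained-variation fraction(s) in [0, 1).
#' @export
r2_d <- function(d) {
  stopifnot(all(is.finite(d)))
  k2 <- 8 / pi
  (d^2 / k2) / (pi^2 / 6 + d^2 / k2)
}

#' Explained variation R2_PM from the spread of the prognostic index
#'
#' \deqn{R^2_{PM} = \frac{s^2}{\sigma^2 + s^2}} where \eqn{s} is the standard
#' deviation of the PI and \eqn{\sigma^2 = \pi^2/6} plays the role of the
#' residual variance of a proportional-hazards model. The outcome is not
#' used, so R2_PM is computable in a validation dataset from the PI alone.
#'
#' @param pi_sd standard deviation(s) of the prognostic index.
#' @return explained-variation fraction(s) in [0, 1).
#' @export
r2_pm <- function(pi_sd) {
  stopifnot(all(is.finite(pi_sd)), all(pi_sd >= 0))
  pi_sd^2 / (pi^2 / 6 + pi_sd^2)
}

#' All discrimination measures for one dataset
#'
#' Computes Harrell's c, Gonen-Heller K, the D statistic, and the
#' explained-variation measures R2_D and R2_PM, together with the spread of
#' the prognostic index and the constants used.
#'
#' @inheritParams harrell_c
#' @param ... passed to [gonen_heller_k()] (`se_method`, `n_boot`, `seed`).
#' @return object of class `discrimination_report`.
#' @export
discrimination_report <- function(time, event, pi, ...) {
  cst <- discrim_constants()
  c_res <- harrell_c(time, event, pi)
  k_res <- gonen_heller_k(pi, ...)
  d_res <- d_statistic(time, event, pi)
  s <- stats::sd(pi)
  # delta-method SE for R2_D as a function of D
  k2 <- cst[["kappa"]]^2
  dR <- 2 * d_res$estimate / k2 * cst[["sigma2"]] /
    (cst[["sigma2"]] + d_res$estimate^2 / k2)^2
  structure(list(
    harrell_c = c_res[c("estimate", "se")],
    gonen_heller_k = k_res[c("estimate", "se")],
    d_statistic = d_res[c("estimate", "se")],
    r2_d = list(estimate = r2_d(d_res$estimate),
                se = abs(dR) * d_res$se),
    r2_pm = list(estimate = r2_pm(s)),
    pi_sd = s, constants = cst,
    caveat = .caveats$c_bias),
    class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, digits = 3, ...) {
  cat("Discrimination measures\n")
  print(as.data.frame(x), digits = digits, row.names = FALSE)
  cat(sprintf("PI spread s = %.3f; sigma2 = %.3f, kappa = %.3f\n",
              x$pi_sd, x$constants[["sigma2"]], x$constants[["kappa"]]))
  cat("Note:", x$caveat, "\n")
  invisible(x)
}

#' @export
as.data.frame.discrimination_report <- function(x, ...) {
  measures <- c(harrell_c = "Harrell c-index",
                gonen_heller_k = "Gonen & Heller K",
                d_statistic = "D statistic",
                r2_d = "Explained variation (R2_D)",
                r2_pm = "Explained variation (R2_PM)")
  data.frame(
    measure = unname(measures),
    estimate = vapply(names(measures), function(m) x[[m]]$estimate,
                      numeric(1)),
    se = vapply(names(measures), function(m) x[[m]]$se %||% NA_real_,
                numeric(1)))
}
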
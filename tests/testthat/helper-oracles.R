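# Independent oracles: deliberately naive hand-coded implementations used to
# check the package's estimators on small inputs. They share no code with the
# package internals.

# Cox partial log-likelihood at a fixed linear predictor eta (one covariate
# times a trial coefficient, say), Breslow or Efron handling of tied events.
oracle_partial_loglik <- function(time, event, eta, ties = "efron") {
  ll <- 0
  for (u in unique(time[event == 1])) {
    D <- which(time == u & event == 1)
    R <- which(time >= u)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    if (ties == "breslow") {
      ll <- ll - d * log(sumR)
    } else {
      for (r in seq_len(d) - 1) ll <- ll - log(sumR - (r / d) * sumD)
    }
  }
  ll
}

# Two-stage grid search for the maximum-partial-likelihood coefficient of a
# single covariate.
oracle_cox_grid <- function(time, event, x, ties = "efron",
                            lo = -4, hi = 4) {
  grid_max <- function(bs) {
    ll <- vapply(bs, function(b)
      oracle_partial_loglik(time, event, b * x, ties), numeric(1))
    bs[which.max(ll)]
  }
  b1 <- grid_max(seq(lo, hi, by = 0.01))
  grid_max(seq(b1 - 0.02, b1 + 0.02, by = 1e-5))
}

# Brute-force O(n^2) concordance: a pair is evaluable when the shorter time
# is an event (ties in time: only when exactly one member has an event, the
# event member failing first); concordant when the earlier failure has the
# higher pi; pi ties score 1/2.
oracle_c <- function(time, event, pi) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    first <- if (time[i] < time[j]) i
             else if (time[j] < time[i]) j
             else if (event[i] + event[j] == 1) c(i, j)[which.max(c(event[i], event[j]))]
             else NA
    if (is.na(first) || event[first] == 0) next
    other <- if (first == i) j else i
    den <- den + 1
    if (pi[first] > pi[other]) num <- num + 1
    else if (pi[first] == pi[other]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# Explicit double sum for the concordance probability K.
oracle_k <- function(pi) {
  n <- length(pi)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + 1 / (1 + exp(-abs(pi[i] - pi[j])))
  s / choose(n, 2)
}

# Hand product-limit estimator at the distinct event times.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(et))
  for (k in seq_along(et)) {
    d <- sum(time == et[k] & event == 1)
    r <- sum(time >= et[k])
    s <- s * (1 - d / r)
    surv[k] <- s
  }
  list(times = et, surv = surv)
}

# Hand Nelson-Aalen estimator.
oracle_na <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  H <- cumsum(vapply(et, function(u)
    sum(time == u & event == 1) / sum(time >= u), numeric(1)))
  list(times = et, cumhaz = H)
}

# Hand two-group logrank: observed-minus-expected with hypergeometric
# variance.
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  OmE <- 0; V <- 0
  for (u in sort(unique(time[event == 1]))) {
    d <- sum(time == u & event == 1)
    at <- time >= u
    n <- sum(at); n1 <- sum(at & g == 1)
    d1 <- sum(time == u & event == 1 & g == 1)
    e1 <- d * n1 / n
    OmE <- OmE + d1 - e1
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

# Quick random censored dataset for property tests.
random_surv <- function(n, beta = 0.7, cens_rate = 0.3) {
  x <- stats::rnorm(n)
  t_ev <- stats::rexp(n, exp(beta * x))
  t_cn <- stats::rexp(n, cens_rate)
  data.frame(time = round(pmin(t_ev, t_cn), 3),  # rounding induces ties
             event = as.numeric(t_ev <= t_cn), x = x)
}
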
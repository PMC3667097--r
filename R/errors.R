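# Error taxonomy: configuration errors (bad model spec / options), data errors
# (problems in the validation dataset), numerical errors (non-convergence,
# degenerate fits). CLI exit codes map onto these classes.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("coxval_config_error", "coxval_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("coxval_data_error", "coxval_error")))
}

stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("coxval_numeric_error", "coxval_error")))
}

# Caveat texts attached to results whose naive interpretation the validation
# literature warns against; carried verbatim into printed reports.
.caveats <- list(
  slope = paste("The P-value for slope = 1 may be anti-conservative: it does",
                "not allow for uncertainty in the published coefficients."),
  case_mix = paste("A narrower case mix in the validation sample shrinks the",
                   "spread of the prognostic index and with it all",
                   "discrimination measures, without the model being wrong."),
  logrank = paste("Deprecated check: a significant logrank/Cox test between",
                  "risk groups only rejects the null hypothesis that the",
                  "groups' survival coincides; it does not quantify",
                  "discrimination."),
  ph = paste("A breach of proportional hazards need not invalidate the",
             "model's discrimination; calibration should be scrutinised."),
  c_bias = paste("Harrell's c is biased away from 0.5 under right-censoring;",
                 "K does not use the outcome and is unaffected.")
)
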
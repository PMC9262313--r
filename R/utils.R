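# Classed error helpers so callers can distinguish contract violations
# without matching message text.

abort_invalid <- function(msg) {
  stop(errorCondition(msg,
    class = c("echopvr_invalid_measurement", "echopvr_error")))
}

abort_insufficient <- function(msg) {
  stop(errorCondition(msg,
    class = c("echopvr_insufficient_data", "echopvr_error")))
}

abort_undefined <- function(msg) {
  stop(errorCondition(msg,
    class = c("echopvr_undefined_correlation", "echopvr_error")))
}

abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("echopvr_config_error", "echopvr_error")))
}

abort_pairing <- function(msg) {
  stop(errorCondition(msg, class = c("echopvr_pairing_error", "echopvr_error")))
}

# Inverse-CDF draw from a truncated normal; vectorised over n.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Location a normal must have so that, after truncation below at `lower`
# with scale `sd`, the realized mean equals `target`.
trunc_location_for_mean <- function(target, sd, lower) {
  if (sd == 0 || lower <= target - 8 * sd) return(target)
  f <- function(m) {
    a <- (lower - m) / sd
    m + sd * dnorm(a) / (1 - pnorm(a)) - target
  }
  uniroot(f, c(target - 6 * sd, target))$root
}

#' @importFrom stats dnorm
NULL
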
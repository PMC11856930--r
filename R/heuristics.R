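#' Asynchrony-contingent bias update
#'
#' The asynchrony-contingent observer compensates for the measured SOA, but
#' scales the update rate by the likelihood that the stimuli were physically
#' simultaneous, `p(m | SOA = 0)` (a density, units 1/s, evaluated under the
#' observer's current bias):
#' `delta - p(m | SOA = 0) * alpha * m`.
#' The update therefore vanishes exponentially as `|m|` leaves the range of
#' measurements plausible under simultaneity — in contrast to the
#' asynchrony-correction rule, whose updates grow linearly in `|m|` beyond
#' its criterion.
#'
#' Because the rule multiplies by a density, the learning rate `alpha` absorbs
#' the 1/seconds scale.  Setting `normalize = TRUE` divides the likelihood by
#' its peak value `1/(tau_a + tau_v)`, giving a dimensionless scaling factor
#' in `[0, 1]`; this variant is off by default.
#'
#' @param model a [meas_model()] carrying the observer's current bias and time
#'   constants.
#' @param delta cumulative bias shift before the trial (s).
#' @param m measured SOA on the trial (s).
#' @param alpha learning rate, >= 0 (units 1 when `normalize = TRUE`,
#'   seconds otherwise).
#' @param normalize if `TRUE`, scale the likelihood to a maximum of 1.
#' @return Updated cumulative shift (s).
#' @export
contingent_bias_update <- function(model, delta, m, alpha, normalize = FALSE) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  lik <- simultaneity_likelihood(model, m)
  if (normalize) lik <- lik * (model$tau_a + model$tau_v)
  delta - lik * alpha * m
}

#' Asynchrony-correction bias update
#'
#' The asynchrony-correction observer recalibrates only when the measured SOA
#' exceeds the simultaneity criterion: if `|m| > criterion` the cumulative
#' shift becomes `delta - alpha * m`, otherwise it is left unchanged.  The
#' comparison is strict at equality.  The same criterion parameter `c` is used
#' here and in the ternary temporal-order judgment.
#'
#' @param delta cumulative bias shift before the trial (s).
#' @param m measured SOA on the trial (s).
#' @param alpha learning rate, >= 0.
#' @param criterion simultaneity criterion `c` in seconds, > 0.
#' @return Updated cumulative shift (s).
#' @export
correction_bias_update <- function(delta, m, alpha, criterion) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  if (any(criterion <= 0)) stop("'criterion' must be strictly positive")
  ifelse(abs(m) > criterion, delta - alpha * m, delta)
}
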
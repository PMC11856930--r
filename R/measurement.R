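#' Double-exponential measurement model of audiovisual asynchrony
#'
#' The arrival latency of each sensory signal is modelled as a fixed delay plus
#' an exponentially distributed random delay with time constant `tau_a`
#' (auditory) or `tau_v` (visual).  The measured stimulus-onset asynchrony
#' (SOA, `m = arrival_A - arrival_V`, negative values = auditory lead) is then
#' the physical SOA `s` plus the audiovisual temporal bias `bias` plus the
#' difference of two exponential variates, which follows an asymmetric
#' double-exponential (asymmetric Laplace) distribution peaking at `s + bias`.
#'
#' @param bias audiovisual temporal bias in seconds (current bias
#'   `beta = beta_pre + delta_beta`).
#' @param tau_a auditory exponential time constant in seconds (> 0).
#' @param tau_v visual exponential time constant in seconds (> 0).
#'
#' @return An object of class `"meas_model"`: a list with elements `bias`,
#'   `tau_a` and `tau_v`.
#' @examples
#' mm <- meas_model(bias = 0.03, tau_a = 0.06, tau_v = 0.07)
#' measurement_density(mm, m = 0.03, s = 0)   # peak: 1 / (tau_a + tau_v)
#' @export
meas_model <- function(bias, tau_a, tau_v = tau_a) {
  stopifnot(is.numeric(bias), length(bias) == 1L, is.finite(bias),
            is.numeric(tau_a), length(tau_a) == 1L, is.finite(tau_a),
            is.numeric(tau_v), length(tau_v) == 1L, is.finite(tau_v))
  if (tau_a <= 0 || tau_v <= 0)
    stop("time constants 'tau_a' and 'tau_v' must be strictly positive")
  structure(list(bias = bias, tau_a = tau_a, tau_v = tau_v),
            class = "meas_model")
}

#' @export
print.meas_model <- function(x, ...) {
  cat("Double-exponential SOA measurement model\n")
  cat(sprintf("  bias  : %+.4f s\n  tau_a : %.4f s\n  tau_v : %.4f s\n",
              x$bias, x$tau_a, x$tau_v))
  invisible(x)
}

check_meas_model <- function(model) {
  if (!inherits(model, "meas_model"))
    stop("'model' must be a 'meas_model' object; see meas_model()")
  model
}

#' Density of the measured SOA
#'
#' Two-branch double-exponential density of the measured SOA `m` given the
#' physical SOA `s`: the left branch (`m <= s + bias`) decays away from the
#' peak with the visual time constant `tau_v`, the right branch with the
#' auditory time constant `tau_a`.  Both branches take the value
#' `1 / (tau_a + tau_v)` at the peak `m = s + bias` (the kink itself is
#' assigned to the left branch; the density is continuous there).
#'
#' @param model a [meas_model()].
#' @param m measured SOA(s), seconds.  Vectorised.
#' @param s physical stimulus SOA, seconds (scalar or same length as `m`).
#' @return Density values (units 1/seconds), strictly positive.
#' @export
measurement_density <- function(model, m, s = 0) {
  check_meas_model(model)
  if (!all(is.finite(m)) || !all(is.finite(s)))
    stop("'m' and 's' must be finite numeric values")
  x <- m - (s + model$bias)
  d <- ifelse(x <= 0, exp(x / model$tau_v), exp(-x / model$tau_a))
  d / (model$tau_a + model$tau_v)
}

#' Distribution function of the measured SOA
#'
#' Closed-form CDF of the double-exponential measurement distribution:
#' `F(m) = tau_v/(tau_a+tau_v) * exp((m-(s+bias))/tau_v)` for
#' `m <= s + bias`, and `1 - tau_a/(tau_a+tau_v) * exp(-(m-(s+bias))/tau_a)`
#' above the peak.
#'
#' @inheritParams measurement_density
#' @return Probabilities in `[0, 1]`, nondecreasing in `m`.
#' @export
measurement_cdf <- function(model, m, s = 0) {
  check_meas_model(model)
  if (!all(is.finite(m)) || !all(is.finite(s)))
    stop("'m' and 's' must be finite numeric values")
  ta <- model$tau_a; tv <- model$tau_v
  x <- m - (s + model$bias)
  ifelse(x <= 0,
         tv / (ta + tv) * exp(x / tv),
         1 - ta / (ta + tv) * exp(-x / ta))
}

#' Quantile function of the measured SOA
#'
#' Inverse of [measurement_cdf()]; used for inverse-CDF sampling with common
#' random numbers so that simulated quantities vary smoothly with the
#' parameters.
#'
#' @inheritParams measurement_density
#' @param p probabilities in `(0, 1)`.
#' @return Measured SOAs in seconds.
#' @export
measurement_quantile <- function(model, p, s = 0) {
  check_meas_model(model)
  if (any(p <= 0) || any(p >= 1) || !all(is.finite(p)))
    stop("'p' must lie strictly within (0, 1)")
  ta <- model$tau_a; tv <- model$tau_v
  pv <- tv / (ta + tv)
  x <- ifelse(p <= pv,
              tv * log(p / pv),
              -ta * log((1 - p) * (ta + tv) / ta))
  s + model$bias + x
}

#' Sample measured SOAs
#'
#' Draws `m = s + bias + E_A - E_V`, where `E_A` and `E_V` are independent
#' exponential variates with means `tau_a` and `tau_v`.
#'
#' @inheritParams measurement_density
#' @param n number of draws (`n = 0` returns an empty vector).
#' @param rng_seed optional integer seed; when given, draws are reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @export
sample_measurements <- function(model, s = 0, n, rng_seed = NULL) {
  check_meas_model(model)
  stopifnot(length(n) == 1L, n >= 0)
  if (n == 0) return(numeric(0))
  with_seed(rng_seed, {
    s + model$bias + stats::rexp(n, rate = 1 / model$tau_a) -
      stats::rexp(n, rate = 1 / model$tau_v)
  })
}

#' Likelihood that the stimuli were simultaneous
#'
#' The probability density of observing measurement `m` had the physical SOA
#' been exactly zero, `p(m | SOA = 0)`, evaluated under the model's current
#' bias.  This is the quantity the asynchrony-contingent observer uses to
#' scale its bias updates; it is maximal (`1/(tau_a+tau_v)`) at `m = bias`
#' and decays exponentially with the distance from it.
#'
#' @inheritParams measurement_density
#' @return Density values (1/seconds).
#' @seealso [contingent_bias_update()]
#' @export
simultaneity_likelihood <- function(model, m) {
  measurement_density(model, m, s = 0)
}

# Evaluate expr with a locally-seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible 31-bit substream seed from a base seed and labels.
# The multiplier keeps every intermediate product below 2^53 so the modular
# arithmetic is exact in double precision.
substream_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 17
  for (v in ids)
    h <- (h * 69069 + (as.numeric(v) %% 2147483647) + 12345) %% 2147483647
  as.integer(h)
}
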
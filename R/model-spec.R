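#' The six observer models
#'
#' An observer model is the combination of a bias-update rule used during the
#' exposure phase — Bayesian causal inference, asynchrony-contingent, or
#' asynchrony-correction — with either modality-specific (separate `tau_a`,
#' `tau_v`) or modality-independent (`tau_a = tau_v = tau`) precision of the
#' arrival latencies.  Six short codes identify the combinations:
#'
#' * `"ci_ms"`, `"ci_mi"` — causal inference, modality-specific/-independent;
#' * `"ac_ms"`, `"ac_mi"` — asynchrony-contingent;
#' * `"corr_ms"`, `"corr_mi"` — asynchrony-correction.
#'
#' Free parameters follow the update rule: the causal-inference models carry
#' `beta_pre`, the time constant(s), `sigma_c1`, `sigma_c2`, `p_common`,
#' `criterion`, `lambda` and `alpha`; the two heuristic rules drop the three
#' causal-prior parameters.
#'
#' @param model either a six-letter code as above, or an update rule
#'   (`"causal_inference"`, `"asynchrony_contingent"`,
#'   `"asynchrony_correction"`) together with `precision`.
#' @param precision `"modality_specific"` or `"modality_independent"`;
#'   ignored when `model` is a short code.
#' @return An object of class `"recal_model_spec"` with elements `code`,
#'   `update_rule`, `precision`, `par_names` and `bounds` (2-row matrix).
#' @examples
#' recal_model("ci_ms")
#' recal_model("asynchrony_correction", "modality_independent")
#' @export
recal_model <- function(model = c("ci_ms", "ci_mi", "ac_ms", "ac_mi",
                                  "corr_ms", "corr_mi",
                                  "causal_inference", "asynchrony_contingent",
                                  "asynchrony_correction"),
                        precision = c("modality_specific",
                                      "modality_independent")) {
  model <- match.arg(model)
  codes <- c(causal_inference = "ci", asynchrony_contingent = "ac",
             asynchrony_correction = "corr")
  if (model %in% names(codes)) {
    precision <- match.arg(precision)
    rule <- model
    code <- paste0(codes[[model]],
                   if (precision == "modality_specific") "_ms" else "_mi")
  } else {
    code <- model
    rule <- names(codes)[match(sub("_m[si]$", "", code), codes)]
    precision <- if (grepl("_ms$", code)) "modality_specific"
                 else "modality_independent"
  }
  taus <- if (precision == "modality_specific") c("tau_a", "tau_v") else "tau"
  par_names <- c("beta_pre", taus,
                 if (rule == "causal_inference")
                   c("sigma_c1", "sigma_c2", "p_common"),
                 "criterion", "lambda", "alpha")
  structure(list(code = code, update_rule = rule, precision = precision,
                 par_names = par_names,
                 bounds = default_bounds(par_names, rule)),
            class = "recal_model_spec")
}

MODEL_CODES <- c("ci_ms", "ci_mi", "ac_ms", "ac_mi", "corr_ms", "corr_mi")

# Fitting bounds.  The source experiment prints no fitting ranges; these are
# plausibility ranges for human audiovisual timing: time constants between 5
# and 500 ms, criteria up to half a second, lapse rate bounded away from zero
# so the likelihood stays finite.  The asynchrony-contingent learning rate is
# given a wider range because it multiplies a density (units 1/s) and so
# absorbs a 1/(tau_a+tau_v) scale.
default_bounds <- function(par_names, rule) {
  lo <- c(beta_pre = -0.3, tau_a = 0.005, tau_v = 0.005, tau = 0.005,
          sigma_c1 = 0.001, sigma_c2 = 0.05, p_common = 0,
          criterion = 0.001, lambda = 1e-4, alpha = 0)
  hi <- c(beta_pre = 0.3, tau_a = 0.5, tau_v = 0.5, tau = 0.5,
          sigma_c1 = 0.3, sigma_c2 = 3, p_common = 1,
          criterion = 0.5, lambda = 0.2,
          alpha = if (rule == "asynchrony_contingent") 2 else 0.1)
  rbind(lower = lo[par_names], upper = hi[par_names])
}

#' @export
print.recal_model_spec <- function(x, ...) {
  cat(sprintf("Observer model '%s': %s update rule, %s precision\n",
              x$code, gsub("_", "-", x$update_rule),
              gsub("_", "-", x$precision)))
  cat("  free parameters:", paste(x$par_names, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter table of an observer model
#'
#' @param spec a [recal_model()] specification.
#' @return A data frame with columns `parameter`, `lower`, `upper`.
#' @export
model_parameters <- function(spec) {
  check_spec(spec)
  data.frame(parameter = spec$par_names,
             lower = spec$bounds["lower", ],
             upper = spec$bounds["upper", ],
             row.names = NULL)
}

check_spec <- function(spec) {
  if (!inherits(spec, "recal_model_spec"))
    stop("'spec' must be a 'recal_model_spec'; see recal_model()")
  spec
}

#' Validate a named parameter vector against a model specification
#'
#' Checks that `params` names exactly the model's free parameters, that all
#' values are finite and within bounds, and that `sigma_c1 < sigma_c2` for the
#' causal-inference models.
#'
#' @param spec a [recal_model()] specification.
#' @param params named numeric vector.
#' @return `params` (invisibly), reordered to the canonical parameter order.
#' @export
validate_params <- function(spec, params) {
  check_spec(spec)
  missing <- setdiff(spec$par_names, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), spec$par_names)
  if (length(extra))
    stop("unknown parameter(s) for model '", spec$code, "': ",
         paste(extra, collapse = ", "))
  params <- params[spec$par_names]
  if (!all(is.finite(params))) stop("parameters must be finite")
  bad <- params < spec$bounds["lower", ] | params > spec$bounds["upper", ]
  if (any(bad))
    stop("parameter(s) out of bounds: ",
         paste(spec$par_names[bad], collapse = ", "))
  if (spec$update_rule == "causal_inference" &&
      params[["sigma_c1"]] >= params[["sigma_c2"]])
    stop("'sigma_c1' must be smaller than 'sigma_c2'")
  invisible(params)
}

# Expand a model-specific parameter vector into the full internal list used
# by the simulation and likelihood code (always carries tau_a and tau_v).
expand_params <- function(spec, params) {
  p <- as.list(params[spec$par_names])
  if (spec$precision == "modality_independent") {
    p$tau_a <- p$tau
    p$tau_v <- p$tau
  }
  p
}

# Measurement model generating the data at a given current bias.
params_meas_model <- function(p, bias) {
  meas_model(bias = bias, tau_a = p$tau_a, tau_v = p$tau_v)
}

params_prior <- function(p) {
  causal_prior(p$sigma_c1, p$sigma_c2, p$p_common)
}
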
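TRIAL_COLUMNS <- c("participant", "session", "adapter_soa_s", "phase",
                   "trial", "test_soa_s", "response")

#' Read a trial table
#'
#' Reads trial-level ternary TOJ records from delimited text with a header row
#' and columns `participant`, `session`, `adapter_soa_s`, `phase`
#' (`pre`/`post`), `trial`, `test_soa_s`, `response` (`A`/`S`/`V`).  All SOAs
#' are in seconds, with negative values denoting auditory lead; files whose
#' SOA magnitudes exceed 5 are rejected as probably millisecond-valued unless
#' `units = "ms"` is given, in which case they are converted on read.
#' Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @param units `"s"` (default) or `"ms"`.
#' @return A validated trial data frame.
#' @export
read_trials <- function(path, sep = ",", units = c("s", "ms")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) return(df[, TRIAL_COLUMNS])
  if (units == "ms") {
    df$adapter_soa_s <- df$adapter_soa_s / 1000
    df$test_soa_s <- df$test_soa_s / 1000
  }
  line_of <- function(i) i + 1L  # header occupies line 1
  bad <- which(!df$response %in% c("A", "S", "V"))
  if (length(bad))
    stop("invalid response code(s) '",
         paste(unique(df$response[bad]), collapse = "', '"),
         "' at line(s) ", paste(line_of(bad), collapse = ", "))
  bad <- which(!df$phase %in% c("pre", "post"))
  if (length(bad))
    stop("invalid phase at line(s) ", paste(line_of(bad), collapse = ", "),
         " (must be 'pre' or 'post')")
  bad <- which(!is.finite(df$test_soa_s) | !is.finite(df$adapter_soa_s))
  if (length(bad))
    stop("non-numeric SOA at line(s) ", paste(line_of(bad), collapse = ", "))
  if (any(abs(df$test_soa_s) > 5) || any(abs(df$adapter_soa_s) > 5))
    stop("SOA magnitudes exceed 5; values look like milliseconds - ",
         "re-read with units = \"ms\"")
  df[, TRIAL_COLUMNS]
}

#' Write a trial table
#'
#' Writes trial records as comma-separated text (seconds everywhere), the
#' format [read_trials()] reads back losslessly.
#'
#' @param data trial data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(data[, TRIAL_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize a model fit to JSON
#'
#' Stores the estimates, log-likelihood, per-start results, settings and seed
#' of a [fit_recalibration()] result as structured JSON for provenance.
#'
#' @param fit a `"recal_fit"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "recal_fit"))
  out <- list(model = fit$spec$code, par = as.list(fit$par),
              loglik = fit$logLik, n_obs = fit$n_obs,
              starts = fit$starts, control = fit$control,
              rng_seed = fit$rng_seed,
              package = as.character(utils::packageVersion("avrecal")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized model fit
#'
#' @param path JSON file written by [write_fit()].
#' @return A list with elements `model`, `par` (named numeric), `loglik`,
#'   `n_obs`, `starts`, `control`, `rng_seed`.
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$par <- unlist(x$par)
  x
}
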
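#' @keywords internal
"_PACKAGE"

# Inverse logit / logit on the log-odds scale used throughout.
inv_logit <- function(eta) stats::plogis(eta)
logit <- function(p) stats::qlogis(p)

#' Format a count as a percentage of a denominator
#'
#' Reporting helper used by every textual summary in the package: returns
#' `100 * num / den` rounded to `digits` decimal places, i.e. the number
#' printed in a report line such as "14227/363040 (3.9%)".
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimal places (default 1, the convention of clinical
#'   reporting).
#' @return numeric scalar, the rounded percentage.
#' @examples
#' pct(14227, 363040)  # 3.9
#' @export
pct <- function(num, den, digits = 1) {
  stopifnot(is.numeric(num), is.numeric(den), den > 0)
  round(100 * num / den, digits)
}

#' Cohort exclusion accounting
#'
#' Bookkeeping for the record-exclusion step of a pipeline run: given a raw
#' record count and the number excluded (e.g. for invalid procedure codes),
#' returns the analysed count and the exclusion percentage as they appear in
#' the run report.
#'
#' @param n_raw raw record count before exclusions.
#' @param n_excluded number of records dropped.
#' @return list with `n_raw`, `n_excluded`, `n_included`, `pct_excluded`.
#' @export
exclusion_report <- function(n_raw, n_excluded) {
  stopifnot(n_excluded >= 0, n_excluded <= n_raw)
  list(
    n_raw = n_raw,
    n_excluded = n_excluded,
    n_included = n_raw - n_excluded,
    pct_excluded = pct(n_excluded, n_raw)
  )
}

# Machine-parsable event logging to stderr: "ssirs [event] key=value ...".
log_event <- function(event, ...) {
  kv <- list(...)
  msg <- paste0(
    "ssirs [", event, "]",
    if (length(kv)) paste0(" ", paste(names(kv), unname(kv), sep = "=", collapse = " ")) else ""
  )
  message(msg)
  invisible(msg)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stop with a classed condition so callers/tests can distinguish validation
# errors (bad input) from runtime errors.
stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("ssirs_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
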
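# Cohort columns, in canonical CSV order. Shared by the generator, the
# validator and the CSV reader/writer.
COHORT_COLUMNS <- c(
  "record_id", "age", "sex", "bmi", "smoker", "functional_status",
  "peripheral_vascular_disease", "metastatic_cancer", "chronic_steroid_use",
  "preop_sepsis", "setting", "wound_class", "asa_class", "anaesthesia",
  "multiple_procedures", "housestaff", "duration_hours", "cpt_code", "ssi30"
)

CATEGORY_DOMAINS <- list(
  sex = c("female", "male"),
  functional_status = c("independent", "partially_dependent", "totally_dependent"),
  setting = c("ambulatory", "inpatient_elective", "emergency"),
  wound_class = c("clean", "clean_contaminated", "contaminated", "dirty"),
  asa_class = c("1", "2", "3", "4", "5"),
  anaesthesia = c("general", "other")
)

LOGICAL_COLUMNS <- c(
  "smoker", "peripheral_vascular_disease", "metastatic_cancer",
  "chronic_steroid_use", "preop_sepsis", "multiple_procedures",
  "housestaff", "ssi30"
)

draw_covariate <- function(cv, n) {
  switch(cv$kind,
    binary = stats::runif(n) < cv$prevalence,
    categorical = factor(
      sample(cv$levels, n, replace = TRUE, prob = cv$probs),
      levels = cv$levels
    ),
    continuous = {
      if (identical(cv$dist, "lognormal")) {
        stats::rlnorm(n, cv$meanlog, cv$sdlog)
      } else if (identical(cv$dist, "truncnorm")) {
        # truncation by resampling; tails are a tiny fraction of mass here
        x <- stats::rnorm(n, cv$mean, cv$sd)
        bad <- which(x < cv$floor | x > cv$ceiling)
        while (length(bad)) {
          x[bad] <- stats::rnorm(length(bad), cv$mean, cv$sd)
          bad <- bad[x[bad] < cv$floor | x[bad] > cv$ceiling]
        }
        x
      } else {
        stop_validation("covariate_spec[%s]$dist: unknown distribution '%s'", cv$name, cv$dist)
      }
    },
    stop_validation("covariate_spec[%s]$kind: unknown kind", cv$name)
  )
}

# g(x) for a continuous true-model term: (x/scale)^power, power 0 = log.
true_term_g <- function(x, term) {
  z <- x / term$scale
  if (term$power == 0) log(z) else z^term$power
}

# Linear predictor WITHOUT intercept and WITHOUT group offset.
true_linear_predictor <- function(data, true_model) {
  eta <- numeric(nrow(data))
  for (nm in names(true_model$terms)) {
    if (!nm %in% names(data)) {
      stop_validation("true_model covariate '%s' absent from data", nm)
    }
    term <- true_model$terms[[nm]]
    x <- data[[nm]]
    if (is.list(term)) {
      term <- utils::modifyList(list(power = 1, scale = 1, center = 0), term)
      centre <- if (term$center > 0) true_term_g(term$center, term) else 0
      eta <- eta + term$coef * (true_term_g(x, term) - centre)
    } else if (is.factor(x) || is.character(x)) {
      coefs <- term
      idx <- match(as.character(x), names(coefs))
      eta <- eta + ifelse(is.na(idx), 0, coefs[idx])
    } else {
      eta <- eta + term * as.numeric(x)
    }
  }
  eta
}

#' Generate a synthetic NSQIP-like surgical cohort
#'
#' Draws `config$n_records` operations from the configured covariate
#' marginals, assigns each a 5-character CPT code whose 3-digit prefix is
#' sampled from the configured group set, computes the ground-truth SSI
#' probability as the inverse logit of
#' `intercept + true covariate effects + group offset`, and draws the
#' binary 30-day SSI outcome from it. When `true_model$intercept` is
#' `NULL` the intercept is tuned (by monotone root finding on this cohort's
#' realised linear predictors) so that the mean true risk equals
#' `event_rate_target`.
#'
#' Generation is bit-reproducible: identical config and seed give an
#' identical cohort.
#'
#' @param config a [cohort_config()].
#' @return a `data.frame` with one row per operation and the documented
#'   cohort columns; attributes `config` (with the resolved intercept) and
#'   `true_risk` (the per-record ground-truth probability) are attached for
#'   verification work.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- as.integer(config$n_records)
  groups <- config$cpt_groups

  data <- with_seed(config$seed, {
    cols <- list(record_id = sprintf("R%07d", seq_len(n)))
    for (cv in config$covariate_spec) cols[[cv$name]] <- draw_covariate(cv, n)
    gidx <- sample.int(groups$n_groups, n, replace = TRUE, prob = groups$weights)
    cols$cpt_code <- paste0(groups$prefixes[gidx], sprintf("%02d",
      sample.int(100L, n, replace = TRUE) - 1L))
    df <- as.data.frame(cols, stringsAsFactors = FALSE)

    eta0 <- true_linear_predictor(df, config$true_model) + groups$offsets[gidx]
    intercept <- config$true_model$intercept
    if (is.null(intercept)) {
      intercept <- if (n == 0) logit(config$event_rate_target) else
        tune_intercept(eta0, config$event_rate_target)
    }
    p <- inv_logit(intercept + eta0)
    df$ssi30 <- stats::runif(n) < p

    attr(df, "true_risk") <- unname(p)
    attr(df, "resolved_intercept") <- intercept
    df
  })

  cfg <- config
  cfg$true_model$intercept <- attr(data, "resolved_intercept")
  p <- attr(data, "true_risk")
  data <- data[, COHORT_COLUMNS[COHORT_COLUMNS %in% names(data)],
               drop = FALSE]
  attr(data, "true_risk") <- p
  attr(data, "config") <- cfg
  data
}

# Mean inverse-logit is strictly increasing in the intercept, so the target
# rate has a unique root.
tune_intercept <- function(eta0, target) {
  f <- function(b) mean(inv_logit(b + eta0)) - target
  stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}

#' Ground-truth SSI probability of a record under a configuration
#'
#' Pure function of the record and the configured true model: inverse logit
#' of the intercept plus the sum of true covariate effects plus the
#' record's CPT-group log-odds offset. The configuration must carry a
#' resolved (non-`NULL`) intercept — use the `config` attribute attached by
#' [generate_cohort()] when the intercept was tuned to an event-rate
#' target.
#'
#' @param records data.frame of one or more cohort rows.
#' @param config a `cohort_config` with resolved intercept.
#' @return numeric vector of probabilities in (0,1).
#' @export
true_risk <- function(records, config) {
  if (is.null(config$true_model$intercept)) {
    stop_validation("true_model$intercept is NULL; use the resolved config attached to a generated cohort")
  }
  prefix <- substr(records$cpt_code, 1, 3)
  off <- config$cpt_groups$offsets[prefix]
  if (anyNA(off)) {
    stop_validation("cpt prefix not in configured group set: %s",
                    paste(unique(prefix[is.na(off)]), collapse = ", "))
  }
  eta <- config$true_model$intercept +
    true_linear_predictor(records, config$true_model) + unname(off)
  inv_logit(eta)
}

#' Validate a cohort data.frame against the record schema
#'
#' Checks column presence and the record invariants: positive BMI,
#' nonnegative duration, ASA class in 1..5, categories within their
#' declared domains, and CPT codes of 5 characters whose first three are
#' digits.
#'
#' @param records cohort data.frame.
#' @return the records, invisibly; errors name the offending column/row.
#' @export
validate_cohort <- function(records) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop_validation("cohort missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(records) == 0) return(invisible(records))
  if (any(records$bmi <= 0)) stop_validation("bmi: must be > 0")
  if (any(records$duration_hours < 0)) stop_validation("duration_hours: must be >= 0")
  for (nm in names(CATEGORY_DOMAINS)) {
    vals <- as.character(records[[nm]])
    bad <- which(!vals %in% CATEGORY_DOMAINS[[nm]])
    if (length(bad)) {
      stop_validation("%s: invalid level '%s' at row %d", nm, vals[bad[1]], bad[1])
    }
  }
  bad_cpt <- which(!grepl("^[0-9]{3}..$", records$cpt_code) |
                     nchar(records$cpt_code) != 5)
  if (length(bad_cpt)) {
    stop_validation("cpt_code: malformed code '%s' at row %d (record %s)",
                    records$cpt_code[bad_cpt[1]], bad_cpt[1],
                    records$record_id[bad_cpt[1]])
  }
  invisible(records)
}
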
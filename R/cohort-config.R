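#' Configuration of the synthetic surgical-cohort generator
#'
#' Describes a ground-truth risk world from which NSQIP-like cohorts are
#' drawn: covariate marginals, a true logistic risk model on the log-odds
#' scale, and a set of 3-digit procedure-code (CPT prefix) groups each
#' carrying its own log-odds offset. The group offsets create the
#' between-procedure risk heterogeneity that the CPT3 observed/expected
#' score is designed to capture, which makes the whole derivation pipeline
#' testable by score and parameter recovery.
#'
#' Group offsets and sampling weights, when not supplied, are materialised
#' once at construction from a stream derived from `seed`, so that
#' [true_risk()] is a pure function of (record, config) and repeated calls
#' to [generate_cohort()] are bit-reproducible.
#'
#' @param n_records number of operations to generate (>= 0).
#' @param seed integer seed governing every random draw.
#' @param covariate_spec list of covariate definitions; each element is a
#'   list with `name`, `kind` (`"binary"`, `"categorical"`, `"continuous"`)
#'   and, depending on kind, `prevalence`, `levels` + `probs`, or a
#'   distribution (`dist` in `"lognormal"`, `"truncnorm"` with its
#'   parameters). See [default_covariate_spec()].
#' @param true_model list with `intercept` (log-odds; `NULL` to tune it to
#'   `event_rate_target`) and `terms`, a named list of per-covariate true
#'   effects: a scalar log-odds ratio for binary covariates, a named vector
#'   of per-level log-odds (reference level 0) for categorical ones, and a
#'   list `(coef, power, scale, center)` for continuous ones, contributing
#'   `coef * (g(x) - g(center))` with `g(x) = (x/scale)^power` and power 0
#'   read as the natural log.
#' @param cpt_groups list with `n_groups` (>= 1), `offset_sd` (SD of the
#'   normal from which per-group log-odds offsets are drawn), and optional
#'   explicit `offsets` and `weights` vectors (length `n_groups`).
#' @param event_rate_target overall SSI fraction in (0,1) used to tune the
#'   intercept when `true_model$intercept` is `NULL`. Default 0.039, the
#'   order of magnitude of 30-day SSI incidence in large surgical
#'   registries.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()], [true_risk()], [default_cohort_config()]
#' @export
cohort_config <- function(n_records,
                          seed = 1L,
                          covariate_spec = default_covariate_spec(),
                          true_model = default_true_model(),
                          cpt_groups = list(n_groups = 290L, offset_sd = 0.4),
                          event_rate_target = 0.039) {
  cfg <- list(
    n_records = n_records, seed = as.integer(seed),
    covariate_spec = covariate_spec, true_model = true_model,
    cpt_groups = cpt_groups, event_rate_target = event_rate_target
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg$cpt_groups <- materialise_groups(cfg)
  cfg
}

# Draw group offsets/weights once, from a stream decoupled from the one used
# for record-level draws so adding records never changes the group structure.
materialise_groups <- function(cfg) {
  g <- cfg$cpt_groups
  n <- as.integer(g$n_groups)
  if (n > 890L) {
    stop_validation("cpt_groups$n_groups: at most 890 distinct 3-digit prefixes supported, got %d", n)
  }
  g$prefixes <- sprintf("%03d", 100L + seq_len(n) - 1L)
  group_seed <- bitwXor(cfg$seed, 1193846613L)
  if (is.null(g$offsets)) {
    g$offsets <- with_seed(group_seed, stats::rnorm(n, 0, g$offset_sd))
  }
  if (is.null(g$weights)) {
    # long-tailed group sizes, as in registry data where a few procedure
    # families dominate
    g$weights <- with_seed(bitwXor(group_seed, 7L), stats::rlnorm(n, 0, 1))
  }
  names(g$offsets) <- g$prefixes
  names(g$weights) <- g$prefixes
  g
}

#' @rdname cohort_config
#' @export
validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) stop_validation("not a cohort_config")
  if (!is.numeric(config$n_records) || length(config$n_records) != 1 ||
      config$n_records < 0 || config$n_records != floor(config$n_records)) {
    stop_validation("n_records: must be a nonnegative integer")
  }
  for (cv in config$covariate_spec) {
    nm <- cv$name
    if (identical(cv$kind, "binary")) {
      if (cv$prevalence < 0 || cv$prevalence > 1) {
        stop_validation("covariate_spec[%s]$prevalence: must lie in [0,1]", nm)
      }
    } else if (identical(cv$kind, "categorical")) {
      if (any(cv$probs < 0) || any(cv$probs > 1) ||
          abs(sum(cv$probs) - 1) > 1e-8 || length(cv$probs) != length(cv$levels)) {
        stop_validation("covariate_spec[%s]$probs: must lie in [0,1] and sum to 1 over levels", nm)
      }
    } else if (!identical(cv$kind, "continuous")) {
      stop_validation("covariate_spec[%s]$kind: unknown kind '%s'", nm, cv$kind)
    }
  }
  g <- config$cpt_groups
  if (is.null(g$n_groups) || g$n_groups < 1) {
    stop_validation("cpt_groups$n_groups: must be >= 1")
  }
  if (!is.null(g$weights)) {
    if (any(g$weights < 0) || all(g$weights == 0)) {
      stop_validation("cpt_groups$weights: must be nonnegative and not all zero")
    }
  }
  ert <- config$event_rate_target
  if (!is.null(ert) && (ert <= 0 || ert >= 1)) {
    stop_validation("event_rate_target: must lie in (0,1)")
  }
  invisible(config)
}

#' Default covariate marginals for the synthetic cohort
#'
#' Prevalences and distributions mirror the qualitative description of a
#' large 2010 general-surgery registry cohort: roughly one third ambulatory,
#' one half elective inpatient and 10% emergency surgery; more than half
#' clean wounds and ASA 1-2; general anaesthesia above 90%; housestaff
#' involvement above half; an additional procedure in over a third; mean
#' operative duration 1.8 h with a log-normal right tail. Marginals of the
#' continuous covariates are plausibility choices (the source description is
#' qualitative), documented in the methods vignette.
#'
#' @return list of covariate definitions, one per covariate.
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "age", kind = "continuous", dist = "truncnorm",
         mean = 55, sd = 16, floor = 18, ceiling = 94),
    list(name = "sex", kind = "categorical",
         levels = c("female", "male"), probs = c(0.56, 0.44)),
    list(name = "bmi", kind = "continuous", dist = "truncnorm",
         mean = 29, sd = 6.5, floor = 14, ceiling = 70),
    list(name = "smoker", kind = "binary", prevalence = 0.21),
    list(name = "functional_status", kind = "categorical",
         levels = c("independent", "partially_dependent", "totally_dependent"),
         probs = c(0.95, 0.04, 0.01)),
    list(name = "peripheral_vascular_disease", kind = "binary", prevalence = 0.025),
    list(name = "metastatic_cancer", kind = "binary", prevalence = 0.02),
    list(name = "chronic_steroid_use", kind = "binary", prevalence = 0.03),
    list(name = "preop_sepsis", kind = "binary", prevalence = 0.035),
    list(name = "setting", kind = "categorical",
         levels = c("ambulatory", "inpatient_elective", "emergency"),
         probs = c(0.36, 0.53, 0.11)),
    list(name = "wound_class", kind = "categorical",
         levels = c("clean", "clean_contaminated", "contaminated", "dirty"),
         probs = c(0.56, 0.29, 0.09, 0.06)),
    list(name = "asa_class", kind = "categorical",
         levels = c("1", "2", "3", "4", "5"),
         probs = c(0.14, 0.43, 0.34, 0.08, 0.01)),
    list(name = "anaesthesia", kind = "categorical",
         levels = c("general", "other"), probs = c(0.92, 0.08)),
    list(name = "multiple_procedures", kind = "binary", prevalence = 0.36),
    list(name = "housestaff", kind = "binary", prevalence = 0.55),
    # meanlog/sdlog give mean exp(0.343 + 0.7^2/2) ~= 1.8 h
    list(name = "duration_hours", kind = "continuous", dist = "lognormal",
         meanlog = 0.343, sdlog = 0.7)
  )
}

#' Default ground-truth risk model
#'
#' Log-odds effects with the directions reported for 30-day SSI (risk up
#' with smoking, BMI, vascular disease, metastatic cancer, steroid use,
#' pre-operative sepsis, inpatient/emergency setting, contaminated or dirty
#' wounds, ASA 3+, general anaesthesia, multiple procedures and longer
#' operations); magnitudes are realistic single-digit odds ratios chosen
#' once as the stated world. BMI enters per 5 units, duration on the log
#' scale (its effect saturates). The intercept is left `NULL` so it is
#' tuned to the configured overall event rate.
#'
#' @return list with `intercept` and `terms` as required by [cohort_config()].
#' @export
default_true_model <- function() {
  list(
    intercept = NULL,
    terms = list(
      smoker = 0.30,
      bmi = list(coef = 0.22, power = 1, scale = 5, center = 25),
      peripheral_vascular_disease = 0.40,
      metastatic_cancer = 0.50,
      chronic_steroid_use = 0.40,
      preop_sepsis = 0.70,
      setting = c(inpatient_elective = 0.60, emergency = 1.00),
      wound_class = c(clean_contaminated = 0.30, contaminated = 0.70, dirty = 1.00),
      asa_class = c("3" = 0.45, "4" = 0.75, "5" = 0.90),
      anaesthesia = c(other = -0.40),
      multiple_procedures = 0.30,
      duration_hours = list(coef = 0.55, power = 0, scale = 1, center = 1)
    )
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_records:", x$n_records, " seed:", x$seed, "\n")
  cat("  covariates:", length(x$covariate_spec), "\n")
  cat("  cpt groups:", x$cpt_groups$n_groups,
      " offset sd:", x$cpt_groups$offset_sd, "\n")
  cat("  event rate target:", x$event_rate_target, "\n")
  invisible(x)
}

#' Default full cohort configuration
#'
#' Convenience wrapper bundling [default_covariate_spec()] and
#' [default_true_model()] with CPT-prefix groups of heterogeneous risk
#' (offset SD 0.4 on the log-odds scale) and a 3.9% overall event-rate
#' target. At full registry scale (363,040 operations) the default is 290
#' distinct 3-digit prefixes, i.e. roughly 1250 operations per group; when
#' the cohort is scaled down the group count scales with it (bounded to
#' [10, 290]) so that per-group sample sizes — which govern how noisy the
#' observed/expected CPT3 score is — stay of the same order as in the
#' emulated registry. Pass `n_groups` to override.
#'
#' @inheritParams cohort_config
#' @param n_groups number of distinct CPT prefixes; `NULL` (default)
#'   scales with `n_records` as described above.
#' @param offset_sd SD of the per-group log-odds offsets.
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(n_records, seed = 1L, n_groups = NULL,
                                  offset_sd = 0.4) {
  if (is.null(n_groups)) {
    n_groups <- max(10L, min(290L, as.integer(round(n_records / 1250))))
  }
  cohort_config(n_records = n_records, seed = seed,
                cpt_groups = list(n_groups = n_groups, offset_sd = offset_sd))
}
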
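# Shared fixtures. The full 20,000-record pipeline run is computed once and
# cached for every test file that needs it (~15 s); its configuration is the
# package default stated world, seed fixed up front.

.fixture_env <- new.env(parent = emptyenv())

pipeline_fixture <- function() {
  if (is.null(.fixture_env$bundle)) {
    cfg <- default_cohort_config(20000L, seed = 42L)
    pc <- pipeline_config(cohort = cfg, seed = 42L)
    .fixture_env$bundle <- suppressMessages(run_pipeline(pc))
    .fixture_env$config <- cfg
  }
  .fixture_env$bundle
}

pipeline_fixture_config <- function() {
  pipeline_fixture()
  .fixture_env$config
}

# A minimal one-covariate world with no group heterogeneity and an explicit
# intercept, for closed-form checks of true_risk().
minimal_config <- function(intercept = 0, coef = 0, prevalence = 0,
                           seed = 1L) {
  cohort_config(
    n_records = 10L, seed = seed,
    covariate_spec = list(
      list(name = "smoker", kind = "binary", prevalence = prevalence)
    ),
    true_model = list(intercept = intercept, terms = list(smoker = coef)),
    cpt_groups = list(n_groups = 1L, offset_sd = 0,
                      offsets = 0, weights = 1),
    event_rate_target = NULL
  )
}

# Minimal record covering the full schema, for hand-built fixtures.
make_record <- function(n = 1, ssi30 = FALSE, cpt_code = "10012",
                        asa_class = "1", wound_class = "clean",
                        duration_hours = 1, bmi = 27, setting = "ambulatory") {
  data.frame(
    record_id = sprintf("T%06d", seq_len(n)),
    age = 50, sex = factor("female", levels = CATEGORY_DOMAINS_sex()),
    bmi = bmi, smoker = FALSE,
    functional_status = factor("independent",
      levels = c("independent", "partially_dependent", "totally_dependent")),
    peripheral_vascular_disease = FALSE, metastatic_cancer = FALSE,
    chronic_steroid_use = FALSE, preop_sepsis = FALSE,
    setting = factor(setting,
      levels = c("ambulatory", "inpatient_elective", "emergency")),
    wound_class = factor(wound_class,
      levels = c("clean", "clean_contaminated", "contaminated", "dirty")),
    asa_class = factor(asa_class, levels = as.character(1:5)),
    anaesthesia = factor("general", levels = c("general", "other")),
    multiple_procedures = FALSE, housestaff = FALSE,
    duration_hours = duration_hours, cpt_code = cpt_code, ssi30 = ssi30,
    stringsAsFactors = FALSE
  )
}

CATEGORY_DOMAINS_sex <- function() c("female", "male")

# Intercept-only risk model whose every prediction is `p`, built through the
# public fitting API from a cohort with exactly that event fraction.
constant_risk_model <- function(p = 0.1) {
  k <- round(1 / p)
  y <- c(1, rep(0, k - 1))
  fit_logistic(matrix(numeric(0), nrow = k, ncol = 0), y, terms = list())
}
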
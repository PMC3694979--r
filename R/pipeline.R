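# Covariates offered to selection by default: everything in the record
# except identifiers, the procedure code (handled via the CPT3 score) and
# the outcome.
DEFAULT_CANDIDATES <- setdiff(COHORT_COLUMNS,
                              c("record_id", "cpt_code", "ssi30"))

#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run: where the cohort comes from (a
#' CSV path or a simulation block), the split seed, both entry thresholds,
#' the a-priori interaction candidates, the categorisation preset for the
#' point table, and evaluation options.
#'
#' @param cohort_path path to a cohort CSV, or `NULL` to simulate.
#' @param cohort cohort-generation block (a [cohort_config()]) used when
#'   `cohort_path` is `NULL`.
#' @param out_dir directory for artifacts (`NULL` to skip writing).
#' @param seed integer seed for the derivation/validation split.
#' @param p_entry_stage1 stage-1 forward-selection entry threshold.
#' @param p_entry_stage2 stage-2 (strong) entry threshold.
#' @param candidates candidate covariate names.
#' @param interactions list of length-2 character vectors tested a priori.
#' @param categorization `"quintiles"`, `"published"`, or an explicit named
#'   boundary list (see [categorization_preset()]).
#' @param reference_covariate,reference_delta point-unit anchor (default: 5
#'   BMI units).
#' @param hl_groups Hosmer-Lemeshow group count.
#' @param ci_level confidence level for intervals.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL, cohort = NULL, out_dir = NULL,
                            seed = 1L, p_entry_stage1 = 0.05,
                            p_entry_stage2 = 1e-4,
                            candidates = DEFAULT_CANDIDATES,
                            interactions = list(),
                            categorization = "quintiles",
                            reference_covariate = "bmi", reference_delta = 5,
                            hl_groups = 10, ci_level = 0.95) {
  for (p in c(p_entry_stage1, p_entry_stage2)) {
    if (p <= 0 || p >= 1) stop_validation("entry thresholds must lie in (0,1)")
  }
  if (is.character(categorization) && length(categorization) == 1) {
    categorization <- categorization_preset(categorization)
  }
  structure(list(
    cohort_path = cohort_path, cohort = cohort, out_dir = out_dir,
    seed = as.integer(seed), p_entry_stage1 = p_entry_stage1,
    p_entry_stage2 = p_entry_stage2, candidates = candidates,
    interactions = interactions, categorization = categorization,
    reference_covariate = reference_covariate,
    reference_delta = reference_delta,
    hl_groups = hl_groups, ci_level = ci_level
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_recursive(config), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Run the full derivation-to-evaluation pipeline
#'
#' Executes, in order: cohort acquisition (simulation or CSV), the random
#' derivation/validation split, the stage-1 forward-selection logistic
#' model, the CPT3 observed/expected table, the stage-2 final model
#' (including a-priori interaction tests), Sullivan point-table
#' conversion, the score-to-risk map (fitted on the derivation half), and
#' evaluation — of the integer score, the continuous final model and the
#' NNIS comparator — on the validation half only. Identical config and
#' seed reproduce identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the cohort halves, `stage1`, `cpt3`,
#'   `final`, `point_table`, `map`, `evaluation` (of the integer score),
#'   `model_evaluation` (c-statistic of the continuous model),
#'   `nnis_evaluation`, `accounting` and `manifest`. When
#'   `config$out_dir` is set, every artifact is also written there.
#' @export
run_pipeline <- function(config) {
  stage <- "setup"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  records <- run_stage("cohort", {
    if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path)
    } else {
      cohort <- config$cohort %||% default_cohort_config(20000L, seed = config$seed)
      generate_cohort(cohort)
    }
  })
  accounting <- exclusion_report(nrow(records), 0L)
  log_event("cohort_ready", n = accounting$n_included,
            events = sum(records$ssi30),
            event_pct = pct(sum(records$ssi30), nrow(records)))

  halves <- run_stage("split", split_cohort(records, seed = config$seed))
  deriv <- halves$derivation; valid <- halves$validation

  stage1 <- run_stage("stage1", forward_select(
    deriv, config$candidates, p_entry = config$p_entry_stage1))

  cpt3 <- run_stage("cpt3", compute_cpt3_table(deriv, stage1))

  final <- run_stage("stage2", derive_final_model(
    deriv, cpt3, config$candidates, interactions = config$interactions,
    p_entry = config$p_entry_stage2))

  deriv$cpt3_score <- as.numeric(lookup_cpt3(deriv$cpt_code, cpt3))
  point_table <- run_stage("point_table", {
    ids <- vapply(final$terms, `[[`, "", "id")
    kinds <- vapply(final$terms, `[[`, "", "kind")
    ref_cov <- config$reference_covariate
    ref_delta <- config$reference_delta
    if (!ref_cov %in% ids[kinds == "continuous"]) {
      # anchor covariate not selected at this scale: fall back to the first
      # continuous term, one point per derivation-cohort SD
      fallback <- ids[kinds == "continuous"][1]
      if (is.na(fallback)) {
        stop_validation("final model has no continuous term to anchor the point scale")
      }
      ref_delta <- stats::sd(deriv[[fallback]])
      log_event("point_anchor_fallback", from = ref_cov, to = fallback,
                delta = format(ref_delta, digits = 4))
      ref_cov <- fallback
    }
    build_point_table(final, deriv, categorization = config$categorization,
                      reference_covariate = ref_cov,
                      reference_delta = ref_delta)
  })

  map <- run_stage("score_risk_map", {
    s_deriv <- ssirs_score(deriv, deriv$cpt3_score, point_table)
    fit_score_risk_map(s_deriv, deriv$ssi30)
  })

  evaluation <- run_stage("evaluate", {
    valid$cpt3_score <- as.numeric(lookup_cpt3(valid$cpt_code, cpt3))
    s_valid <- ssirs_score(valid, valid$cpt3_score, point_table)
    evaluate_scores(s_valid, valid$ssi30, map,
                    hl_groups = config$hl_groups, level = config$ci_level)
  })
  model_eval <- run_stage("evaluate_model", {
    valid$cpt3_score <- as.numeric(lookup_cpt3(valid$cpt_code, cpt3))
    c_statistic(predict(final, valid), valid$ssi30, config$ci_level)
  })
  nnis_eval <- run_stage("evaluate_nnis", {
    cuts <- nnis_cutpoints(deriv)
    c_statistic(nnis_index(valid, cuts), valid$ssi30, config$ci_level)
  })

  manifest <- list(
    package = "ssirs", format_version = SSIRS_FORMAT_VERSION,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, config_hash = config_hash(config),
    n_records = nrow(records), n_derivation = nrow(deriv),
    n_validation = nrow(valid)
  )

  bundle <- list(
    derivation = deriv, validation = valid, accounting = accounting,
    stage1 = stage1, cpt3 = cpt3, final = final,
    point_table = point_table, map = map, evaluation = evaluation,
    model_evaluation = model_eval, nnis_evaluation = nnis_eval,
    manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    run_stage("write_artifacts", write_bundle(bundle, config$out_dir))
  }
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_model(bundle$stage1, fp("model_stage1.json"))
  write_model(bundle$final, fp("model_final.json"))
  write_cpt3_table(bundle$cpt3, fp("cpt3_table.csv"))
  write_point_table(bundle$point_table, fp("point_table.json"),
                    map = bundle$map)
  ev <- bundle$evaluation
  jsonlite::write_json(list(
    score = list(
      c_statistic = ev$discrimination$c_statistic,
      ci = c(ev$discrimination$ci_low, ev$discrimination$ci_high),
      hl_statistic = ev$hl$statistic, hl_df = ev$hl$df, hl_p = ev$hl$p,
      levels_within = ev$calibration$levels_within,
      levels_total = ev$calibration$levels_total,
      pct_levels_within = ev$calibration$pct_levels_within,
      pct_population_within = ev$calibration$pct_population_within
    ),
    model = list(c_statistic = bundle$model_evaluation$c_statistic,
                 ci = c(bundle$model_evaluation$ci_low,
                        bundle$model_evaluation$ci_high)),
    nnis = list(c_statistic = bundle$nnis_evaluation$c_statistic,
                ci = c(bundle$nnis_evaluation$ci_low,
                       bundle$nnis_evaluation$ci_high))
  ), fp("evaluation.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(summary_lines(bundle), fp("summary.txt"))
  invisible(out_dir)
}

# Plain-text run summary mirroring clinical reporting style.
summary_lines <- function(bundle) {
  ev <- bundle$evaluation
  acc <- bundle$accounting
  c(
    sprintf("cohort: %d records analysed (%d raw, %d excluded [%s%%])",
            acc$n_included, acc$n_raw, acc$n_excluded, acc$pct_excluded),
    sprintf("events: %d of %d (%s%%)",
            bundle$final$n_events, bundle$final$n_obs,
            pct(bundle$final$n_events, bundle$final$n_obs)),
    sprintf("validation c-statistic, final model: %.3f (95%% CI %.3f-%.3f)",
            bundle$model_evaluation$c_statistic,
            bundle$model_evaluation$ci_low, bundle$model_evaluation$ci_high),
    sprintf("validation c-statistic, SSIRS: %.3f (95%% CI %.3f-%.3f)",
            ev$discrimination$c_statistic, ev$discrimination$ci_low,
            ev$discrimination$ci_high),
    sprintf("validation c-statistic, NNIS index: %.3f",
            bundle$nnis_evaluation$c_statistic),
    sprintf("Hosmer-Lemeshow: chi-square %.2f on %d df, p = %.3g",
            ev$hl$statistic, ev$hl$df, ev$hl$p),
    sprintf("calibration: expected within exact 95%% CI at %d of %d SSI levels (%s%%), %s%% of population",
            ev$calibration$levels_within, ev$calibration$levels_total,
            ev$calibration$pct_levels_within,
            ev$calibration$pct_population_within)
  )
}
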
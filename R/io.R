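# ---- cohort CSV ------------------------------------------------------------

#' Write a cohort to CSV
#'
#' Fixed, documented header (see [read_cohort()]); logical columns written
#' as TRUE/FALSE, categories as their level labels.
#'
#' @param records cohort data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cohort <- function(records, path) {
  out <- records[, COHORT_COLUMNS, drop = FALSE]
  for (nm in names(out)) if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Expects exactly the documented header (`record_id, age, sex, bmi,
#' smoker, functional_status, peripheral_vascular_disease,
#' metastatic_cancer, chronic_steroid_use, preop_sepsis, setting,
#' wound_class, asa_class, anaesthesia, multiple_procedures, housestaff,
#' duration_hours, cpt_code, ssi30`). Unknown columns are an error. Rows
#' with any missing covariate are dropped complete-case with a logged
#' count. Category labels outside their declared domains raise an error
#' naming the row.
#'
#' @param path CSV file path.
#' @return typed cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_validation("cohort file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  unknown <- setdiff(names(raw), COHORT_COLUMNS)
  if (length(unknown)) {
    stop_validation("unknown column(s) in cohort file: %s",
                    paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop_validation("cohort file missing column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }

  numeric_cols <- c("age", "bmi", "duration_hours")
  df <- raw
  for (nm in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(!is.na(raw[[nm]]) & raw[[nm]] != "" & is.na(v))
    if (length(bad)) {
      stop_validation("%s: non-numeric value '%s' at row %d", nm, raw[[nm]][bad[1]], bad[1])
    }
    df[[nm]] <- v
  }
  for (nm in LOGICAL_COLUMNS) {
    v <- toupper(raw[[nm]])
    bad <- which(!v %in% c("TRUE", "FALSE", ""))
    if (length(bad)) {
      stop_validation("%s: invalid logical '%s' at row %d", nm, raw[[nm]][bad[1]], bad[1])
    }
    df[[nm]] <- v == "TRUE"
    df[[nm]][v == ""] <- NA
  }
  for (nm in names(CATEGORY_DOMAINS)) {
    v <- raw[[nm]]
    bad <- which(!v %in% c(CATEGORY_DOMAINS[[nm]], ""))
    if (length(bad)) {
      stop_validation("%s: invalid level '%s' at row %d", nm, v[bad[1]], bad[1])
    }
    df[[nm]] <- factor(ifelse(v == "", NA, v), levels = CATEGORY_DOMAINS[[nm]])
  }
  for (nm in c("record_id", "cpt_code")) {
    df[[nm]][df[[nm]] == ""] <- NA
  }

  complete <- stats::complete.cases(df)
  n_drop <- sum(!complete)
  if (n_drop) log_event("incomplete_rows_dropped", n = n_drop)
  df <- df[complete, , drop = FALSE]
  rownames(df) <- NULL
  validate_cohort(df)
  df
}

# ---- JSON serialization ----------------------------------------------------

SSIRS_FORMAT_VERSION <- 1L

transform_to_list <- function(t) {
  if (is.null(t)) return(NULL)
  list(variable = t$variable, powers = as.numeric(t$powers),
       shift = t$shift, scale = t$scale)
}

transform_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  fp_transform(l$variable, as.numeric(unlist(l$powers)),
               shift = l$shift, scale = l$scale)
}

term_to_list <- function(term) {
  list(id = term$id, var = term$var, kind = term$kind,
       levels = term$levels, transform = transform_to_list(term$transform),
       parents = if (is.null(term$parents)) NULL else
         lapply(term$parents, term_to_list))
}

term_from_list <- function(l) {
  make_term(
    var = l$var, kind = l$kind,
    levels = if (is.null(l$levels)) NULL else as.character(unlist(l$levels)),
    transform = transform_from_list(l$transform),
    parents = if (is.null(l$parents)) NULL else lapply(l$parents, term_from_list)
  )
}

#' Serialize / restore a fitted model as JSON
#'
#' The JSON artifact is self-contained: it stores the version-stamped
#' coefficient table together with every term's transform (including
#' fractional-polynomial shift, scale and powers) so that a restored model
#' predicts identically.
#'
#' @param model an `ssirs_model`.
#' @param path output JSON file.
#' @return `write_model`: the path, invisibly. `read_model`: the model.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = "ssirs_model", version = SSIRS_FORMAT_VERSION,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    se = as.list(model$se),
    wald_p = as.list(model$wald_p),
    intercept_se = model$intercept_se,
    deviance = model$deviance,
    null_deviance = model$null_deviance,
    converged = model$converged,
    n_obs = model$n_obs, n_events = model$n_events,
    entry_p = model$entry_p,
    terms = if (is.null(model$terms)) NULL else lapply(model$terms, term_to_list)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @param path JSON file written by [write_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "ssirs_model")) {
    stop_validation("%s is not an ssirs_model JSON artifact", path)
  }
  model <- list(
    intercept = obj$intercept,
    coefficients = unlist(obj$coefficients),
    se = unlist(obj$se),
    wald_p = unlist(obj$wald_p),
    intercept_se = obj$intercept_se,
    deviance = obj$deviance,
    null_deviance = obj$null_deviance,
    converged = isTRUE(obj$converged),
    n_obs = obj$n_obs, n_events = obj$n_events,
    entry_p = obj$entry_p,
    terms = if (is.null(obj$terms)) NULL else lapply(obj$terms, term_from_list)
  )
  class(model) <- "ssirs_model"
  model
}

#' Serialize / restore a CPT3 table
#'
#' CSV keyed by 3-digit prefix, one row per procedure group.
#'
#' @param table a `cpt3_table`.
#' @param path CSV path.
#' @export
write_cpt3_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cpt3_table
#' @export
read_cpt3_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(prefix = "character"))
  need <- c("prefix", "n_operations", "observed_ssi", "expected_ssi",
            "score", "provenance")
  if (!identical(names(df), need)) {
    stop_validation("%s is not a cpt3_table CSV", path)
  }
  class(df) <- c("cpt3_table", "data.frame")
  df
}

#' Serialize / restore a point-score table (with its risk map)
#'
#' JSON artifact carrying the full score card — category boundaries,
#' representatives, integer points, transforms — plus, optionally, the
#' fitted score-to-risk logistic map, so a saved table supports bedside
#' scoring and risk mapping with nothing else.
#'
#' @param table a `point_table`; may carry `attr(, "map")`.
#' @param map optional `score_risk_map` stored alongside.
#' @param path JSON path.
#' @export
write_point_table <- function(table, path, map = NULL) {
  entries <- lapply(table$entries, function(e) {
    cats <- e$categories
    if (e$kind == "continuous") {
      # string-encoded (JSON has no Inf) at full double precision
      cats$lower <- sprintf("%.17g", cats$lower)
      cats$upper <- sprintf("%.17g", cats$upper)
    }
    list(var = e$var, kind = e$kind, reference = e$reference,
         transform = transform_to_list(e$transform), categories = cats)
  })
  obj <- list(
    format = "ssirs_point_table", version = SSIRS_FORMAT_VERSION,
    base_constant = table$base_constant,
    reference_unit = table$reference_unit,
    reference_covariate = table$reference_covariate,
    reference_delta = table$reference_delta,
    score_range = as.numeric(table$score_range),
    entries = entries,
    map = if (is.null(map)) NULL else
      list(intercept = map$intercept, beta = map$beta, converged = map$converged)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_point_table
#' @export
read_point_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$format, "ssirs_point_table")) {
    stop_validation("%s is not an ssirs_point_table JSON artifact", path)
  }
  entries <- list()
  for (raw in obj$entries) {
    e <- list(var = raw$var, kind = raw$kind, reference = raw$reference,
              categories = raw$categories)
    if (e$kind == "continuous") {
      tl <- raw$transform
      e$transform <- fp_transform(tl$variable, as.numeric(unlist(tl$powers)),
                                  shift = tl$shift, scale = tl$scale)
      e$categories$lower <- as.numeric(e$categories$lower)
      e$categories$upper <- as.numeric(e$categories$upper)
      e$reference <- as.integer(e$reference)
    }
    entries[[e$var]] <- e
  }
  tab <- structure(list(
    base_constant = obj$base_constant,
    reference_unit = obj$reference_unit,
    reference_covariate = obj$reference_covariate,
    reference_delta = obj$reference_delta,
    entries = entries,
    score_range = c(min = obj$score_range[1], max = obj$score_range[2])
  ), class = "point_table")
  if (!is.null(obj$map)) {
    attr(tab, "map") <- structure(
      list(intercept = obj$map$intercept, beta = obj$map$beta,
           converged = isTRUE(obj$map$converged), diagnostic = NULL),
      class = "score_risk_map")
  }
  tab
}

# ---- cohort configuration file ---------------------------------------------

# Named atomic vectors must serialize as JSON objects, not bare arrays.
named_to_list <- function(x) {
  if (is.list(x)) {
    lapply(x, named_to_list)
  } else if (!is.null(names(x))) {
    as.list(x)
  } else {
    x
  }
}

#' Serialize / restore a cohort configuration
#'
#' Human-editable JSON with one block per covariate, the true model, the
#' CPT group structure (including the materialised offsets and weights, so
#' a saved configuration regenerates bit-identical cohorts) and the event
#' rate target.
#'
#' @param config a [cohort_config()].
#' @param path JSON file path.
#' @export
write_cohort_config <- function(config, path) {
  obj <- list(
    format = "ssirs_cohort_config", version = SSIRS_FORMAT_VERSION,
    n_records = config$n_records, seed = config$seed,
    covariate_spec = config$covariate_spec,
    true_model = named_to_list(config$true_model),
    cpt_groups = named_to_list(config$cpt_groups[
      c("n_groups", "offset_sd", "offsets", "weights")]),
    event_rate_target = config$event_rate_target
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "ssirs_cohort_config")) {
    stop_validation("%s is not an ssirs_cohort_config JSON artifact", path)
  }
  spec <- lapply(obj$covariate_spec, function(cv) {
    for (nm in c("levels")) if (!is.null(cv[[nm]])) cv[[nm]] <- as.character(unlist(cv[[nm]]))
    for (nm in c("probs")) if (!is.null(cv[[nm]])) cv[[nm]] <- as.numeric(unlist(cv[[nm]]))
    cv
  })
  terms <- lapply(obj$true_model$terms, function(tm) {
    if (is.list(tm) && !is.null(tm$coef)) {
      lapply(tm, function(v) as.numeric(v))
    } else if (is.list(tm)) {
      unlist(tm) # named per-level log-odds
    } else {
      tm
    }
  })
  g <- obj$cpt_groups
  cohort_config(
    n_records = obj$n_records, seed = obj$seed,
    covariate_spec = spec,
    true_model = list(intercept = obj$true_model$intercept, terms = terms),
    cpt_groups = list(n_groups = g$n_groups, offset_sd = g$offset_sd,
                      offsets = if (is.null(g$offsets)) NULL else unlist(g$offsets),
                      weights = if (is.null(g$weights)) NULL else unlist(g$weights)),
    event_rate_target = obj$event_rate_target
  )
}
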
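# Round half away from zero (documented convention for point values;
# base-R round() would round halves to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Boundary presets for categorising continuous covariates
#'
#' `"published"` returns the boundary facts printed for the bedside score
#' (influential regions: BMI above 35; operation duration at or below half
#' an hour or above 3.5 h; CPT3 score below 0.9 or above 1.262).
#' `"quintiles"` signals that boundaries should be computed from the
#' derivation cohort's quintiles at table-build time (the default).
#'
#' @param name `"quintiles"` or `"published"`.
#' @return named list of numeric boundary vectors (or the string
#'   `"quintiles"`).
#' @export
categorization_preset <- function(name = c("quintiles", "published")) {
  name <- match.arg(name)
  if (name == "quintiles") return("quintiles")
  list(
    bmi = c(25, 30, 35),
    duration_hours = c(0.5, 1, 2, 3.5),
    cpt3_score = c(0.5, 0.9, 1.262)
  )
}

# Linear-predictor contribution of a continuous model term at value x.
continuous_contribution <- function(x, transform, coefs) {
  drop(fp_apply(x, transform) %*% coefs)
}

#' Convert a fitted risk model into an integer point-score table
#'
#' Sullivan point-system conversion: one point is defined as the change in
#' log-odds induced by `reference_delta` units of `reference_covariate`
#' (default: 5 BMI units), evaluated at the derivation-cohort median and
#' passed through the covariate's stored transform. Every covariate is
#' categorised; each category's points are
#' `round(beta * (W_ij - W_iREF) / B)` on the modeled (transformed) scale,
#' rounding half away from zero, with the category representative `W_ij`
#' the interval midpoint for bounded intervals and the category's observed
#' derivation-cohort median for open-ended ones. Each covariate's
#' reference (zero-point) category is the one containing its derivation
#' median (continuous) or its first declared level (categorical/binary).
#' Interaction terms, if present in the model, are excluded from the table
#' with a logged warning: the integer score is a main-effects
#' approximation, recalibrated by the score-to-risk map.
#'
#' @param model a fitted `ssirs_model`.
#' @param data derivation cohort data.frame (supplies medians/quintiles);
#'   must contain a `cpt3_score` column when the model uses one.
#' @param categorization named list of interior boundary vectors per
#'   continuous covariate, or `"quintiles"` (default) to use
#'   derivation-cohort quintiles; see [categorization_preset()].
#' @param reference_covariate continuous model covariate anchoring the
#'   point unit (default `"bmi"`).
#' @param reference_delta covariate change worth one point (default 5).
#' @param base_constant points-scale offset added to every score (default
#'   0).
#' @return an object of class `point_table`.
#' @export
build_point_table <- function(model, data, categorization = "quintiles",
                              reference_covariate = "bmi",
                              reference_delta = 5, base_constant = 0) {
  term_ids <- vapply(model$terms, `[[`, "", "id")
  ref_idx <- match(reference_covariate, term_ids)
  if (is.na(ref_idx) || model$terms[[ref_idx]]$kind != "continuous") {
    stop_validation("reference covariate '%s' is not a continuous model term",
                    reference_covariate)
  }
  if (reference_delta <= 0) stop_validation("reference_delta must be > 0")

  coefs_of <- function(term) {
    model$coefficients[colnames(term_columns(data[1, , drop = FALSE], term))]
  }

  ref_term <- model$terms[[ref_idx]]
  ref_coefs <- coefs_of(ref_term)
  x_med <- stats::median(data[[reference_covariate]])
  B <- abs(continuous_contribution(x_med + reference_delta, ref_term$transform, ref_coefs) -
           continuous_contribution(x_med, ref_term$transform, ref_coefs))
  if (B == 0) stop_validation("reference coefficient is zero: point unit undefined")

  if (identical(categorization, "quintiles")) categorization <- list()
  extra <- setdiff(names(categorization), term_ids)
  if (length(extra)) {
    stop_validation("categorization names covariates not in the model: %s",
                    paste(extra, collapse = ", "))
  }

  entries <- list()
  for (term in model$terms) {
    if (term$kind == "interaction") {
      log_event("point_table_interaction_dropped", term = term$id)
      next
    }
    coefs <- coefs_of(term)
    if (term$kind == "binary") {
      pts <- round_half_away(coefs[[1]] / B)
      cats <- data.frame(level = c("FALSE", "TRUE"), points = c(0, pts),
                         stringsAsFactors = FALSE)
      entries[[term$id]] <- list(var = term$var, kind = "binary",
                                 reference = "FALSE", categories = cats)
    } else if (term$kind == "categorical") {
      pts <- c(0, round_half_away(coefs / B))
      cats <- data.frame(level = term$levels, points = unname(pts),
                         stringsAsFactors = FALSE)
      entries[[term$id]] <- list(var = term$var, kind = "categorical",
                                 reference = term$levels[1], categories = cats)
    } else {
      x <- data[[term$var]]
      bounds <- categorization[[term$var]]
      if (is.null(bounds)) {
        bounds <- unique(stats::quantile(x, probs = seq(0.2, 0.8, by = 0.2),
                                         names = FALSE))
      }
      bounds <- sort(unique(bounds))
      lower <- c(-Inf, bounds)
      upper <- c(bounds, Inf)
      rep_val <- numeric(length(lower))
      for (k in seq_along(lower)) {
        if (is.infinite(lower[k]) || is.infinite(upper[k])) {
          inside <- x > lower[k] & x <= upper[k]
          rep_val[k] <- if (any(inside)) stats::median(x[inside]) else
            (if (is.infinite(lower[k])) upper[k] else lower[k])
        } else {
          rep_val[k] <- (lower[k] + upper[k]) / 2
        }
      }
      med <- stats::median(x)
      ref_k <- which(med > lower & med <= upper)[1]
      eta <- vapply(rep_val, continuous_contribution, numeric(1),
                    transform = term$transform, coefs = coefs)
      pts <- round_half_away((eta - eta[ref_k]) / B)
      cats <- data.frame(lower = lower, upper = upper,
                         representative = rep_val, points = pts)
      entries[[term$id]] <- list(var = term$var, kind = "continuous",
                                 reference = ref_k, transform = term$transform,
                                 categories = cats)
    }
  }

  mins <- vapply(entries, function(e) min(e$categories$points), numeric(1))
  maxs <- vapply(entries, function(e) max(e$categories$points), numeric(1))
  structure(list(
    base_constant = base_constant,
    reference_unit = B,
    reference_covariate = reference_covariate,
    reference_delta = reference_delta,
    entries = entries,
    score_range = c(min = base_constant + sum(mins),
                    max = base_constant + sum(maxs))
  ), class = "point_table")
}

#' @export
print.point_table <- function(x, ...) {
  cat("<point_table> SSI Risk Score card\n")
  cat(sprintf("  1 point = %.4f log-odds (%g units of %s); potential range %d to %d\n",
              x$reference_unit, x$reference_delta, x$reference_covariate,
              as.integer(x$score_range[1]), as.integer(x$score_range[2])))
  for (e in x$entries) {
    cat("  --", e$var, "--\n")
    if (e$kind == "continuous") {
      for (k in seq_len(nrow(e$categories))) {
        cat(sprintf("    (%g, %g]: %+d\n", e$categories$lower[k],
                    e$categories$upper[k], as.integer(e$categories$points[k])))
      }
    } else {
      for (k in seq_len(nrow(e$categories))) {
        cat(sprintf("    %s: %+d\n", e$categories$level[k],
                    as.integer(e$categories$points[k])))
      }
    }
  }
  invisible(x)
}

# Points for one covariate entry given a vector of raw values.
entry_points <- function(entry, values) {
  if (entry$kind %in% c("binary", "categorical")) {
    lv <- as.character(values)
    if (entry$kind == "binary") lv <- as.character(as.logical(values))
    i <- match(lv, entry$categories$level)
    if (anyNA(i)) {
      stop_validation("%s: value '%s' matches no score category",
                      entry$var, lv[which(is.na(i))[1]])
    }
    entry$categories$points[i]
  } else {
    v <- as.numeric(values)
    pts <- rep(NA_real_, length(v))
    for (k in seq_len(nrow(entry$categories))) {
      inside <- v > entry$categories$lower[k] & v <= entry$categories$upper[k]
      pts[inside] <- entry$categories$points[k]
    }
    if (anyNA(pts)) {
      stop_validation("%s: value %g falls in a gap between score categories",
                      entry$var, v[which(is.na(pts))[1]])
    }
    pts
  }
}

#' Compute integer SSI Risk Scores for records
#'
#' Sums the point-table category points over all covariates (the CPT3
#' score being supplied separately, since it comes from the score table
#' rather than the record) plus the base constant.
#'
#' @param records cohort data.frame.
#' @param cpt3 numeric vector of CPT3 scores, one per record (ignored when
#'   the table has no `cpt3_score` entry).
#' @param table a `point_table`.
#' @return integer vector of scores, each within the table's potential
#'   range.
#' @export
ssirs_score <- function(records, cpt3, table) {
  total <- rep(table$base_constant, nrow(records))
  for (e in table$entries) {
    values <- if (identical(e$var, "cpt3_score")) cpt3 else records[[e$var]]
    if (is.null(values)) stop_validation("records lack covariate '%s'", e$var)
    total <- total + entry_points(e, values)
  }
  as.integer(total)
}

#' Fit the score-to-risk logistic map
#'
#' Single-covariate logistic regression of the binary 30-day SSI outcome
#' on the integer risk score; its intercept and slope define the expected
#' risk at each score level.
#'
#' @param scores integer score vector (not constant).
#' @param y binary outcome vector.
#' @return object of class `score_risk_map` with `intercept`, `beta`,
#'   `converged`.
#' @export
fit_score_risk_map <- function(scores, y) {
  if (length(unique(scores)) < 2) {
    stop_validation("scores are constant: slope is unidentifiable")
  }
  X <- matrix(as.numeric(scores), ncol = 1, dimnames = list(NULL, "ssirs"))
  fit <- fit_logistic(X, y)
  structure(list(intercept = fit$intercept,
                 beta = unname(fit$coefficients[1]),
                 converged = fit$converged,
                 diagnostic = fit$diagnostic),
            class = "score_risk_map")
}

#' @export
print.score_risk_map <- function(x, ...) {
  cat(sprintf("<score_risk_map> risk = 1/(1 + exp(-(%.4f + %.4f * score)))%s\n",
              x$intercept, x$beta,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Expected SSI risk at a score value
#'
#' Exactly `1 / (1 + exp(-(intercept + beta * score)))`.
#'
#' @param score numeric/integer score value(s).
#' @param map a `score_risk_map`.
#' @return probability vector.
#' @export
risk_from_score <- function(score, map) {
  inv_logit(map$intercept + map$beta * score)
}

#' Number needed to treat
#'
#' NNT of an intervention with a given relative risk at a given baseline
#' risk: the reciprocal of the absolute risk reduction,
#' `1 / (baseline_risk * (1 - relative_risk))`. A relative risk of 1 (no
#' effect) gives an infinite NNT; a relative risk above 1 (harm) is
#' signalled as an error rather than returned as a misleading negative
#' number.
#'
#' @param baseline_risk probability in (0, 1].
#' @param relative_risk nonnegative multiplier on risk under treatment.
#' @return positive real, or `Inf` when `relative_risk` is 1.
#' @examples
#' nnt(0.10, 0.5) # 20
#' nnt(0.01, 0.5) # 200
#' @export
nnt <- function(baseline_risk, relative_risk) {
  if (baseline_risk <= 0 || baseline_risk > 1) {
    stop_validation("baseline_risk must lie in (0, 1]")
  }
  if (relative_risk < 0) stop_validation("relative_risk must be >= 0")
  if (relative_risk > 1) {
    stop(structure(
      class = c("ssirs_harm_error", "error", "condition"),
      list(message = sprintf(
        "relative risk %g > 1: intervention is harmful (negative benefit); NNT undefined",
        relative_risk), call = sys.call())
    ))
  }
  if (relative_risk == 1) return(Inf)
  1 / (baseline_risk * (1 - relative_risk))
}
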
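#' Split a cohort into derivation and validation halves
#'
#' Random, seeded, reproducible partition into two equally sized groups;
#' with an odd number of records the derivation half receives the extra
#' record.
#'
#' @param records nonempty cohort data.frame.
#' @param seed integer seed.
#' @return list with `derivation` and `validation` data.frames.
#' @export
split_cohort <- function(records, seed = 1L) {
  n <- nrow(records)
  if (is.null(n) || n == 0) stop_validation("split_cohort: empty cohort")
  idx <- with_seed(seed, sample.int(n, ceiling(n / 2)))
  list(
    derivation = records[sort(idx), , drop = FALSE],
    validation = records[setdiff(seq_len(n), idx), , drop = FALSE]
  )
}

# Likelihood-ratio p-value for adding `extra_term` to the model with design
# `X_cur` (deviance dev_cur). Returns NA (with a logged warning) when the
# augmented fit separates or is rank-deficient, so selection can skip it.
lr_test_add <- function(data, y, X_cur, dev_cur, extra_term) {
  cols <- term_columns(data, extra_term)
  fit <- tryCatch(
    fit_logistic(cbind(X_cur, cols), y),
    ssirs_validation_error = function(e) e
  )
  if (inherits(fit, "condition")) {
    log_event("candidate_skipped", term = extra_term$id, reason = conditionMessage(fit))
    return(list(p = NA_real_, fit = NULL, df = ncol(cols)))
  }
  if (!fit$converged) {
    log_event("candidate_skipped", term = extra_term$id,
              reason = fit$diagnostic %||% "non-convergence")
    return(list(p = NA_real_, fit = NULL, df = ncol(cols)))
  }
  df <- ncol(cols)
  stat <- max(dev_cur - fit$deviance, 0)
  list(p = stats::pchisq(stat, df, lower.tail = FALSE), fit = fit, df = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forward variable selection for a logistic risk model
#'
#' Iteratively adds, among the remaining candidates, the one with the
#' smallest likelihood-ratio entry p-value, as long as it falls below
#' `p_entry`; stops when no candidate qualifies. Categorical covariates
#' enter as whole indicator blocks (multi-df test). Continuous candidates
#' are given a fractional-polynomial form by [fp_select()] once, adjusted
#' for the locked terms, before the selection loop (an `"omit"` verdict
#' falls back to the linear form — the entry test then decides). Candidates
#' whose addition produces separation or collinearity are skipped with a
#' logged warning. Ties in p-value resolve to the alphabetically first
#' candidate for exact reproducibility.
#'
#' @param records cohort data.frame containing the outcome column.
#' @param candidates character vector of candidate covariate names.
#' @param p_entry likelihood-ratio entry threshold (default 0.05).
#' @param locked covariate names kept in the model throughout (never
#'   tested).
#' @param outcome name of the binary outcome column (default `"ssi30"`).
#' @param fp_alpha significance level handed to [fp_select()].
#' @param fp_degree maximum FP degree for continuous candidates.
#' @return an `ssirs_model` with term specs and per-term entry p-values.
#' @export
forward_select <- function(records, candidates, p_entry = 0.05,
                           locked = character(), outcome = "ssi30",
                           fp_alpha = 0.05, fp_degree = 2) {
  if (!length(candidates)) stop_validation("forward_select: no candidates")
  y <- as.numeric(records[[outcome]])
  candidates <- sort(setdiff(candidates, locked))

  locked_terms <- lapply(locked, function(v) infer_term(records, v))
  X_locked <- build_design(records, locked_terms)

  # resolve FP form once per continuous candidate, against the locked design
  cand_terms <- list()
  for (v in candidates) {
    x <- records[[v]]
    if (is.numeric(x) && !is.logical(x)) {
      adj <- if (ncol(X_locked)) X_locked else NULL
      sel <- fp_select(x, y, adjustment = adj, alpha = fp_alpha,
                       degree = fp_degree)
      tfm <- if (inherits(sel, "fp_transform")) {
        sel$variable <- v
        sel
      } else { # "linear" or "omit": linear form, entry test decides
        ss <- fp_shift_scale(x)
        fp_transform(v, 1, shift = ss$shift, scale = ss$scale)
      }
      cand_terms[[v]] <- make_term(v, "continuous", transform = tfm)
    } else {
      cand_terms[[v]] <- infer_term(records, v)
    }
  }

  selected <- locked_terms
  X <- X_locked
  cur_fit <- fit_logistic(X, y)
  entry_p <- list()
  remaining <- candidates

  repeat {
    if (!length(remaining)) break
    tests <- lapply(remaining, function(v) {
      lr_test_add(records, y, X, cur_fit$deviance, cand_terms[[v]])
    })
    pvals <- vapply(tests, `[[`, numeric(1), "p")
    if (all(is.na(pvals))) break
    best <- which.min(pvals) # first minimum = alphabetical tie-break
    if (is.na(pvals[best]) || pvals[best] >= p_entry) break
    v <- remaining[best]
    entry_p[[v]] <- pvals[best]
    selected <- c(selected, list(cand_terms[[v]]))
    X <- cbind(X, term_columns(records, cand_terms[[v]]))
    cur_fit <- tests[[best]]$fit
    remaining <- setdiff(remaining, v)
    log_event("term_entered", term = v, p = format(pvals[best], digits = 3))
  }

  model <- fit_logistic(build_design(records, selected), y, terms = selected)
  model$entry_p <- entry_p
  model$locked <- locked
  model
}

# ---- CPT3 score ------------------------------------------------------------

#' Observed/expected SSI score per 3-digit CPT group
#'
#' Groups derivation operations by the first three digits of their CPT
#' code and quantifies each group's SSI risk, net of the patient-level
#' covariates, as the ratio of observed to expected SSIs — an indirect
#' standardization. Expected counts are the sums of stage-1 predicted
#' probabilities over the group's records; by construction the expected
#' counts sum to the cohort's total predicted probability (conservation).
#' Zero-event groups are defaulted: score 0 when the expected count exceeds
#' 0.5 (enough exposure to have seen an event), score 1 (risk-neutral)
#' otherwise.
#'
#' @param records derivation cohort (the same one `stage1` was fitted on).
#' @param stage1 the stage-1 `ssirs_model`.
#' @return a `cpt3_table`: data.frame with prefix, `n_operations`,
#'   `observed_ssi`, `expected_ssi`, `score` and a `provenance` flag
#'   (`ratio`, `default_zero`, `default_one`).
#' @export
compute_cpt3_table <- function(records, stage1) {
  prefix <- substr(records$cpt_code, 1, 3)
  bad <- which(!grepl("^[0-9]{3}$", prefix))
  if (length(bad)) {
    stop_validation("unparsable CPT prefix '%s' (record %s)",
                    prefix[bad[1]], records$record_id[bad[1]])
  }
  pred <- predict(stage1, records)
  obs <- tapply(as.numeric(records$ssi30), prefix, sum)
  expd <- tapply(pred, prefix, sum)
  n_op <- tapply(rep(1L, nrow(records)), prefix, sum)

  score <- numeric(length(obs))
  provenance <- character(length(obs))
  for (i in seq_along(obs)) {
    if (obs[i] > 0) {
      score[i] <- obs[i] / expd[i]
      provenance[i] <- "ratio"
    } else if (expd[i] > 0.5) {
      score[i] <- 0
      provenance[i] <- "default_zero"
    } else {
      score[i] <- 1
      provenance[i] <- "default_one"
    }
  }
  out <- data.frame(
    prefix = names(obs), n_operations = as.integer(n_op),
    observed_ssi = as.integer(obs), expected_ssi = as.numeric(expd),
    score = score, provenance = provenance,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("cpt3_table", "data.frame")
  out
}

#' Look up CPT3 scores for procedure codes
#'
#' @param cpt_code character vector of 5-character CPT codes whose first
#'   three characters are digits.
#' @param table a `cpt3_table`.
#' @return numeric score vector; prefixes absent from the table receive the
#'   risk-neutral unseen default of 1 (attribute `provenance` reports
#'   `unseen_default` for them).
#' @export
lookup_cpt3 <- function(cpt_code, table) {
  ok <- nchar(cpt_code) == 5 & grepl("^[0-9]{3}", cpt_code)
  if (any(!ok)) {
    stop_validation("malformed CPT code '%s'", cpt_code[which(!ok)[1]])
  }
  prefix <- substr(cpt_code, 1, 3)
  i <- match(prefix, table$prefix)
  score <- ifelse(is.na(i), 1, table$score[i])
  prov <- ifelse(is.na(i), "unseen_default", table$provenance[i])
  attr(score, "provenance") <- prov
  score
}

#' Derive the final (stage-2) risk model
#'
#' Adds the CPT3 score to the candidate covariates and reruns forward
#' selection at the strong stage-2 threshold (default p < 0.0001); the CPT3
#' score enters as a continuous covariate, itself eligible for
#' fractional-polynomial transformation. Each a-priori interaction is then
#' tested by likelihood ratio against the selected model and retained when
#' p < `p_entry`; hierarchy is enforced — an interaction is only tested, and
#' only retained, when both main effects are in the model.
#'
#' @param records derivation cohort.
#' @param table `cpt3_table` computed on the same derivation cohort.
#' @param candidates character vector of candidate covariates.
#' @param interactions list of length-2 character vectors (covariate
#'   pairs).
#' @param p_entry stage-2 entry threshold (default 0.0001).
#' @param outcome outcome column name.
#' @return an `ssirs_model`; the `cpt3_table` used is attached as
#'   `model$cpt3_table`.
#' @export
derive_final_model <- function(records, table, candidates,
                               interactions = list(), p_entry = 1e-4,
                               outcome = "ssi30") {
  records$cpt3_score <- as.numeric(lookup_cpt3(records$cpt_code, table))
  model <- forward_select(records, c(candidates, "cpt3_score"),
                          p_entry = p_entry, outcome = outcome)
  y <- as.numeric(records[[outcome]])

  in_model <- vapply(model$terms, `[[`, "", "id")
  for (pair in interactions) {
    if (!all(pair %in% in_model)) {
      log_event("interaction_skipped", pair = paste(pair, collapse = "x"),
                reason = "main effect absent (hierarchy)")
      next
    }
    t1 <- model$terms[[match(pair[1], in_model)]]
    t2 <- model$terms[[match(pair[2], in_model)]]
    inter <- make_term(NULL, "interaction", parents = list(t1, t2))
    X <- build_design(records, model$terms)
    test <- lr_test_add(records, y, X, model$deviance, inter)
    if (!is.na(test$p) && test$p < p_entry) {
      new_terms <- c(model$terms, list(inter))
      entry_p <- model$entry_p
      entry_p[[inter$id]] <- test$p
      model <- fit_logistic(build_design(records, new_terms), y,
                            terms = new_terms)
      model$entry_p <- entry_p
      in_model <- c(in_model, inter$id)
      log_event("interaction_retained", pair = inter$id,
                p = format(test$p, digits = 3))
    }
  }
  model$cpt3_table <- table
  model
}
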
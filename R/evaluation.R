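#' Concordance statistic with confidence interval
#'
#' The c-statistic (area under the ROC curve): the proportion of
#' (event, non-event) pairs in which the event case received the higher
#' prediction, ties counting one half. Computed by the midrank formulation
#' (identical to exhaustive pair counting); the 95% CI uses the DeLong
#' placement-component asymptotic variance, recorded in the method tag.
#'
#' @param predictions numeric risk predictions (any monotone score works).
#' @param y binary outcome vector containing both classes.
#' @param level confidence level (default 0.95).
#' @return list of class `discrimination_report`: `c_statistic`, `ci_low`,
#'   `ci_high`, `n_pairs`, `method`.
#' @export
c_statistic <- function(predictions, y, level = 0.95) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_validation("y must be binary")
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop_validation("y must contain both classes")

  r <- rank(predictions, ties.method = "average")
  cstat <- (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)

  # DeLong placement values, O(n log n): for each event, the fraction of
  # non-events strictly below plus half the fraction tied.
  neg <- sort(predictions[y == 0])
  pos <- sort(predictions[y == 1])
  v10 <- (findInterval(predictions[y == 1], neg, left.open = TRUE) +
            findInterval(predictions[y == 1], neg)) / (2 * n)
  v01 <- 1 - (findInterval(predictions[y == 0], pos, left.open = TRUE) +
                findInterval(predictions[y == 0], pos)) / (2 * m)
  var_c <- stats::var(v10) / m + stats::var(v01) / n
  zq <- stats::qnorm(1 - (1 - level) / 2)
  half <- zq * sqrt(max(var_c, 0))

  structure(list(
    c_statistic = cstat,
    ci_low = max(0, cstat - half),
    ci_high = min(1, cstat + half),
    n_pairs = m * n,
    method = "midrank AUC; DeLong asymptotic CI"
  ), class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("c-statistic %.3f (95%% CI %.3f-%.3f), %d comparable pairs [%s]\n",
              x$c_statistic, x$ci_low, x$ci_high, x$n_pairs, x$method))
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk calibration test: records are grouped by predicted
#' probability (tied predictions stay together), and the statistic sums
#' `(O - E)^2 / E` over groups for both outcomes, referred to a chi-square
#' with `groups - 2` degrees of freedom. A group whose expected event count
#' is zero is merged with its neighbour and the merge logged.
#'
#' @param predictions probability vector.
#' @param y binary outcome vector.
#' @param groups number of risk groups (default 10).
#' @return list with `statistic`, `df`, `p`, `table` (per-group observed
#'   and expected counts).
#' @export
hosmer_lemeshow <- function(predictions, y, groups = 10) {
  y <- as.numeric(y)
  if (groups < 2) stop_validation("groups must be >= 2")
  if (length(y) < groups) stop_validation("need at least `groups` observations")

  breaks <- unique(stats::quantile(predictions, probs = seq_len(groups - 1) / groups,
                                   names = FALSE))
  g <- findInterval(predictions, breaks, left.open = TRUE) + 1L
  agg <- function(v) tapply(v, g, sum)
  tab <- data.frame(
    n = as.numeric(agg(rep(1, length(y)))),
    obs = as.numeric(agg(y)),
    exp = as.numeric(agg(predictions))
  )

  i <- 1L
  while (i <= nrow(tab)) {
    if (tab$exp[i] == 0 && nrow(tab) > 1) {
      j <- if (i < nrow(tab)) i + 1L else i - 1L
      log_event("hl_group_merged", group = i, into = j)
      tab[j, ] <- tab[j, ] + tab[i, ]
      tab <- tab[-i, , drop = FALSE]
    } else {
      i <- i + 1L
    }
  }

  o1 <- tab$obs; e1 <- tab$exp
  o0 <- tab$n - o1; e0 <- tab$n - e1
  stat <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- nrow(tab) - 2L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Interval for an event proportion from beta-distribution quantiles; the
#' lower bound is 0 at zero events and the upper bound 1 when every trial
#' is an event.
#'
#' @param events event count, `0 <= events <= n`.
#' @param n trial count, `>= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
exact_binomial_ci <- function(events, n, level = 0.95) {
  if (n < 1 || events < 0 || events > n) stop_validation("invalid counts: events=%s n=%s", events, n)
  a <- 1 - level
  low <- if (events == 0) 0 else stats::qbeta(a / 2, events, n - events + 1)
  high <- if (events == n) 1 else stats::qbeta(1 - a / 2, events + 1, n - events)
  c(low = low, high = high)
}

#' Per-score-level calibration against the score-to-risk map
#'
#' For each distinct score value: the number of patients, observed SSIs and
#' observed rate with its exact 95% binomial CI, the expected rate from the
#' score-to-risk map, and whether the expected rate falls within the exact
#' CI of the observed rate. The headline summary counts only levels with at
#' least one observed SSI (the reporting convention of point-score
#' validation), and also reports the fraction of the population sitting at
#' within-CI levels.
#'
#' @param scores integer score vector.
#' @param y binary outcome vector.
#' @param map a `score_risk_map`.
#' @param level CI level (default 0.95).
#' @return list of class `calibration_report`: `rows` (one per score
#'   level), `levels_within`, `levels_total`, `pct_levels_within`,
#'   `pct_population_within`.
#' @export
calibration_by_score <- function(scores, y, map, level = 0.95) {
  y <- as.numeric(y)
  lv <- sort(unique(scores))
  rows <- data.frame(score = lv, n = NA_integer_, observed = NA_integer_,
                     observed_rate = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, expected_rate = NA_real_,
                     within_ci = NA)
  for (k in seq_along(lv)) {
    sel <- scores == lv[k]
    nk <- sum(sel); ok <- sum(y[sel])
    ci <- exact_binomial_ci(ok, nk, level)
    ek <- risk_from_score(lv[k], map)
    rows[k, -1] <- list(nk, ok, ok / nk, ci[["low"]], ci[["high"]], ek,
                        ci[["low"]] <= ek && ek <= ci[["high"]])
  }
  with_ssi <- rows$observed >= 1
  levels_total <- sum(with_ssi)
  levels_within <- sum(rows$within_ci & with_ssi)
  pop_within <- sum(rows$n[rows$within_ci & with_ssi])
  structure(list(
    rows = rows,
    levels_within = levels_within,
    levels_total = levels_total,
    pct_levels_within = if (levels_total) pct(levels_within, levels_total) else NA_real_,
    pct_population_within = pct(pop_within, sum(rows$n))
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration: expected within exact 95%% CI of observed at %d of %d SSI levels (%s%%), capturing %s%% of the population\n",
              x$levels_within, x$levels_total, x$pct_levels_within,
              x$pct_population_within))
  invisible(x)
}

#' Per-procedure duration cutpoints for the NNIS index
#'
#' 75th percentile of operation duration within each 3-digit CPT prefix of
#' the supplied (derivation) cohort, with the overall 75th percentile as
#' the fallback for unseen prefixes.
#'
#' @param records cohort data.frame.
#' @return named numeric vector of cutpoints (hours), attribute `global`
#'   holding the fallback.
#' @export
nnis_cutpoints <- function(records) {
  prefix <- substr(records$cpt_code, 1, 3)
  cp <- tapply(records$duration_hours, prefix, stats::quantile, probs = 0.75,
               names = FALSE)
  out <- as.numeric(cp)
  names(out) <- names(cp)
  attr(out, "global") <- stats::quantile(records$duration_hours, 0.75,
                                         names = FALSE)
  out
}

#' NNIS basic SSI risk index
#'
#' The legacy 0-3 comparator: one point each for ASA class 3 or higher, a
#' contaminated or dirty wound, and operation duration above the
#' procedure-specific 75th-percentile cutpoint (global fallback for unseen
#' procedures).
#'
#' @param records cohort data.frame.
#' @param cutpoints output of [nnis_cutpoints()].
#' @return integer vector in 0..3.
#' @export
nnis_index <- function(records, cutpoints) {
  prefix <- substr(records$cpt_code, 1, 3)
  cut_h <- unname(cutpoints[prefix])
  cut_h[is.na(cut_h)] <- attr(cutpoints, "global")
  as.integer(
    (as.integer(as.character(records$asa_class)) >= 3) +
      (as.character(records$wound_class) %in% c("contaminated", "dirty")) +
      (records$duration_hours > cut_h)
  )
}

#' Full evaluation of a score on a validation cohort
#'
#' Bundles discrimination (c-statistic with CI), Hosmer-Lemeshow
#' calibration of the mapped risks, and per-score-level exact-CI
#' calibration into one report.
#'
#' @param scores integer score vector (validation cohort).
#' @param y binary outcome vector.
#' @param map a `score_risk_map`.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @param level CI level.
#' @return list of class `evaluation_report` with `discrimination`, `hl`,
#'   `calibration`.
#' @export
evaluate_scores <- function(scores, y, map, hl_groups = 10, level = 0.95) {
  pred <- risk_from_score(scores, map)
  structure(list(
    discrimination = c_statistic(scores, y, level),
    hl = hosmer_lemeshow(pred, y, hl_groups),
    calibration = calibration_by_score(scores, y, map, level)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$discrimination)
  cat(sprintf("Hosmer-Lemeshow chi-square %.2f on %d df, p = %.3g\n",
              x$hl$statistic, x$hl$df, x$hl$p))
  print(x$calibration)
  invisible(x)
}
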
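# ---- model terms -----------------------------------------------------------
#
# A fitted risk model is a list of "terms". Each term expands to one or more
# design-matrix columns:
#   binary       one 0/1 column
#   categorical  indicator columns for every non-reference level (the whole
#                block enters/leaves selection jointly)
#   continuous   the fractional-polynomial basis of the stored fp_transform
#                (a linear term is an fp_transform with power 1)
#   interaction  all pairwise products of two parent terms' columns

make_term <- function(var, kind, levels = NULL, transform = NULL,
                      parents = NULL) {
  id <- if (kind == "interaction") paste(vapply(parents, `[[`, "", "id"),
                                         collapse = ":") else var
  structure(list(id = id, var = var, kind = kind, levels = levels,
                 transform = transform, parents = parents),
            class = "ssirs_term")
}

# Infer a term spec for a cohort column: logicals are binary, factors and
# characters categorical, numerics continuous (linear unless a transform is
# supplied later by fp selection).
infer_term <- function(data, var, transform = NULL) {
  x <- data[[var]]
  if (is.null(x)) stop_validation("unknown covariate '%s'", var)
  if (is.logical(x)) {
    make_term(var, "binary")
  } else if (is.factor(x) || is.character(x)) {
    lv <- if (var %in% names(CATEGORY_DOMAINS)) CATEGORY_DOMAINS[[var]] else
      sort(unique(as.character(x)))
    make_term(var, "categorical", levels = lv)
  } else {
    if (is.null(transform)) {
      ss <- fp_shift_scale(x)
      transform <- fp_transform(var, 1, shift = ss$shift, scale = ss$scale)
    }
    make_term(var, "continuous", transform = transform)
  }
}

term_columns <- function(data, term) {
  switch(term$kind,
    binary = {
      out <- cbind(as.numeric(data[[term$var]]))
      colnames(out) <- term$var
      out
    },
    categorical = {
      x <- factor(as.character(data[[term$var]]), levels = term$levels)
      if (anyNA(x)) stop_validation("%s: value outside declared levels", term$var)
      ref <- term$levels[1]
      out <- vapply(term$levels[-1], function(l) as.numeric(x == l),
                    numeric(nrow(data)))
      out <- matrix(out, nrow = nrow(data),
                    dimnames = list(NULL, paste0(term$var, "=", term$levels[-1])))
      out
    },
    continuous = {
      out <- fp_apply(data[[term$var]], term$transform)
      out
    },
    interaction = {
      A <- term_columns(data, term$parents[[1]])
      B <- term_columns(data, term$parents[[2]])
      out <- NULL
      for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
        col <- A[, i] * B[, j]
        out <- cbind(out, col)
        colnames(out)[ncol(out)] <- paste(colnames(A)[i], colnames(B)[j], sep = ":")
      }
      out
    },
    stop_validation("unknown term kind '%s'", term$kind)
  )
}

build_design <- function(data, terms) {
  if (!length(terms)) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  do.call(cbind, lapply(terms, function(tm) term_columns(data, tm)))
}

# ---- maximum-likelihood logistic fit ---------------------------------------

#' Fit a binomial logistic regression by IRLS
#'
#' Maximum-likelihood fit of a logistic model to a raw design matrix (an
#' intercept column is added internally), the numerical core of every
#' selection and scoring step in the pipeline. Convergence follows the
#' iteratively reweighted least squares criterion (relative deviance change
#' below 1e-10, up to 100 iterations). Wald p-values are reported per
#' coefficient. Perfect or quasi-perfect separation is detected (fitted
#' probabilities collapsing to 0/1 with diverging coefficients) and flagged
#' as non-converged with a diagnostic rather than returned silently.
#'
#' @param design numeric matrix of predictors, no intercept column; may
#'   have zero columns for an intercept-only fit.
#' @param y binary outcome (logical or 0/1), length `nrow(design)`.
#' @param terms optional list of term specs that generated `design`;
#'   stored so the model can rebuild its design from a data.frame.
#' @return an object of class `ssirs_model`: intercept, named coefficient
#'   vector, standard errors, Wald p-values, deviance, convergence flag,
#'   `n_obs`, `n_events`.
#' @export
fit_logistic <- function(design, y, terms = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_validation("y must be binary (0/1 or logical)")
  if (length(unique(y)) < 2) {
    stop_validation("degenerate outcome: y is constant, no maximum-likelihood estimate")
  }
  design <- as.matrix(design)
  if (nrow(design) != length(y)) stop_validation("design rows and y length differ")
  X <- cbind(`(Intercept)` = 1, design)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    collinear <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_validation("rank-deficient design; collinear columns: %s",
                    paste(collinear, collapse = ", "))
  }

  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))

  p <- ncol(X)
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  names(se) <- colnames(X)
  coefs <- fit$coefficients
  z <- coefs / se
  wald_p <- 2 * stats::pnorm(-abs(z))

  separated <- (min(fit$fitted.values) < 1e-8 || max(fit$fitted.values) > 1 - 1e-8) &&
    max(abs(coefs)) > 15
  converged <- fit$converged && !separated

  structure(list(
    intercept = unname(coefs[1]),
    coefficients = coefs[-1],
    se = se[-1],
    wald_p = wald_p[-1],
    intercept_se = se[1],
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    converged = converged,
    diagnostic = if (separated) "possible complete separation" else NULL,
    n_obs = length(y),
    n_events = sum(y),
    terms = terms,
    entry_p = NULL
  ), class = "ssirs_model")
}

#' @export
print.ssirs_model <- function(x, ...) {
  cat("<ssirs_model> logistic risk model\n")
  cat(sprintf("  n = %d, events = %d (%s%%), deviance = %.2f, converged: %s\n",
              x$n_obs, x$n_events, pct(x$n_events, x$n_obs), x$deviance,
              x$converged))
  tab <- term_table(x)
  if (nrow(tab)) print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Term-level summary of a fitted model
#'
#' One row per design column: covariate, its level or transform label, the
#' log-odds coefficient, Wald p-value and (when the model came from forward
#' selection) the likelihood-ratio entry p-value of its term.
#'
#' @param model an `ssirs_model`.
#' @return data.frame.
#' @export
term_table <- function(model) {
  if (!length(model$coefficients)) {
    return(data.frame(covariate = character(), label = character(),
                      coefficient = numeric(), wald_p = numeric(),
                      entry_p = numeric()))
  }
  labels <- names(model$coefficients)
  covariate <- sub("[=.:].*$", "", labels)
  entry <- rep(NA_real_, length(labels))
  if (!is.null(model$entry_p)) {
    for (id in names(model$entry_p)) {
      entry[startsWith(labels, id) | grepl(id, labels, fixed = TRUE)] <-
        model$entry_p[[id]]
    }
  }
  data.frame(covariate = covariate, label = labels,
             coefficient = unname(model$coefficients),
             wald_p = unname(model$wald_p), entry_p = entry,
             stringsAsFactors = FALSE)
}

#' Predicted SSI probabilities from a fitted model
#'
#' @param object an `ssirs_model`.
#' @param newdata either a cohort data.frame (when the model carries term
#'   specs) or a design matrix with the model's columns.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.ssirs_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else {
    if (is.null(object$terms)) {
      stop_validation("model has no term specs; supply a design matrix")
    }
    build_design(newdata, object$terms)
  }
  if (ncol(X) != length(object$coefficients)) {
    stop_validation("design has %d columns, model expects %d",
                    ncol(X), length(object$coefficients))
  }
  eta <- object$intercept + drop(X %*% object$coefficients)
  if (type == "link") eta else inv_logit(eta)
}
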
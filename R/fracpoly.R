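# Canonical fractional-polynomial power set (Royston-Altman convention).
FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial transform of a continuous covariate
#'
#' Stores everything needed to reproduce a selected FP form at scoring
#' time: the pre-transformation shift (to make all values strictly
#' positive) and power-of-ten scale, plus 1 (FP1) or 2 (FP2) powers from
#' the canonical set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, with power 0 read
#' as the natural log.
#'
#' @param variable covariate name.
#' @param powers numeric vector of 1 or 2 canonical powers (stored sorted).
#' @param shift nonnegative shift added to the covariate before scaling.
#' @param scale positive divisor (a power of 10 in practice).
#' @return object of class `fp_transform`.
#' @export
fp_transform <- function(variable, powers, shift = 0, scale = 1) {
  if (!length(powers) %in% c(1L, 2L)) {
    stop_validation("powers: FP degree must be 1 or 2")
  }
  if (!all(powers %in% FP_POWERS)) {
    stop_validation("powers: must come from the canonical set {%s}",
                    paste(FP_POWERS, collapse = ", "))
  }
  if (shift < 0) stop_validation("shift: must be nonnegative")
  if (scale <= 0) stop_validation("scale: must be positive")
  structure(
    list(variable = variable, powers = sort(powers),
         shift = shift, scale = scale, degree = length(powers)),
    class = "fp_transform"
  )
}

#' @export
print.fp_transform <- function(x, ...) {
  cat(sprintf("<fp_transform> %s: FP%d powers (%s), shift %g, scale %g\n",
              x$variable, x$degree, paste(x$powers, collapse = ", "),
              x$shift, x$scale))
  invisible(x)
}

# Standard preprocessing rule: no shift when already positive, else a small
# data-derived offset; scale is the power of ten of the shifted median.
fp_shift_scale <- function(x) {
  shift <- 0
  if (min(x) <= 0) {
    ux <- sort(unique(x))
    incr <- if (length(ux) > 1) min(diff(ux)) else 1
    shift <- -min(x) + incr
  }
  med <- stats::median(x + shift)
  scale <- 10^floor(log10(med))
  list(shift = shift, scale = scale)
}

#' Apply a fractional-polynomial transform
#'
#' Returns the FP basis of `x`: with `z = (x + shift)/scale`, column `j` is
#' `z^p_j` (power 0 meaning `log z`); for a repeated-power FP2 `(p, p)` the
#' columns are `z^p` and `z^p * log z`, the standard convention.
#'
#' @param x numeric vector; all values must be strictly positive after
#'   shift/scale.
#' @param transform an [fp_transform()].
#' @return numeric matrix with `degree` columns.
#' @export
fp_apply <- function(x, transform) {
  stopifnot(inherits(transform, "fp_transform"))
  z <- (x + transform$shift) / transform$scale
  bad <- which(z <= 0)
  if (length(bad)) {
    stop_validation("fp_apply: nonpositive value after shift at index %d (x = %g)",
                    bad[1], x[bad[1]])
  }
  pw <- transform$powers
  pow1 <- function(p) if (p == 0) log(z) else z^p
  if (transform$degree == 1L) {
    out <- cbind(pow1(pw[1]))
  } else if (pw[1] == pw[2]) {
    h <- pow1(pw[1])
    out <- cbind(h, h * log(z))
  } else {
    out <- cbind(pow1(pw[1]), pow1(pw[2]))
  }
  colnames(out) <- paste0(transform$variable, ".fp", seq_len(ncol(out)))
  out
}

# All FP candidate power tuples up to a degree, in tie-break order:
# degree 1 first, then lexicographic.
fp_candidates <- function(degree = 2) {
  cands <- lapply(FP_POWERS, function(p) p)
  if (degree >= 2) {
    for (i in seq_along(FP_POWERS)) {
      for (j in i:length(FP_POWERS)) {
        cands[[length(cands) + 1L]] <- c(FP_POWERS[i], FP_POWERS[j])
      }
    }
  }
  cands
}

# Binomial deviance of y ~ [1 | adjustment | extra], via IRLS.
fp_deviance <- function(y, adjustment, extra = NULL) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), adjustment, extra)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  fit$deviance
}

#' Select a fractional-polynomial form for a continuous covariate
#'
#' Implements the closed test of the Royston-Sauerbrei function-selection
#' procedure against a binary outcome, adjusted for an optional working
#' design matrix: the best FP2 (exhaustive search over 36 power pairs) is
#' compared with the null (4 df), then the linear form (3 df), then the
#' best FP1 (8 candidates, 2 df), by deviance differences against
#' chi-square critical values at `alpha`. The simplest adequate form wins;
#' ties in deviance are broken toward lower degree, then lexicographically
#' smaller power tuple.
#'
#' @param x numeric covariate vector.
#' @param y binary (0/1 or logical) outcome, same length.
#' @param adjustment optional numeric design matrix of the current working
#'   model (no intercept column), row-aligned with `x`.
#' @param alpha significance level of each closed-test stage (default
#'   0.05).
#' @param degree maximum FP degree searched, 1 or 2 (default 2).
#' @return the string `"omit"` (no association), `"linear"`, or an
#'   [fp_transform()]; the attribute `deviances` carries the null, linear,
#'   best-FP1 and best-FP2 deviances for reporting.
#' @export
fp_select <- function(x, y, adjustment = NULL, alpha = 0.05, degree = 2) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_validation("fp_select: y must be binary")
  if (length(unique(y)) < 2) stop_validation("fp_select: y is constant")
  n_events <- sum(y)
  max_par <- 1 + (if (is.null(adjustment)) 0 else ncol(adjustment)) + degree
  if (min(n_events, length(y) - n_events) < max_par) {
    stop_validation("fp_select: fewer events (%d) than parameters (%d)",
                    n_events, max_par)
  }

  ss <- fp_shift_scale(x)
  tf <- function(p) fp_transform("x", p, shift = ss$shift, scale = ss$scale)

  dev_null <- fp_deviance(y, adjustment)
  dev_linear <- fp_deviance(y, adjustment, fp_apply(x, tf(1)))

  best <- function(cands) {
    devs <- vapply(cands, function(p) fp_deviance(y, adjustment, fp_apply(x, tf(p))),
                   numeric(1))
    # first index attaining the minimum within tolerance: candidate order
    # encodes the tie-break (lower degree, then lexicographic)
    i <- which(devs <= min(devs) + 1e-9)[1]
    list(powers = cands[[i]], deviance = devs[i])
  }
  fp1 <- best(fp_candidates(1))
  fp2 <- if (degree >= 2) best(fp_candidates(2)) else fp1

  crit <- function(df) stats::qchisq(1 - alpha, df)
  devs <- c(null = dev_null, linear = dev_linear,
            fp1 = fp1$deviance, fp2 = fp2$deviance)

  result <- if (degree >= 2) {
    if (dev_null - fp2$deviance <= crit(4)) "omit"
    else if (dev_linear - fp2$deviance <= crit(3)) "linear"
    else if (fp1$deviance - fp2$deviance <= crit(2)) tf(fp1$powers)
    else tf(fp2$powers)
  } else {
    if (dev_null - fp1$deviance <= crit(2)) "omit"
    else if (dev_linear - fp1$deviance <= crit(1)) "linear"
    else tf(fp1$powers)
  }
  attr(result, "deviances") <- devs
  result
}
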
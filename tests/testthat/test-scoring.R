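# Hand-built two-covariate model with a known point unit: bmi enters as
# (bmi/5) so one point (5 bmi units) is worth exactly `unit` log-odds.
toy_point_model <- function(unit = 0.25, coef_a = NULL, coef_b = NULL) {
  terms <- list(
    ssirs:::make_term("bmi", "continuous",
                      transform = fp_transform("bmi", 1, shift = 0, scale = 5)),
    ssirs:::make_term("smoker", "binary"),
    ssirs:::make_term("preop_sepsis", "binary")
  )
  structure(list(
    intercept = -4,
    coefficients = c(bmi.fp1 = unit, smoker = coef_a %||% unit,
                     preop_sepsis = coef_b %||% 2.4 * unit),
    se = c(bmi.fp1 = 0.1, smoker = 0.1, preop_sepsis = 0.1),
    wald_p = c(bmi.fp1 = 0, smoker = 0, preop_sepsis = 0),
    deviance = 0, converged = TRUE, n_obs = 100L, n_events = 10,
    terms = terms
  ), class = "ssirs_model")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_data <- function(n = 200, seed = 1) {
  set.seed(seed)
  df <- make_record(n)
  df$bmi <- rnorm(n, 29, 6)
  df$smoker <- runif(n) < 0.3
  df$preop_sepsis <- runif(n) < 0.1
  df
}

test_that("point values follow the Sullivan unit definition and rounding rule", {
  df <- toy_data()
  tab <- build_point_table(toy_point_model(), df,
                           reference_covariate = "bmi", reference_delta = 5)
  # binary coefficient exactly B -> 1 point; 2.4 B -> 2 points
  smoker_pts <- tab$entries$smoker$categories$points
  expect_equal(smoker_pts[smoker_pts != 0], 1)
  sepsis_pts <- tab$entries$preop_sepsis$categories$points
  expect_equal(sepsis_pts[sepsis_pts != 0], 2)
  expect_equal(tab$reference_unit, 0.25, tolerance = 1e-12)

  # every covariate has exactly one zero-point reference category and the
  # declared range is the sum of per-covariate extremes
  mins <- vapply(tab$entries, function(e) min(e$categories$points), numeric(1))
  maxs <- vapply(tab$entries, function(e) max(e$categories$points), numeric(1))
  expect_equal(unname(tab$score_range), c(sum(mins), sum(maxs)))

  expect_error(build_point_table(toy_point_model(unit = 0), df),
               "zero")
  expect_error(build_point_table(toy_point_model(), df,
                                 categorization = list(nope = c(1, 2))),
               "nope")
  expect_error(build_point_table(toy_point_model(), df,
                                 reference_covariate = "smoker"),
               "continuous")
})

test_that("pipeline point table matches the brute-force round(beta * dW / B) oracle", {
  b <- pipeline_fixture()
  tab <- b$point_table
  model <- b$final
  B <- tab$reference_unit
  round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

  for (e in tab$entries) {
    coefs <- model$coefficients
    if (e$kind == "binary") {
      beta <- coefs[[e$var]]
      expect_equal(e$categories$points, c(0, round_away(beta / B)))
    } else if (e$kind == "categorical") {
      for (k in seq_len(nrow(e$categories))) {
        lvl <- e$categories$level[k]
        expected <- if (lvl == e$reference) 0 else
          round_away(coefs[[paste0(e$var, "=", lvl)]] / B)
        expect_equal(e$categories$points[k], expected)
      }
    } else {
      cols <- paste0(e$var, ".fp", seq_len(e$transform$degree))
      eta <- function(x) sum(fp_apply(x, e$transform)[1, ] * coefs[cols])
      eta_ref <- eta(e$categories$representative[e$reference])
      for (k in seq_len(nrow(e$categories))) {
        expected <- round_away((eta(e$categories$representative[k]) - eta_ref) / B)
        expect_equal(e$categories$points[k], expected)
      }
    }
  }
})

test_that("ssirs_score sums category points and stays in range", {
  df <- toy_data(1000, seed = 3)
  tab <- build_point_table(toy_point_model(), df)
  s <- ssirs_score(df, cpt3 = NULL, tab)

  # brute-force oracle: per-record category lookup in plain R
  oracle <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    pts <- 0
    for (e in tab$entries) {
      v <- df[[e$var]][i]
      if (e$kind == "binary") {
        pts <- pts + e$categories$points[match(as.character(v),
                                               e$categories$level)]
      } else {
        k <- which(v > e$categories$lower & v <= e$categories$upper)
        pts <- pts + e$categories$points[k]
      }
    }
    oracle[i] <- pts
  }
  expect_identical(s, as.integer(oracle))
  expect_true(all(s >= tab$score_range["min"] & s <= tab$score_range["max"]))

  # all-reference record scores the base constant (default 0)
  ref_rec <- df[1, , drop = FALSE]
  ref_rec$smoker <- FALSE; ref_rec$preop_sepsis <- FALSE
  ref_cat <- tab$entries$bmi$categories
  k <- tab$entries$bmi$reference
  ref_rec$bmi <- tab$entries$bmi$categories$representative[k]
  expect_equal(ssirs_score(ref_rec, NULL, tab), 0L)

  # a gap in explicit boundaries is an error
  tab_gap <- tab
  tab_gap$entries$bmi$categories <- tab$entries$bmi$categories[-2, ]
  expect_error(ssirs_score(df, NULL, tab_gap), "gap")
})

test_that("the score-risk map is the single-covariate logistic MLE", {
  # binary score: closed-form slope logit(p1) - logit(p0)
  scores <- c(rep(0, 200), rep(1, 200))
  y <- c(rep(1, 20), rep(0, 180), rep(1, 60), rep(0, 140))
  map <- fit_score_risk_map(scores, y)
  expect_equal(map$beta, qlogis(60 / 200) - qlogis(20 / 200), tolerance = 1e-8)
  expect_equal(map$intercept, qlogis(20 / 200), tolerance = 1e-8)

  # null: slope within 3 SE of zero
  set.seed(14)
  s <- sample(0:10, 2000, replace = TRUE)
  y2 <- runif(2000) < 0.1
  map2 <- fit_score_risk_map(s, y2)
  se <- fit_logistic(cbind(s = as.numeric(s)), y2)$se[["s"]]
  expect_lt(abs(map2$beta), 3 * se)

  expect_error(fit_score_risk_map(rep(3, 10), rbinom(10, 1, 0.5)), "constant")

  # perfect separation by score is flagged
  map3 <- fit_score_risk_map(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_false(map3$converged)
})

test_that("risk_from_score is the exact inverse-logit map", {
  map0 <- structure(list(intercept = 0, beta = 0), class = "score_risk_map")
  expect_equal(risk_from_score(-5:5, map0), rep(0.5, 11))

  map <- structure(list(intercept = -4, beta = 0.3), class = "score_risk_map")
  s <- -17:62
  r <- risk_from_score(s, map)
  expect_equal(r, 1 / (1 + exp(-(-4 + 0.3 * s))), tolerance = 1e-15)
  expect_true(all(diff(r) > 0)) # monotone when beta > 0

  # self-consistency with the fitting routine at every observed score
  set.seed(6)
  sc <- sample(0:20, 500, replace = TRUE)
  y <- runif(500) < plogis(-3 + 0.15 * sc)
  m <- fit_score_risk_map(sc, y)
  fitted <- predict(fit_logistic(cbind(ssirs = as.numeric(sc)), y),
                    cbind(ssirs = as.numeric(sc)))
  expect_equal(risk_from_score(sc, m), fitted, tolerance = 1e-10)
})

test_that("integer score loses (never gains) discrimination vs the full model", {
  b <- pipeline_fixture()
  v <- b$validation
  v$cpt3_score <- as.numeric(lookup_cpt3(v$cpt_code, b$cpt3))
  s <- ssirs_score(v, v$cpt3_score, b$point_table)
  c_int <- c_statistic(s, v$ssi30)$c_statistic
  c_model <- c_statistic(predict(b$final, v), v$ssi30)$c_statistic
  expect_lte(c_int, c_model + 1e-9)
})

test_that("point tables round-trip through JSON with identical scores", {
  b <- pipeline_fixture()
  d <- b$derivation
  d$cpt3_score <- as.numeric(lookup_cpt3(d$cpt_code, b$cpt3))
  fix <- d[seq_len(500), , drop = FALSE]
  path <- withr::local_tempfile(fileext = ".json")
  write_point_table(b$point_table, path, map = b$map)
  tab2 <- read_point_table(path)
  expect_identical(ssirs_score(fix, fix$cpt3_score, b$point_table),
                   ssirs_score(fix, fix$cpt3_score, tab2))
  map2 <- attr(tab2, "map")
  expect_equal(map2$beta, b$map$beta, tolerance = 1e-12)
})

test_that("NNT arithmetic is exact and harm is signalled", {
  expect_equal(nnt(0.10, 0.5), 20)
  expect_equal(nnt(0.01, 0.5), 200)
  expect_identical(nnt(0.3, 1.0), Inf)
  expect_error(nnt(0.1, 1.2), class = "ssirs_harm_error")
  expect_error(nnt(0, 0.5), "baseline_risk")
})
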
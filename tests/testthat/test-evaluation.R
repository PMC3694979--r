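test_that("c-statistic equals exhaustive pair counting", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$c_statistic, 1)
  expect_equal(c_statistic(rep(0.3, 10), c(1, 1, rep(0, 8)))$c_statistic, 0.5)

  set.seed(18)
  for (r in 1:5) {
    n <- sample(30:500, 1)
    pred <- round(runif(n), 2) # rounding forces ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    rep <- c_statistic(pred, y)
    expect_equal(rep$c_statistic, brute_force_c(pred, y), tolerance = 1e-12)
    expect_equal(rep$n_pairs, sum(y == 1) * sum(y == 0))
    expect_true(rep$ci_low <= rep$c_statistic && rep$c_statistic <= rep$ci_high)
  }
  expect_error(c_statistic(runif(5), rep(1, 5)), "both classes")
})

test_that("Hosmer-Lemeshow is zero under exact calibration and matches hand arithmetic", {
  # two risk strata where observed rate equals predicted rate exactly
  pred <- c(rep(0.2, 10), rep(0.5, 10))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 5), rep(0, 5))
  hl0 <- hosmer_lemeshow(pred, y, groups = 2)
  expect_equal(hl0$statistic, 0, tolerance = 1e-12)

  # hand-computed 2-group toy: group1 n=10 E=2 O=3; group2 n=10 E=5 O=4
  y2 <- c(rep(1, 3), rep(0, 7), rep(1, 4), rep(0, 6))
  hl <- hosmer_lemeshow(pred, y2, groups = 2)
  hand <- (3 - 2)^2 / 2 + (7 - 8)^2 / 8 + (4 - 5)^2 / 5 + (6 - 5)^2 / 5
  expect_equal(hl$statistic, hand, tolerance = 1e-12)
  expect_equal(hl$df, 0L)

  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), groups = 1), "groups")
})

test_that("Hosmer-Lemeshow rejects at about the nominal rate for a well-specified model", {
  set.seed(40)
  reps <- 500; n <- 10000
  rejections <- 0
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-3 + 0.6 * x))
    fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y, family = binomial()))
    hl <- hosmer_lemeshow(fit$fitted.values, y, groups = 10)
    rejections <- rejections + (hl$p < 0.05)
  }
  rate <- rejections / reps
  # within 3 binomial SEs of 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("exact binomial CI matches the beta-quantile and tail-probability oracles", {
  alpha <- 0.05
  n <- 12
  ci0 <- exact_binomial_ci(0, n)
  expect_equal(ci0[["low"]], 0)
  expect_equal(ci0[["high"]], 1 - (alpha / 2)^(1 / n), tolerance = 1e-12)
  expect_equal(exact_binomial_ci(n, n)[["high"]], 1)

  # independent oracle: bounds solve the binomial tail equations
  ci <- exact_binomial_ci(3, 10)
  low_oracle <- uniroot(function(p) 1 - pbinom(2, 10, p) - alpha / 2,
                        c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  high_oracle <- uniroot(function(p) pbinom(3, 10, p) - alpha / 2,
                         c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(ci[["low"]], low_oracle, tolerance = 1e-9)
  expect_equal(ci[["high"]], high_oracle, tolerance = 1e-9)

  expect_error(exact_binomial_ci(5, 4), "invalid")
})

test_that("exact CI coverage is at least nominal (Clopper-Pearson conservatism)", {
  set.seed(23)
  reps <- 2000; n <- 50; p <- 0.3
  x <- rbinom(reps, n, p)
  covered <- vapply(x, function(k) {
    ci <- exact_binomial_ci(k, n)
    ci[["low"]] <= p && p <= ci[["high"]]
  }, logical(1))
  expect_gte(mean(covered), 0.95 - 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("per-score-level calibration follows the CI coverage property", {
  map <- structure(list(intercept = -3.5, beta = 0.25),
                   class = "score_risk_map")
  set.seed(51)
  scores <- sample(0:12, 40000, replace = TRUE)
  y <- runif(length(scores)) < risk_from_score(scores, map)
  rep <- calibration_by_score(scores, y, map)
  expect_equal(nrow(rep$rows), 13)
  # outcomes drawn exactly from the map: ~95% of levels within the exact CI
  expect_gte(rep$levels_within / rep$levels_total, 0.8)
  expect_true(all(rep$rows$ci_low <= rep$rows$observed_rate + 1e-12))
  expect_true(all(rep$rows$observed_rate <= rep$rows$ci_high + 1e-12))

  # a level with zero events stays in the rows but leaves the summary
  s2 <- c(rep(0, 50), rep(1, 50))
  y2 <- c(rep(FALSE, 50), rep(TRUE, 5), rep(FALSE, 45))
  rep2 <- calibration_by_score(s2, y2, map)
  expect_equal(nrow(rep2$rows), 2)
  expect_equal(rep2$levels_total, 1)

  rep3 <- calibration_by_score(rep(4L, 30), rbinom(30, 1, 0.3), map)
  expect_equal(nrow(rep3$rows), 1)
})

test_that("NNIS index counts its three criteria", {
  deriv <- generate_cohort(default_cohort_config(5000L, seed = 60L))
  cuts <- nnis_cutpoints(deriv)

  rec0 <- make_record(asa_class = "1", wound_class = "clean",
                      duration_hours = 0.1, cpt_code = "10011")
  expect_equal(nnis_index(rec0, cuts), 0L)
  rec3 <- make_record(asa_class = "4", wound_class = "dirty",
                      duration_hours = 99, cpt_code = "10011")
  expect_equal(nnis_index(rec3, cuts), 3L)
  # unseen prefix falls back to the global cutpoint
  rec_unseen <- make_record(asa_class = "3", wound_class = "clean",
                            duration_hours = attr(cuts, "global") + 1,
                            cpt_code = "99999")
  expect_equal(nnis_index(rec_unseen, cuts), 2L)

  # on default synthetic settings the distribution concentrates at 0-1
  idx <- nnis_index(deriv, cuts)
  expect_true(all(idx %in% 0:3))
  expect_gte(mean(idx <= 1), 0.6)
})

test_that("the full model out-discriminates the NNIS index on heterogeneity-rich cohorts", {
  b <- pipeline_fixture()
  expect_gt(b$model_evaluation$c_statistic, b$nnis_evaluation$c_statistic)
})
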
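test_that("split_cohort partitions reproducibly with derivation taking the extra", {
  coh <- generate_cohort(default_cohort_config(11L, seed = 2L))
  h <- split_cohort(coh, seed = 5L)
  expect_equal(nrow(h$derivation), 6L)
  expect_equal(nrow(h$validation), 5L)
  expect_length(intersect(h$derivation$record_id, h$validation$record_id), 0)
  expect_setequal(c(h$derivation$record_id, h$validation$record_id),
                  coh$record_id)

  h2 <- split_cohort(coh, seed = 5L)
  expect_identical(h, h2)

  even <- split_cohort(coh[1:10, ], seed = 5L)
  expect_equal(nrow(even$derivation), 5L)

  expect_error(split_cohort(coh[0, ], seed = 1L), "empty")
})

test_that("CPT3 table applies the O/E ratio and the zero-event defaults", {
  stage1 <- constant_risk_model(0.1) # predicts 0.1 for every record
  records <- rbind(
    make_record(7, ssi30 = FALSE, cpt_code = "10011"),  # E = 0.7, O = 0
    make_record(3, ssi30 = FALSE, cpt_code = "20022"),  # E = 0.3, O = 0
    make_record(20, ssi30 = c(rep(TRUE, 4), rep(FALSE, 16)),
                cpt_code = "30033")                     # E = 2.0, O = 4
  )
  tab <- compute_cpt3_table(records, stage1)
  row <- function(p) tab[tab$prefix == p, ]

  expect_equal(row("100")$expected_ssi, 0.7, tolerance = 1e-9)
  expect_equal(row("100")$score, 0)
  expect_equal(row("100")$provenance, "default_zero")

  expect_equal(row("200")$expected_ssi, 0.3, tolerance = 1e-9)
  expect_equal(row("200")$score, 1)
  expect_equal(row("200")$provenance, "default_one")

  expect_equal(row("300")$score, 2.0, tolerance = 1e-9)
  expect_equal(row("300")$provenance, "ratio")
  expect_equal(row("300")$n_operations, 20L)

  # conservation: group expected counts sum to total predicted probability
  expect_equal(sum(tab$expected_ssi), sum(predict(stage1, records)),
               tolerance = 1e-9)
})

test_that("conservation holds on a full pipeline derivation cohort", {
  b <- pipeline_fixture()
  expect_equal(sum(b$cpt3$expected_ssi),
               sum(predict(b$stage1, b$derivation)), tolerance = 1e-6)
  expect_equal(sum(b$cpt3$observed_ssi), sum(b$derivation$ssi30))
})

test_that("lookup_cpt3 resolves prefixes, defaults and malformed codes", {
  tab <- structure(
    data.frame(prefix = "441", n_operations = 10L, observed_ssi = 2L,
               expected_ssi = 1.5, score = 1.3, provenance = "ratio",
               stringsAsFactors = FALSE),
    class = c("cpt3_table", "data.frame"))
  expect_equal(as.numeric(lookup_cpt3("44140", tab)), 1.3)
  unseen <- lookup_cpt3("99912", tab)
  expect_equal(as.numeric(unseen), 1.0)
  expect_equal(attr(unseen, "provenance"), "unseen_default")
  expect_error(lookup_cpt3("4x140", tab), "malformed")
  expect_error(lookup_cpt3("4414", tab), "malformed")
})

test_that("forward selection stops at the entry threshold and skips collinear candidates", {
  set.seed(21)
  coh <- generate_cohort(default_cohort_config(2000L, seed = 21L))
  coh$noise1 <- runif(nrow(coh)) < 0.5
  coh$noise2 <- runif(nrow(coh)) < 0.5

  # nothing reaches an absurdly strict threshold: intercept-only model
  m0 <- suppressMessages(
    forward_select(coh, c("noise1", "noise2"), p_entry = 1e-12))
  expect_length(m0$terms, 0)
  expect_length(m0$coefficients, 0)

  # identical duplicate covariate: exactly one copy enters
  coh$smoker_copy <- coh$smoker
  m1 <- suppressMessages(
    forward_select(coh, c("smoker", "smoker_copy", "preop_sepsis"),
                   p_entry = 0.9))
  ids <- vapply(m1$terms, `[[`, "", "id")
  expect_equal(sum(ids %in% c("smoker", "smoker_copy")), 1L)

  expect_error(forward_select(coh, character()), "no candidates")
})

test_that("forward selection finds a lone true signal among nulls", {
  set.seed(33)
  n <- 20000
  df <- data.frame(true_cov = runif(n) < 0.3)
  for (k in 1:10) df[[paste0("null", k)]] <- runif(n) < 0.5
  df$ssi30 <- runif(n) < plogis(-3.3 + 0.8 * df$true_cov)
  m <- suppressMessages(
    forward_select(df, c("true_cov", paste0("null", 1:10)), p_entry = 0.05))
  expect_true("true_cov" %in% vapply(m$terms, `[[`, "", "id"))
})

test_that("refitting on the identical cohort reproduces identical models", {
  coh <- generate_cohort(default_cohort_config(4000L, seed = 8L))
  m1 <- suppressMessages(forward_select(coh, c("smoker", "wound_class", "asa_class",
                                               "duration_hours"), p_entry = 0.05))
  m2 <- suppressMessages(forward_select(coh, c("smoker", "wound_class", "asa_class",
                                               "duration_hours"), p_entry = 0.05))
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(vapply(m1$terms, `[[`, "", "id"),
                   vapply(m2$terms, `[[`, "", "id"))
})

test_that("the CPT3 score is selected with a positive coefficient under group heterogeneity", {
  b <- pipeline_fixture()
  ids <- vapply(b$final$terms, `[[`, "", "id")
  expect_true("cpt3_score" %in% ids)
  cpt3_coefs <- b$final$coefficients[startsWith(names(b$final$coefficients),
                                                "cpt3_score")]
  v <- b$validation
  v$cpt3_score <- as.numeric(lookup_cpt3(v$cpt_code, b$cpt3))
  # higher CPT3 score must mean higher predicted risk, all else equal
  lo <- hi <- v[1, , drop = FALSE]
  lo$cpt3_score <- 0.8; hi$cpt3_score <- 1.5
  expect_gt(predict(b$final, hi), predict(b$final, lo))
  expect_equal(b$final$entry_p[["cpt3_score"]] < 1e-4, TRUE)
})

test_that("a-priori interactions are tested with hierarchy and retained when strong", {
  set.seed(55)
  coh <- generate_cohort(default_cohort_config(50000L, seed = 55L))
  # rebuild the outcome with strong mains plus a wound x duration interaction
  dirty <- coh$wound_class %in% c("contaminated", "dirty")
  logdur <- log(pmax(coh$duration_hours, 0.05))
  eta <- -3.6 + 0.8 * dirty + 0.5 * logdur + 1.0 * dirty * logdur
  coh$ssi30 <- runif(nrow(coh)) < plogis(eta)
  stage1 <- suppressMessages(
    forward_select(coh, c("wound_class", "duration_hours"), p_entry = 0.05))
  tab <- compute_cpt3_table(coh, stage1)
  m <- suppressMessages(derive_final_model(
    coh, tab, c("wound_class", "duration_hours"),
    interactions = list(c("wound_class", "duration_hours")),
    p_entry = 1e-4))
  ids <- vapply(m$terms, `[[`, "", "id")
  expect_true("wound_class:duration_hours" %in% ids)

  # hierarchy: an interaction whose main effect is absent is not tested
  msgs <- testthat::capture_messages(
    m2 <- derive_final_model(coh, tab, c("wound_class", "duration_hours"),
                             interactions = list(c("wound_class", "smoker")),
                             p_entry = 1e-4))
  expect_true(any(grepl("hierarchy", msgs)))
  expect_false(any(grepl("smoker", vapply(m2$terms, `[[`, "", "id"))))

  # empty interaction set leaves the forward-selection result untouched
  m3 <- suppressMessages(derive_final_model(
    coh, tab, c("wound_class", "duration_hours"), p_entry = 1e-4))
  expect_false(any(vapply(m3$terms, `[[`, "", "kind") == "interaction"))
})

test_that("the CPT3 stage adds discrimination when group heterogeneity is real", {
  b <- pipeline_fixture()
  v <- b$validation
  v$cpt3_score <- as.numeric(lookup_cpt3(v$cpt_code, b$cpt3))
  c_stage1 <- c_statistic(predict(b$stage1, v), v$ssi30)$c_statistic
  c_final <- c_statistic(predict(b$final, v), v$ssi30)$c_statistic
  expect_gte(c_final, c_stage1 - 0.02) # allow sampling noise
})
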
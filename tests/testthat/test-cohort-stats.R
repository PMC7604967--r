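test_that("descriptive summary reproduces published cohort statistics", {
  d <- descriptive_summary(reconstruct_printed_cohort())
  expect_equal(round(d$score_mean, 1), 5.3)
  expect_equal(round(d$score_sd, 1), 2.8)
  # count/percent tables sum to 100 up to rounding
  for (tab in d$tables) {
    expect_equal(sum(tab$n), 46)
    expect_lt(abs(sum(tab$percent) - 100), 0.3)
  }
  # constant score: SD exactly 0
  df <- data.frame(volume_grade = rep(2, 5), arterial_score = 1,
                   cs_involved = FALSE, bone_invaded = FALSE)
  expect_equal(descriptive_summary(cohort_table(df))$score_sd, 0)
})

test_that("Spearman correlation handles monotone and tied inputs", {
  expect_equal(spearman_rho(1:8, (1:8)^2)$rs, 1.0)
  expect_equal(spearman_rho(1:8, rev(1:8))$rs, -1.0)
  expect_equal(spearman_rho(1:8, (1:8)^2)$p, 0)
  # tie case against the hand-computed mid-rank oracle
  x <- c(1, 2, 2, 3); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y)$rs, spearman_oracle(x, y), tolerance = 1e-12)
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("Spearman matches the brute-force ranks oracle on random tied vectors", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y)$rs, spearman_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("univariate tests behave on degenerate and hand-computed cases", {
  df <- data.frame(volume_grade = rep(2L, 40), arterial_score = rep(3L, 40),
                   cs_involved = rep(c(TRUE, FALSE), 20),
                   bone_invaded = FALSE,
                   simpson_grade = rep(1:4, each = 10))
  co <- cohort_table(df)
  ut <- univariate_tests(co, ordinal = "volume_grade", nominal = "cs_involved")
  # variable identical across groups: KW statistic 0, p = 1
  kw <- ut[ut$variable == "volume_grade", ]
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p, 1)

  # 2x2 chi-square against the hand-computed Sum (O-E)^2 / E = 6.6667
  df2 <- data.frame(volume_grade = 1, arterial_score = 0,
                    cs_involved = rep(c(TRUE, FALSE, TRUE, FALSE),
                                      c(20, 10, 10, 20)),
                    bone_invaded = FALSE,
                    simpson_grade = rep(c(1, 2), each = 30))
  ut2 <- univariate_tests(cohort_table(df2), ordinal = character(0),
                          nominal = "cs_involved")
  expect_equal(ut2$statistic, 20 / 3, tolerance = 1e-10)
})

test_that("Kruskal-Wallis p is invariant under monotone relabeling", {
  co <- simulate_cohort(cohort_model(n_patients = 120, seed = 5))
  p1 <- univariate_tests(co, ordinal = "total_score", nominal = character(0))$p
  co2 <- co
  co2$total_score <- co2$total_score^3 + 5   # strictly monotone relabeling
  class(co2) <- class(co)
  p2 <- univariate_tests(co2, ordinal = "total_score", nominal = character(0))$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("a strong score effect is detected reliably", {
  hits <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_model(n_patients = 100, beta_score = 1.5,
                                       seed = s))
    univariate_tests(co, ordinal = "total_score",
                     nominal = character(0))$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("ordinal regression recovers the generating coefficient", {
  b <- vapply(1:10, function(s) {
    co <- simulate_cohort(cohort_model(n_patients = 2000, beta_score = 1,
                                       seed = 100 + s))
    log(adjusted_odds_ratios(co, predictors = "total_score")$or)
  }, 0)
  expect_equal(mean(b), 1, tolerance = 0.15)
  expect_error(
    adjusted_odds_ratios(cohort_table(
      data.frame(volume_grade = 1:3, arterial_score = 0, cs_involved = FALSE,
                 bone_invaded = FALSE, simpson_grade = 2))),
    "single level")
})

test_that("binary-family odds ratios run as a sensitivity analysis", {
  co <- simulate_cohort(cohort_model(n_patients = 400, seed = 21))
  or <- adjusted_odds_ratios(co, family = "binary")
  expect_equal(nrow(or), 4)
  expect_true(all(or$ci_lower <= or$or & or$or <= or$ci_upper))
  expect_gt(or$or[or$variable == "arterial_score"], 1)
})

test_that("discriminant accuracy spans separable and chance-level regimes", {
  # perfectly separable classes (arterial score varies within each group so
  # the within-group covariance is non-degenerate)
  df <- data.frame(volume_grade = rep(1:3, length.out = 40),
                   arterial_score = rep(c(0, 1, 3, 4), each = 10),
                   cs_involved = rep(c(FALSE, TRUE), 20),
                   bone_invaded = FALSE,
                   simpson_grade = rep(c(1, 4), each = 20))
  expect_equal(discriminant_accuracy(cohort_table(df),
                                     predictors = "arterial_score"), 100)

  # labels independent of the predictor, 4 balanced classes: ~25%
  set.seed(3)
  df2 <- data.frame(volume_grade = sample(1:3, 2000, TRUE),
                    arterial_score = sample(0:4, 2000, TRUE),
                    cs_involved = sample(c(TRUE, FALSE), 2000, TRUE),
                    bone_invaded = sample(c(TRUE, FALSE), 2000, TRUE),
                    simpson_grade = rep(1:4, 500))
  acc <- discriminant_accuracy(cohort_table(df2),
                               predictors = c("volume_grade", "arterial_score",
                                              "cs_involved", "bone_invaded"))
  expect_lt(abs(acc - 25), 5)

  expect_error(discriminant_accuracy(cohort_table(
    data.frame(volume_grade = 1:2, arterial_score = 0, cs_involved = FALSE,
               bone_invaded = FALSE, simpson_grade = c(1, 2)))),
    "fewer records than classes")
})

test_that("leave-one-out accuracy is available and not above resubstitution by construction", {
  co <- simulate_cohort(cohort_model(n_patients = 200, seed = 31))
  resub <- discriminant_accuracy(co)
  loo <- discriminant_accuracy(co, mode = "loo")
  expect_true(is.finite(loo) && loo >= 0 && loo <= 100)
  expect_lte(loo, resub + 5)
})

test_that("score-outcome correlation is negative under an adverse outcome effect", {
  co <- simulate_cohort(cohort_model(n_patients = 500, outcome_beta = -0.5,
                                     seed = 17))
  so <- score_outcome_correlation(co)
  expect_lt(so$rs, 0)

  # outcome = reverse-ranked score: rs = -1
  df <- data.frame(volume_grade = c(1, 1, 2, 3), arterial_score = c(0, 1, 2, 4),
                   cs_involved = FALSE, bone_invaded = FALSE,
                   simpson_grade = NA_integer_, outcome_grade = c(3, 2, 1, 0))
  expect_equal(score_outcome_correlation(cohort_table(df))$rs, -1)

  df$outcome_grade <- 1
  expect_error(score_outcome_correlation(cohort_table(df)), "constant")
})

test_that("the full battery mirrors the published pattern on simulated data", {
  co <- simulate_cohort(cohort_model(n_patients = 300, seed = 4))
  st <- cohort_stats(co)
  expect_true(all(st$univariate$p < 0.05))
  expect_true(all(abs(st$spearman$rs) <= 1))
  expect_gt(st$spearman$rs[st$spearman$variable == "total_score"], 0.5)
  expect_lt(st$score_outcome$rs, 0)
  expect_true(st$discriminant_accuracy > 25 && st$discriminant_accuracy <= 100)
  expect_true(all(st$odds_ratios$ci_lower <= st$odds_ratios$or &
                    st$odds_ratios$or <= st$odds_ratios$ci_upper))
})
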
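trial_tables <- attention_trial_tables()

test_that("chi-square reproduces the published trial statistics", {
  full <- chi_square_test(trial_tables$treatment_outcome)
  expect_equal(round(full$statistic, 3), 5.930)
  expect_equal(round(full$p_value, 3), 0.015)
  expect_equal(round(full$cramers_v, 3), 0.317)
  expect_equal(full$v_label, "moderate")

  stroke <- chi_square_test(trial_tables$stroke_treatment_outcome)
  expect_equal(round(stroke$statistic, 3), 8.073)
  expect_equal(round(stroke$cramers_v, 3), 0.419)

  cr <- chi_square_test(trial_tables$highcr_treatment_outcome)
  expect_equal(round(cr$statistic, 3), 4.725)
  expect_equal(round(cr$cramers_v, 2), 0.34)
})

test_that("a balanced table gives zero chi-square and V", {
  res <- chi_square_test(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$cramers_v, 0)
  expect_equal(res$v_label, "weak")
})

test_that("zero margins are a degenerate-table error", {
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 5))),
               class = "rehabspc_error_degenerate")
  expect_error(chi_square_test(rbind(c(5, 0), c(5, 0))),
               class = "rehabspc_error_degenerate")
})

test_that("2x2 chi-square equals the closed form on random tables", {
  set.seed(11)
  for (i in 1:300) {
    m <- random_2x2()
    expect_equal(chi_square_test(m)$statistic, oracle_chisq_2x2(m),
                 tolerance = 1e-9)
  }
})

test_that("chi-square, V and Fisher p are invariant under permutation and transpose", {
  set.seed(12)
  for (i in 1:40) {
    m <- random_2x2()
    base <- chi_square_test(m)
    swapped_rows <- chi_square_test(m[2:1, ])
    transposed <- chi_square_test(t(m))
    expect_equal(base$statistic, swapped_rows$statistic, tolerance = 1e-12)
    expect_equal(base$cramers_v, transposed$cramers_v, tolerance = 1e-12)
    expect_equal(fisher_exact(m), fisher_exact(t(m)), tolerance = 1e-12)
  }
})

test_that("Fisher exact p reproduces the published values and the enumeration oracle", {
  expect_equal(round(fisher_exact(trial_tables$treatment_outcome), 3), 0.021)
  expect_equal(round(fisher_exact(trial_tables$stroke_treatment_outcome), 3),
               0.010)
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1))), 1.0)
  set.seed(13)
  for (i in 1:100) {
    m <- random_2x2(n_max = 100)
    p <- fisher_exact(m)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, oracle_fisher_2x2(m), tolerance = 1e-7)
  }
  expect_error(fisher_exact(matrix(1, 3, 2)), class = "rehabspc_error_shape")
})

test_that("odds ratio matches the published orientation, interval and headline", {
  or <- odds_ratio(trial_tables$treatment_outcome)
  expect_equal(round(or$odds_ratio, 3), 0.231)
  expect_equal(round(or$conf_low, 3), 0.068)
  expect_equal(round(or$conf_high, 3), 0.784)
  expect_equal(round(or$reciprocal, 1), 4.3)
  expect_equal(round(odds_ratio(trial_tables$stroke_treatment_outcome)$odds_ratio, 3),
               0.149)
})

test_that("odds-ratio identities: equal odds give 1; column swap inverts", {
  expect_equal(odds_ratio(rbind(c(7, 7), c(3, 3)))$odds_ratio, 1)
  set.seed(14)
  for (i in 1:40) {
    m <- random_2x2()
    if (any(m == 0)) next
    a <- odds_ratio(m)$odds_ratio
    b <- odds_ratio(m[, 2:1])$odds_ratio
    expect_equal(a * b, 1, tolerance = 1e-12)
    ci <- odds_ratio(m)
    expect_lte(ci$conf_low, ci$odds_ratio)
    expect_gte(ci$conf_high, ci$odds_ratio)
  }
})

test_that("zero cells flag the Woolf interval unavailable unless corrected", {
  m <- rbind(c(5, 0), c(3, 4))
  plain <- odds_ratio(m)
  expect_false(plain$ci_available)
  expect_true(is.na(plain$conf_low))
  corrected <- odds_ratio(m, correction = TRUE)
  expect_true(corrected$ci_available)
  expect_true(is.finite(corrected$conf_high))
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
  res <- one_way_anova(d, y, g)
  expect_equal(res$f_statistic, 13.5)
  expect_equal(res$eta_squared, 13.5 / 17.5, tolerance = 1e-6)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$eta_label, "large")
})

test_that("identical groups give F = 0 with p = 1", {
  d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(5, 6))
  res <- one_way_anova(d, y, g)
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$eta_squared, 0)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(15)
  for (i in 1:30) {
    y1 <- rnorm(sample(3:12, 1))
    y2 <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    d <- tibble::tibble(g = rep(c("a", "b"), c(length(y1), length(y2))),
                        y = c(y1, y2))
    res <- one_way_anova(d, y, g)
    tt <- t.test(y1, y2, var.equal = TRUE)
    expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    # eta^2 = F df1 / (F df1 + df2)
    expect_equal(res$eta_squared,
                 res$f_statistic / (res$f_statistic + res$df_within),
                 tolerance = 1e-9)
  }
})

test_that("eta-squared interval covers the point estimate and respects bounds", {
  ci <- eta_squared_ci(4.245, 1, 31)
  eta <- 4.245 / (4.245 + 31)
  expect_lte(ci[1], eta)
  expect_gte(ci[2], eta)
  expect_gte(ci[1], 0)
  expect_lte(ci[2], 1)
  # tiny F pins the lower bound at zero
  expect_equal(eta_squared_ci(0.01, 1, 30)[1], 0)
})

test_that("Pearson correlation handles the standard cases", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  expect_equal(pearson_correlation(d, x, y)$r, 0.6)
  expect_equal(pearson_correlation(tibble::tibble(x = 1:5, y = 1:5), x, y)$r, 1)
  expect_equal(pearson_correlation(tibble::tibble(x = 1:5, y = -(1:5)), x, y)$r, -1)
  expect_error(
    pearson_correlation(tibble::tibble(x = 1:5, y = rep(2, 5)), x, y),
    class = "rehabspc_error_degenerate"
  )
})

test_that("linear-probability regression recovers exact and null structure", {
  d <- tibble::tibble(x = c(0, 0, 1, 1), y = c(0, 0, 1, 1))
  fit <- lp_regression(d, y ~ x)
  # summary.lm warns about the numerically perfect fit; that is the point
  expect_equal(suppressWarnings(glance(fit)$r_squared), 1)
  expect_equal(unname(coef(fit$fit)), c(0, 1), tolerance = 1e-12)

  set.seed(16)
  x <- rep(c(-1, 1), 10)
  y <- rep(c(0, 1, 1, 0), 5) # orthogonal to x by construction
  g <- glance(lp_regression(tibble::tibble(x = x, y = y), y ~ x))
  expect_equal(g$r_squared, 0, tolerance = 1e-12)
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n),
                        y = as.numeric(runif(n) < 0.5))
    if (length(unique(d$y)) < 2) next
    fit <- lp_regression(d, y ~ x1 + x2)
    X <- cbind(1, d$x1, d$x2)
    expect_equal(unname(coef(fit$fit)),
                 as.vector(oracle_ols(X, d$y)), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected", {
  d <- tibble::tibble(x1 = 1:6, x2 = 2 * (1:6), y = rep(c(0, 1), 3))
  expect_error(lp_regression(d, y ~ x1 + x2), class = "rehabspc_error_rank")
})

test_that("linear-by-linear matches its derivation and expansion oracle", {
  expect_equal(linear_by_linear(matrix(5, 2, 2))$statistic, 0)
  expect_equal(linear_by_linear(rbind(c(10, 0), c(0, 10)))$statistic, 19)
  set.seed(18)
  for (i in 1:40) {
    m <- random_2x2()
    got <- linear_by_linear(m)$statistic
    want <- oracle_linear_by_linear(m)
    if (is.na(want)) next # zero variance in expanded scores
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(linear_by_linear(rbind(c(2, 3), c(4, 1)), row_scores = c(1, 1)),
               class = "rehabspc_error_degenerate")
})

test_that("effect-size band labels follow the stated thresholds", {
  expect_equal(label_cramers_v(c(0.1, 0.2, 0.21, 0.6, 0.9)),
               c("weak", "weak", "moderate", "strong", "strong"))
  expect_equal(label_eta_squared(c(0.01, 0.059, 0.06, 0.139, 0.14)),
               c("small", "small", "medium", "medium", "large"))
})

test_that("associate screens categorical and numeric predictors tidily", {
  set.seed(19)
  coh <- simulate_cohort(sim_config(n_patients = 60), seed = 19)
  out <- suppressWarnings(spc_classify(coh$series, coh$covariates))
  out$age <- rnorm(nrow(out), 45, 11)
  res <- associate(out, predictors = c("arm", "age"))
  expect_true(all(c("chi_square", "fisher_exact") %in%
                    res$test[res$term == "arm"]))
  expect_true(all(c("pearson_correlation", "one_way_anova") %in%
                    res$test[res$term == "age"]))
  expect_equal(attr(res, "n_tests"), nrow(res))
})
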
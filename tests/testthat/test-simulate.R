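test_that("configuration validation rejects impossible parameters", {
  expect_error(sim_config(p_apt = 1.2), class = "rehabspc_error_config")
  expect_error(sim_config(n_patients = 0), class = "rehabspc_error_config")
  expect_error(sim_config(noise_sd = -1), class = "rehabspc_error_config")
  expect_error(sim_config(p_side = c(left = 0.5, right = 0.2,
                                     bilateral = 0.2)),
               class = "rehabspc_error_config")
  expect_warning(sim_config(n_sessions = 5),
                 class = "rehabspc_warning_short_series")
})

test_that("identical configuration and seed give identical cohorts", {
  cfg <- sim_config(n_patients = 25)
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$series, b$series)
  expect_identical(a$covariates, b$covariates)
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$series, c$series))
})

test_that("every patient appears exactly once in each component", {
  coh <- simulate_cohort(sim_config(n_patients = 30), seed = 3)
  expect_equal(anyDuplicated(coh$covariates$patient_id), 0)
  expect_setequal(unique(coh$series$patient_id), coh$covariates$patient_id)
  expect_equal(nrow(coh$series), 30 * coh$config$n_sessions)
})

test_that("a noiseless, driftless, effect-free cohort is constant", {
  cfg <- sim_config(n_patients = 8, noise_sd = 0, learning_drift = 0,
                    effect_size_delta = 0)
  coh <- simulate_cohort(cfg, seed = 4)
  spread <- coh$series %>%
    dplyr::group_by(patient_id) %>%
    dplyr::summarise(d = max(score) - min(score))
  expect_true(all(spread$d == 0))
})

test_that("scores respect the configured range and integer scale", {
  cfg <- sim_config(n_patients = 40, baseline_mean = 58, baseline_sd = 6)
  coh <- simulate_cohort(cfg, seed = 5)
  expect_true(all(coh$series$score >= 0 & coh$series$score <= 60))
  expect_true(all(coh$series$score == round(coh$series$score)))
})

test_that("covariate frequencies converge to their configured values", {
  cfg <- sim_config(n_patients = 10000)
  coh <- simulate_cohort(cfg, seed = 6)
  cv <- coh$covariates
  n <- nrow(cv)
  check_freq <- function(obs_p, p) {
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs_p - p), 3 * se + 1e-12)
  }
  check_freq(mean(cv$arm == "APT"), cfg$p_apt)
  check_freq(mean(cv$diagnosis == "stroke"), cfg$p_stroke)
  check_freq(mean(cv$cr_class == "high"), cfg$p_high_cr)
  check_freq(mean(cv$lesion_side == "right"), cfg$p_side[["right"]])
  check_freq(mean(cv$lesion_distribution == "multifocal"), cfg$p_multifocal)
  # responder frequency is a mixture over arms
  check_freq(mean(cv$responder[cv$arm == "APT"]),
             cfg$p_responder[["APT"]])
})

test_that("a strong step is detected in nearly all responders", {
  cfg <- sim_config(n_patients = 200, effect_size_delta = 6,
                    changepoint_session = 4, noise_sd = 2,
                    p_responder = c(APT = 1, ABAT = 1))
  coh <- simulate_cohort(cfg, seed = 8)
  out <- spc_classify(coh$series)
  expect_gt(mean(out$label == "CHANGE"), 0.95)
})

test_that("null CHANGE fraction matches the exact per-series signal probability", {
  # no drift, no effect: every alarm is false; the pooled cohort sigma makes
  # the noiseless analytic recursion applicable
  # noise SD large relative to the integer rounding grid so the continuous
  # Gaussian recursion applies; the shared pooled-sigma estimate contributes
  # a small systematic term on top of the binomial error
  cfg <- sim_config(n_patients = 3000, learning_drift = 0,
                    effect_size_delta = 0, baseline_mean = 30,
                    baseline_sd = 0, noise_sd = 20,
                    score_range = c(-1e6, 1e6))
  coh0 <- simulate_cohort(cfg, seed = 9)
  out <- spc_classify(coh0$series)
  p <- signal_probability(cfg$n_sessions, baseline = "estimated")
  se <- sqrt(p * (1 - p) / nrow(out))
  expect_lt(abs(mean(out$label == "CHANGE") - p), 3 * se + 0.01)
})

test_that("operating characteristics: power rises with the step height", {
  oc <- operating_characteristics(deltas = c(0, 1, 2, 4), n_replicates = 300,
                                  config = sim_config(learning_drift = 0),
                                  seed = 10)
  expect_equal(nrow(oc), 4)
  rates <- oc$detection_rate[order(oc$delta)]
  expect_true(all(diff(rates) >= 0))
  expect_gt(oc$detection_rate[oc$delta == 4],
            oc$detection_rate[oc$delta == 1])
  # under the null the two rates estimate the same quantity
  null_row <- oc[oc$delta == 0, ]
  expect_lt(abs(null_row$detection_rate - null_row$false_alarm_rate),
            3 * sqrt(null_row$detection_se^2 + null_row$false_alarm_se^2) +
              1e-12)
})

test_that("operating characteristics are reproducible and plottable", {
  a <- operating_characteristics(deltas = c(0, 4), n_replicates = 30,
                                 seed = 11)
  b <- operating_characteristics(deltas = c(0, 4), n_replicates = 30,
                                 seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_s3_class(autoplot(a), "ggplot")
})

test_that("the pipeline closes end-to-end over generator, charts and association", {
  coh <- simulate_cohort(sim_config(n_patients = 80), seed = 12)
  out <- spc_classify(coh$series, coh$covariates)
  res <- associate(out, predictors = c("arm", "diagnosis", "cr_class"))
  expect_true(nrow(res) >= 3)
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
})
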
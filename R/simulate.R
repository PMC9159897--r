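#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates the parameters of the generative model used by
#' [simulate_cohort()]. Defaults mirror the study conditions the pipeline is
#' designed for: 59 patients randomized 32/27 to two attention-training arms
#' (APT vs ABAT), nine serial-addition test sessions (baseline, one after
#' every third hour of a 20-hour programme, and one after completion), an
#' early learning effect over the first three administrations shared by both
#' arms, arm-specific latent responder probabilities 27/32 and 15/27, and
#' covariate frequencies matching the trial's baseline tables (78 percent
#' stroke, 71 percent high cognitive reserve, lesion side 25/22/12
#' left/right/bilateral, lesion site 20/11/22/6
#' anterior/posterior/subcortical/global, 34/63 multifocal).
#'
#' The trajectory model is additive:
#' \deqn{score_{it} = b_i + d \cdot \min(t - 1, 3) + R_i \, \delta \sigma_\epsilon \,
#'   1[t \ge t_0] + \epsilon_{it}}
#' with patient baseline \eqn{b_i \sim N(\mu_b, \sigma_b^2)}, learning drift
#' d per session capped after `learning_sessions` sessions, latent responder
#' flag \eqn{R_i}, step height \eqn{\delta} in noise-SD units from the
#' changepoint session \eqn{t_0}, and i.i.d. Gaussian session noise. Scores
#' are rounded to integers and clipped to `score_range` (counts of correct
#' responses on a 61-trial serial-addition form by default).
#'
#' @param n_patients Number of patients.
#' @param p_apt Probability of allocation to the APT arm.
#' @param n_sessions Sessions per patient; values below 8 warn (the chart
#'   design assumes at least eight repeated measurements).
#' @param p_responder Named vector: latent responder probability in each arm.
#' @param baseline_mean,baseline_sd Between-patient baseline distribution.
#' @param noise_sd Within-patient session-to-session SD.
#' @param learning_drift Per-session score increment during the first
#'   `learning_sessions` transitions (both arms; emulates the early learning
#'   effect).
#' @param learning_sessions Number of sessions over which the drift
#'   accumulates.
#' @param effect_size_delta Responder step height in units of `noise_sd`.
#' @param changepoint_session First session at which the responder step is
#'   active.
#' @param p_stroke,p_high_cr Covariate frequencies (stroke diagnosis, high
#'   cognitive reserve).
#' @param p_side Named probabilities for lesion side (left/right/bilateral).
#' @param p_multifocal Probability of a multifocal lesion distribution.
#' @param p_site Named probabilities for lesion site.
#' @param score_range Closed interval to which scores are clipped.
#' @param seed Optional integer seed stored with the configuration;
#'   [simulate_cohort()] uses it unless given one explicitly.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 59,
                       p_apt = 32 / 59,
                       n_sessions = 9,
                       p_responder = c(APT = 27 / 32, ABAT = 15 / 27),
                       baseline_mean = 30,
                       baseline_sd = 8,
                       noise_sd = 2,
                       learning_drift = 1,
                       learning_sessions = 3,
                       effect_size_delta = 4,
                       changepoint_session = 4,
                       p_stroke = 46 / 59,
                       p_high_cr = 42 / 59,
                       p_side = c(left = 25 / 59, right = 22 / 59,
                                  bilateral = 12 / 59),
                       p_multifocal = 34 / 63,
                       p_site = c(anterior = 20 / 59, posterior = 11 / 59,
                                  subcortical = 22 / 59, global = 6 / 59),
                       score_range = c(0, 60),
                       seed = NULL) {
  cfg <- list(
    n_patients = as.integer(n_patients), p_apt = p_apt,
    n_sessions = as.integer(n_sessions), p_responder = p_responder,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd, learning_drift = learning_drift,
    learning_sessions = as.integer(learning_sessions),
    effect_size_delta = effect_size_delta,
    changepoint_session = as.integer(changepoint_session),
    p_stroke = p_stroke, p_high_cr = p_high_cr, p_side = p_side,
    p_multifocal = p_multifocal, p_site = p_site,
    score_range = score_range, seed = seed
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_apt, cfg$p_responder, cfg$p_stroke, cfg$p_high_cr,
             cfg$p_side, cfg$p_multifocal, cfg$p_site)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("All probabilities must lie in [0, 1].",
          class = "rehabspc_error_config")
  }
  if (cfg$n_patients < 1L) {
    abort("`n_patients` must be at least 1.",
          class = "rehabspc_error_config")
  }
  if (cfg$n_sessions < 2L) {
    abort("`n_sessions` must be at least 2.",
          class = "rehabspc_error_config")
  }
  if (cfg$n_sessions < 8L) {
    warn("`n_sessions` below 8: the chart design assumes a minimum of eight repeated measurements.",
         class = "rehabspc_warning_short_series")
  }
  if (!isTRUE(all.equal(sum(cfg$p_side), 1, tolerance = 1e-6))) {
    abort("`p_side` must sum to 1.", class = "rehabspc_error_config")
  }
  if (!isTRUE(all.equal(sum(cfg$p_site), 1, tolerance = 1e-6))) {
    abort("`p_site` must sum to 1.", class = "rehabspc_error_config")
  }
  if (cfg$noise_sd < 0 || cfg$baseline_sd < 0) {
    abort("Standard deviations must be non-negative.",
          class = "rehabspc_error_config")
  }
  if (diff(cfg$score_range) <= 0) {
    abort("`score_range` must be an increasing interval.",
          class = "rehabspc_error_config")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, %d sessions, P(APT) = %.3f\n",
              x$n_patients, x$n_sessions, x$p_apt))
  cat(sprintf("  responder probabilities: APT %.3f, ABAT %.3f\n",
              x$p_responder[["APT"]], x$p_responder[["ABAT"]]))
  cat(sprintf(
    "  baseline %s +/- %s, noise SD %s, drift %s x %d sessions, step %s SD at session %d\n",
    format(x$baseline_mean), format(x$baseline_sd), format(x$noise_sd),
    format(x$learning_drift), x$learning_sessions,
    format(x$effect_size_delta), x$changepoint_session))
  invisible(x)
}

#' Generate a synthetic cohort of attention-test trajectories
#'
#' Draws per-patient covariates and repeated-measurement series from the
#' model described in [sim_config()]. The output has the exact shape the
#' change-detection and association stages consume, so the whole pipeline is
#' exercisable without any external data.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`. Identical
#'   configuration and seed give identical cohorts. `NULL` leaves the RNG
#'   state untouched.
#' @return An object of class `rehab_cohort`: a list with tibbles
#'   `covariates` (patient_id, arm, diagnosis, lesion_side,
#'   lesion_distribution, lesion_site, cr_class, responder) and `series`
#'   (patient_id, session, score), plus the `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 10), seed = 42)
#' head(coh$series)
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_patients
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(n))

  arm <- ifelse(runif(n) < config$p_apt, "APT", "ABAT")
  responder <- rbinom(n, 1, config$p_responder[arm]) == 1
  covariates <- tibble(
    patient_id = ids,
    arm = arm,
    diagnosis = ifelse(runif(n) < config$p_stroke, "stroke", "TBI"),
    lesion_side = sample(names(config$p_side), n, replace = TRUE,
                         prob = config$p_side),
    lesion_distribution = ifelse(runif(n) < config$p_multifocal,
                                 "multifocal", "unifocal"),
    lesion_site = sample(names(config$p_site), n, replace = TRUE,
                         prob = config$p_site),
    cr_class = ifelse(runif(n) < config$p_high_cr, "high", "low"),
    responder = responder
  )

  t <- seq_len(config$n_sessions)
  drift <- config$learning_drift * pmin(t - 1, config$learning_sessions)
  step <- config$effect_size_delta * config$noise_sd *
    (t >= config$changepoint_session)
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  series <- purrr::map(seq_len(n), function(i) {
    mu <- baseline[i] + drift + if (responder[i]) step else 0
    sc <- round(mu + rnorm(config$n_sessions, 0, config$noise_sd))
    sc <- pmin(pmax(sc, config$score_range[1]), config$score_range[2])
    tibble(patient_id = ids[i], session = t, score = sc)
  }) %>% bind_rows()

  structure(list(covariates = covariates, series = series, config = config),
            class = "rehab_cohort")
}

#' @export
print.rehab_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$covariates), " patients x ",
      x$config$n_sessions, " sessions (",
      sum(x$covariates$arm == "APT"), " APT, ",
      sum(x$covariates$arm == "ABAT"), " ABAT)\n", sep = "")
  invisible(x)
}

#' Operating characteristics of the detection rules
#'
#' Monte-Carlo power analysis of the change-detection stage: for each step
#' height delta (in noise-SD units) and series length, simulates responder
#' and non-responder series from the generative model and reports the
#' detection rate P(CHANGE | responder) and false-alarm rate
#' P(CHANGE | non-responder) with binomial standard errors.
#'
#' Each grid cell simulates an independent cohort of `n_replicates`
#' responders and `n_replicates` non-responders, classified with the pooled
#' cohort sigma exactly as [spc_classify()] would.
#'
#' @param deltas Numeric vector of step heights to evaluate.
#' @param n_sessions Integer vector of series lengths to evaluate.
#' @param n_replicates Simulated patients per responder status per cell.
#' @param config Base [sim_config()]; its drift, noise and baseline
#'   parameters are kept, delta and length are overridden per cell.
#' @param seed Integer seed for reproducibility.
#' @return A tibble of class `spc_oc`: `delta`, `n_sessions`,
#'   `detection_rate`, `detection_se`, `false_alarm_rate`, `false_alarm_se`,
#'   `n_replicates`.
#' @examples
#' operating_characteristics(deltas = c(0, 4), n_replicates = 50, seed = 1)
#' @export
operating_characteristics <- function(deltas = c(0, 1, 2, 4),
                                      n_sessions = 9,
                                      n_replicates = 500,
                                      config = sim_config(),
                                      seed = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  grid <- expand.grid(delta = deltas, n_sessions = n_sessions,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- purrr::pmap(grid, function(delta, n_sessions) {
    cfg <- config
    cfg$effect_size_delta <- delta
    cfg$n_sessions <- as.integer(n_sessions)
    rates <- vapply(c(TRUE, FALSE), function(resp) {
      sim <- simulate_status_cohort(cfg, n_replicates, responder = resp)
      out <- suppressWarnings(spc_classify(sim))
      mean(out$label == "CHANGE")
    }, numeric(1))
    tibble(
      delta = delta, n_sessions = as.integer(n_sessions),
      detection_rate = rates[1],
      detection_se = sqrt(rates[1] * (1 - rates[1]) / n_replicates),
      false_alarm_rate = rates[2],
      false_alarm_se = sqrt(rates[2] * (1 - rates[2]) / n_replicates),
      n_replicates = as.integer(n_replicates)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("spc_oc", class(out))
  out
}

# internal: series for n patients with a forced responder status
simulate_status_cohort <- function(config, n, responder) {
  t <- seq_len(config$n_sessions)
  drift <- config$learning_drift * pmin(t - 1, config$learning_sessions)
  step <- config$effect_size_delta * config$noise_sd *
    (t >= config$changepoint_session)
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  width <- max(3L, nchar(as.character(n)))
  ids <- sprintf(paste0("S%0", width, "d"), seq_len(n))
  purrr::map(seq_len(n), function(i) {
    mu <- baseline[i] + drift + if (responder) step else 0
    sc <- round(mu + rnorm(config$n_sessions, 0, config$noise_sd))
    sc <- pmin(pmax(sc, config$score_range[1]), config$score_range[2])
    tibble(patient_id = ids[i], session = t, score = sc)
  }) %>% bind_rows()
}

#' Plot detection power against step height
#'
#' @param object An `spc_oc` tibble from [operating_characteristics()].
#' @param ... Unused.
#' @return A ggplot object: detection and false-alarm rates vs delta, one
#'   line per series length, with binomial standard-error ribbons.
#' @export
autoplot.spc_oc <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("detection_rate", "false_alarm_rate"),
    names_to = "quantity", values_to = "rate"
  )
  long$se <- ifelse(long$quantity == "detection_rate",
                    object$detection_se[match(
                      paste(long$delta, long$n_sessions),
                      paste(object$delta, object$n_sessions))],
                    object$false_alarm_se[match(
                      paste(long$delta, long$n_sessions),
                      paste(object$delta, object$n_sessions))])
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$delta, y = .data$rate,
    colour = factor(.data$n_sessions), linetype = .data$quantity)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$rate - 2 * .data$se, 0),
      ymax = pmin(.data$rate + 2 * .data$se, 1),
      fill = factor(.data$n_sessions)), alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Step height (noise-SD units)", y = "P(CHANGE)",
                  colour = "Sessions", fill = "Sessions",
                  linetype = NULL,
                  title = "Operating characteristics of the run rules")
}
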
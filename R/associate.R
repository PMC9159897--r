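#' Predictor-association screen over a classified cohort
#'
#' Runs the association suite across a set of candidate predictors of the
#' dichotomous outcome, the way the downstream analysis treats a classified
#' cohort: categorical predictors are cross-tabulated against the outcome
#' and tested with the chi-square bundle ([table_association()]); numeric
#' predictors are screened with the Pearson correlation against the 0/1
#' outcome and tested with one-way ANOVA using the outcome as the grouping
#' factor ([one_way_anova()]). No multiplicity adjustment is applied (each
#' test is reported at its nominal level, matching the exploratory design);
#' the number of tests run is attached as the `n_tests` attribute and
#' reported by `print()`.
#'
#' @param data Data frame with one row per patient, e.g. from
#'   [spc_classify()]: must contain the outcome column plus the predictors.
#' @param outcome Name of the outcome column (default `"label"`); must have
#'   exactly two levels, the first of which is taken as the event
#'   (`CHANGE`).
#' @param predictors Character vector of predictor column names; defaults to
#'   every column except the outcome, `patient_id`, and chart bookkeeping
#'   columns.
#' @param conf_level Confidence level for odds-ratio intervals.
#' @return A tibble with one row per test: `term`, `test`, `statistic`,
#'   `df`, `p_value`, `effect_size`, `effect_label`, `odds_ratio`,
#'   `conf_low`, `conf_high`, `n`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 40), seed = 2)
#' out <- spc_classify(coh$series, coh$covariates)
#' associate(out, predictors = c("arm", "diagnosis"))
#' @export
associate <- function(data, outcome = "label", predictors = NULL,
                      conf_level = 0.95) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  y <- factor(data[[outcome]])
  y <- droplevels(y)
  if (nlevels(y) != 2L) {
    abort("The outcome must have exactly two observed levels.")
  }
  if (is.null(predictors)) {
    skip <- c(outcome, "patient_id", "n_signals", "first_signal_session",
              "first_signal_rule", "centreline", "sigma", "n_sessions")
    predictors <- setdiff(names(data), skip)
  }
  miss <- setdiff(predictors, names(data))
  if (length(miss) > 0L) {
    abort(paste0("Unknown predictor column(s): ",
                 paste(miss, collapse = ", ")))
  }

  rows <- list()
  for (p in predictors) {
    v <- data[[p]]
    if (is.numeric(v) && length(unique(na.omit(v))) > 2L) {
      y01 <- as.numeric(y == levels(y)[1])
      cr <- pearson_correlation(tibble(x = v, y = y01), x, y)
      rows[[length(rows) + 1L]] <- tibble(
        term = p, test = "pearson_correlation", statistic = cr$r,
        df = cr$n - 2, p_value = cr$p_value, effect_size = cr$r,
        effect_label = NA_character_, odds_ratio = NA_real_,
        conf_low = NA_real_, conf_high = NA_real_, n = cr$n
      )
      anova_dat <- tibble(.score = v, .grp = y)
      av <- one_way_anova(anova_dat, .score, .grp)
      rows[[length(rows) + 1L]] <- tibble(
        term = p, test = "one_way_anova", statistic = av$f_statistic,
        df = av$df_between, p_value = av$p_value,
        effect_size = av$eta_squared, effect_label = av$eta_label,
        odds_ratio = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
        n = av$df_between + av$df_within + 1
      )
    } else {
      tab <- table(factor(v), y)
      if (any(dim(tab) < 2L) || any(rowSums(tab) == 0) ||
          any(colSums(tab) == 0)) next
      ta <- table_association(as.matrix(unclass(tab)),
                              conf_level = conf_level)
      rows[[length(rows) + 1L]] <- tibble(
        term = p, test = "chi_square", statistic = ta$statistic,
        df = ta$df, p_value = ta$p_value, effect_size = ta$cramers_v,
        effect_label = ta$v_label, odds_ratio = ta$odds_ratio,
        conf_low = ta$conf_low, conf_high = ta$conf_high, n = ta$n
      )
      if (!is.na(ta$fisher_p)) {
        rows[[length(rows) + 1L]] <- tibble(
          term = p, test = "fisher_exact", statistic = NA_real_,
          df = NA_real_, p_value = ta$fisher_p, effect_size = ta$cramers_v,
          effect_label = ta$v_label, odds_ratio = NA_real_,
          conf_low = NA_real_, conf_high = NA_real_, n = ta$n
        )
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "n_tests") <- nrow(out)
  class(out) <- c("rehab_association", class(out))
  out
}

#' @export
print.rehab_association <- function(x, ...) {
  cat("Association screen:", attr(x, "n_tests"),
      "tests (no multiplicity adjustment)\n")
  NextMethod()
}
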
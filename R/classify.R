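#' Fit individual control charts to a cohort of measurement series
#'
#' The workhorse of the change-detection stage. Takes a long-format table of
#' repeated measurements, builds one individual chart per patient (centreline
#' from the first two sessions, sigma pooled across the cohort's baseline
#' pairs or estimated per patient from the baseline moving range), scans the
#' remaining sessions with the two run rules, and labels every patient
#' `CHANGE` or `NO_CHANGE`.
#'
#' @param data Data frame with one row per measurement and columns
#'   `patient_id`, `session` (ordered within patient) and `score`.
#' @param sigma_strategy `"pooled"` (one sigma for the whole cohort, pooled
#'   over all baseline pairs — the default, which stabilises a two-point
#'   spread estimate) or `"moving-range"` (per-patient `|x1 - x2| / 1.128`).
#' @param direction Passed to [detect_signals()]; `"improvement"` by default.
#' @param sigma Optional externally supplied sigma (overrides
#'   `sigma_strategy`); a single value recycled to all patients.
#' @return An object of class `spc_fit` with components `outcomes`,
#'   `signals`, `charts` (tibbles) and `series` (the input, ordered).
#'   Use [tidy()] for the per-patient outcome table, [glance()] for cohort
#'   counts, [autoplot()] for faceted charts, or [spc_classify()] to go
#'   straight to the outcome tibble.
#' @details Patients with fewer than 8 sessions trigger a warning (the design
#'   of the rule set assumes a minimum of eight repeated measurements);
#'   fewer than 2 sessions is an error since no baseline can be formed.
#'   Duplicated `(patient_id, session)` rows are an error.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 12), seed = 1)
#' fit <- spc_fit(coh$series)
#' tidy(fit)
#' @export
spc_fit <- function(data, sigma_strategy = c("pooled", "moving-range"),
                    direction = c("improvement", "both"), sigma = NULL) {
  sigma_strategy <- match.arg(sigma_strategy)
  direction <- match.arg(direction)
  data <- check_series_frame(data)

  split_scores <- split(data$score, data$patient_id)
  split_sessions <- split(data$session, data$patient_id)
  ids <- names(split_scores)

  for (id in ids) check_scores(split_scores[[id]], min_n = 2L, patient = id)
  short <- ids[vapply(split_scores, length, integer(1)) < 8L]
  if (length(short) > 0L) {
    warn(
      sprintf(
        "%d patient(s) have fewer than 8 sessions (%s); the chart design assumes a minimum of eight repeated measurements.",
        length(short), paste(utils::head(short, 5L), collapse = ", ")
      ),
      class = "rehabspc_warning_short_series"
    )
  }

  b1 <- vapply(split_scores, `[[`, numeric(1), 1L)
  b2 <- vapply(split_scores, `[[`, numeric(1), 2L)
  if (!is.null(sigma)) {
    sigmas <- rep_len(sigma, length(ids))
    strategy <- "supplied"
  } else if (sigma_strategy == "pooled") {
    sigmas <- rep_len(pooled_sigma(b1, b2), length(ids))
    strategy <- "pooled"
  } else {
    sigmas <- moving_range_sigma(b1, b2)
    strategy <- "moving-range"
  }

  charts <- purrr::map2(split_scores, sigmas, build_chart,
                        sigma_strategy = strategy)
  names(charts) <- ids

  signals <- purrr::imap(charts, function(ch, id) {
    s <- detect_signals(split_scores[[id]], ch, direction = direction)
    s$session <- split_sessions[[id]][s$index]
    s$patient_id <- rep_len(id, nrow(s))
    s
  }) %>%
    bind_rows() %>%
    select("patient_id", "session", "index", "rule", "side", "score")

  outcomes <- purrr::imap(charts, function(ch, id) {
    s <- signals[signals$patient_id == id, ]
    imp <- s[s$side == "above", ]
    tibble(
      patient_id = id,
      label = classify_outcome(imp),
      n_signals = nrow(s),
      first_signal_session = if (nrow(s)) s$session[which.min(s$index)] else NA_integer_,
      first_signal_rule = if (nrow(s)) s$rule[which.min(s$index)] else NA_character_,
      centreline = ch$centreline,
      sigma = ch$sigma,
      n_sessions = length(split_scores[[id]])
    )
  }) %>% bind_rows()

  structure(
    list(outcomes = outcomes, signals = signals, charts = charts,
         series = data, sigma_strategy = strategy, direction = direction),
    class = "spc_fit"
  )
}

#' Classify a cohort as CHANGE / NO CHANGE
#'
#' Convenience wrapper around [spc_fit()] that returns the per-patient
#' outcome tibble directly, optionally joined with a covariate table for
#' downstream association analysis.
#'
#' @inheritParams spc_fit
#' @param covariates Optional data frame with a `patient_id` column and one
#'   row per patient; joined onto the outcome table. Duplicate ids are an
#'   error, and ids present in only one of the two tables are an error
#'   (listed in the message).
#' @return A tibble with one row per patient: `patient_id`, `label`
#'   (`CHANGE`/`NO_CHANGE`), `n_signals`, `first_signal_session`,
#'   `first_signal_rule`, chart parameters, and any covariates.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 12), seed = 1)
#' spc_classify(coh$series, coh$covariates)
#' @export
spc_classify <- function(data, covariates = NULL,
                         sigma_strategy = c("pooled", "moving-range"),
                         direction = c("improvement", "both"), sigma = NULL) {
  fit <- spc_fit(data, sigma_strategy = sigma_strategy,
                 direction = direction, sigma = sigma)
  out <- fit$outcomes
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    if (!"patient_id" %in% names(covariates)) {
      abort("`covariates` must contain a `patient_id` column.")
    }
    covariates$patient_id <- as.character(covariates$patient_id)
    dup <- unique(covariates$patient_id[duplicated(covariates$patient_id)])
    if (length(dup) > 0L) {
      abort(paste0("Duplicate patient ids in `covariates`: ",
                   paste(utils::head(dup, 5L), collapse = ", ")),
            class = "rehabspc_error_duplicate_id")
    }
    only_series <- setdiff(out$patient_id, covariates$patient_id)
    only_cov <- setdiff(covariates$patient_id, out$patient_id)
    if (length(only_series) || length(only_cov)) {
      abort(
        paste0(
          "Series and covariates do not match. ",
          if (length(only_series)) paste0("Missing covariates for: ",
            paste(utils::head(only_series, 5L), collapse = ", "), ". ") else "",
          if (length(only_cov)) paste0("No series for: ",
            paste(utils::head(only_cov, 5L), collapse = ", "), ".") else ""
        ),
        class = "rehabspc_error_join"
      )
    }
    out <- left_join(out, covariates, by = "patient_id")
  }
  out
}

#' @export
tidy.spc_fit <- function(x, ...) x$outcomes

#' @export
glance.spc_fit <- function(x, ...) {
  tibble(
    n_patients = nrow(x$outcomes),
    n_change = sum(x$outcomes$label == "CHANGE"),
    n_no_change = sum(x$outcomes$label == "NO_CHANGE"),
    prop_change = mean(x$outcomes$label == "CHANGE"),
    sigma_strategy = x$sigma_strategy,
    direction = x$direction
  )
}

#' @export
print.spc_fit <- function(x, ...) {
  g <- glance(x)
  cat("SPC change-detection fit: ", g$n_patients, " patients (",
      g$n_change, " CHANGE, ", g$n_no_change, " NO_CHANGE), sigma: ",
      g$sigma_strategy, "\n", sep = "")
  invisible(x)
}

#' Plot the individual charts of an SPC fit
#'
#' One panel per patient: the score series, centreline (solid), 2-sigma
#' warning limits (dashed), 3-sigma control limits (dotted), with signalling
#' points highlighted.
#'
#' @param object An [spc_fit()] object.
#' @param patients Optional character vector restricting which patients are
#'   drawn (all by default; consider a subset for large cohorts).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spc_fit <- function(object, patients = NULL, ...) {
  ser <- object$series
  if (!is.null(patients)) ser <- ser[ser$patient_id %in% patients, ]
  ids <- unique(ser$patient_id)
  lim <- bind_rows(lapply(ids, function(id) {
    ch <- object$charts[[id]]
    tibble(patient_id = id, centreline = ch$centreline,
           uwl = ch$uwl, lwl = ch$lwl, ucl = ch$ucl, lcl = ch$lcl)
  }))
  sig <- object$signals[object$signals$patient_id %in% ids, ]
  sig <- left_join(sig,
                   ser[, c("patient_id", "session", "score")],
                   by = c("patient_id", "session", "score"))
  ggplot2::ggplot(ser, ggplot2::aes(x = .data$session, y = .data$score)) +
    ggplot2::geom_hline(data = lim,
      ggplot2::aes(yintercept = .data$centreline)) +
    ggplot2::geom_hline(data = lim, ggplot2::aes(yintercept = .data$uwl),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = lim, ggplot2::aes(yintercept = .data$lwl),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = lim, ggplot2::aes(yintercept = .data$ucl),
                        linetype = "dotted") +
    ggplot2::geom_hline(data = lim, ggplot2::aes(yintercept = .data$lcl),
                        linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = sig, colour = "red", size = 2) +
    ggplot2::facet_wrap(~patient_id, scales = "free_y") +
    ggplot2::labs(x = "Session", y = "Score",
                  title = "Individual control charts",
                  subtitle = "Red points: rule violations")
}

# internal: validate/coerce a long series frame
check_series_frame <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("patient_id", "session", "score")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    abort(paste0("`data` is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  data <- as_tibble(data)
  data$patient_id <- as.character(data$patient_id)
  if (!is.numeric(data$session)) abort("`session` must be numeric.")
  if (!is.numeric(data$score)) abort("`score` must be numeric.")
  if (anyNA(data$session) || !all(is.finite(data$score))) {
    abort("`session` and `score` must be finite and non-missing.")
  }
  dup <- duplicated(data[, c("patient_id", "session")])
  if (any(dup)) {
    abort(paste0("Duplicate (patient_id, session) rows, e.g. patient ",
                 data$patient_id[which(dup)[1]], " session ",
                 data$session[which(dup)[1]], "."),
          class = "rehabspc_error_duplicate_id")
  }
  arrange(data, .data$patient_id, .data$session)
}
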
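#' Run configuration for the pipeline front end
#'
#' A validated key-value configuration shared by the `simulate`, `detect`
#' and `associate` stages and their command-line wrappers. Unknown keys are
#' rejected, and a configuration round-trips unchanged through its YAML
#' serialization.
#'
#' @param sigma_strategy `"pooled"` or `"moving-range"`.
#' @param direction `"improvement"` or `"both"`.
#' @param seed Integer seed or `NULL`.
#' @param plots Render per-patient chart plots in [run_detect()].
#' @param conf_level Confidence level for odds-ratio intervals.
#' @param format_version Serialization format tag.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sigma_strategy = "pooled",
                       direction = "improvement",
                       seed = NULL,
                       plots = FALSE,
                       conf_level = 0.95,
                       format_version = "1") {
  cfg <- list(sigma_strategy = sigma_strategy, direction = direction,
              seed = seed, plots = plots, conf_level = conf_level,
              format_version = format_version)
  validate_run_config(cfg)
}

run_config_keys <- c("sigma_strategy", "direction", "seed", "plots",
                     "conf_level", "format_version")

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "rehabspc_error_config")
  }
  if (!cfg$sigma_strategy %in% c("pooled", "moving-range")) {
    abort("`sigma_strategy` must be \"pooled\" or \"moving-range\".",
          class = "rehabspc_error_config")
  }
  if (!cfg$direction %in% c("improvement", "both")) {
    abort("`direction` must be \"improvement\" or \"both\".",
          class = "rehabspc_error_config")
  }
  if (!is.numeric(cfg$conf_level) || cfg$conf_level <= 0 ||
      cfg$conf_level >= 1) {
    abort("`conf_level` must be in (0, 1).", class = "rehabspc_error_config")
  }
  structure(cfg, class = "run_config")
}

#' Serialize / deserialize a run configuration
#'
#' @param config A [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  cfg <- yaml::read_yaml(path)
  base <- unclass(run_config())
  base[names(cfg)] <- cfg
  # re-impose NULL for keys yaml dropped
  for (k in setdiff(run_config_keys, names(cfg))) base[k] <- list(base[[k]])
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "rehabspc_error_config")
  }
  validate_run_config(base)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `series.csv`, `covariates.csv`, the generator configuration as
#' `sim_config.yaml` (provenance echo) and a `run.log` with the seed, row
#' counts and configuration hash.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config, seed = seed)
  paths <- list(
    series = file.path(out_dir, "series.csv"),
    covariates = file.path(out_dir, "covariates.csv"),
    config = file.path(out_dir, "sim_config.yaml"),
    log = file.path(out_dir, "run.log")
  )
  write.csv(cohort$series, paths$series, row.names = FALSE)
  write.csv(cohort$covariates, paths$covariates, row.names = FALSE)
  cfg <- unclass(config)
  cfg$seed <- seed
  yaml::write_yaml(cfg, paths$config)
  write_run_log(paths$log, stage = "simulate", config = cfg, seed = seed,
                extra = c(n_patients = nrow(cohort$covariates),
                          n_rows_series = nrow(cohort$series)))
  invisible(paths)
}

#' Detect change on a series file or data frame
#'
#' The `detect` stage: classify every patient as CHANGE / NO CHANGE and
#' write `outcomes.csv` (patient_id, label, n_signals, first_signal_session,
#' first_signal_rule). A warning is logged for every patient with fewer than
#' 8 observations. With `plots = TRUE`, faceted individual charts are saved
#' as `charts.png`.
#'
#' @param series Path to a series CSV or a long-format data frame.
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @return Invisibly, a named list of written file paths; the outcome
#'   tibble as attribute `"outcomes"`.
#' @export
run_detect <- function(series, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- if (is.character(series)) read_series_csv(series) else
    check_series_frame(series)
  fit <- spc_fit(dat, sigma_strategy = config$sigma_strategy,
                 direction = config$direction)
  out <- fit$outcomes %>%
    select("patient_id", "label", "n_signals", "first_signal_session",
           "first_signal_rule")
  paths <- list(outcomes = file.path(out_dir, "outcomes.csv"),
                log = file.path(out_dir, "run.log"))
  write.csv(out, paths$outcomes, row.names = FALSE)
  if (isTRUE(config$plots)) {
    paths$charts <- file.path(out_dir, "charts.png")
    p <- autoplot(fit)
    n <- nrow(fit$outcomes)
    ggplot2::ggsave(paths$charts, p, width = 10,
                    height = 2.5 * ceiling(sqrt(n)), limitsize = FALSE)
  }
  write_run_log(paths$log, stage = "detect", config = unclass(config),
                seed = config$seed,
                extra = c(n_patients = nrow(out),
                          n_change = sum(out$label == "CHANGE")))
  res <- invisible(paths)
  attr(res, "outcomes") <- fit$outcomes
  res
}

#' Run the association suite and write a tidy results file
#'
#' The `associate` stage. Either joins an outcomes table with a covariate
#' table and screens every covariate against the outcome, or analyses a
#' bare counts table directly. Writes `results.csv` (one row per test) and
#' a human-readable `report.txt` with effect-size interpretation bands.
#'
#' @param outcomes Path to an outcomes CSV (from [run_detect()]) or the
#'   corresponding data frame. Ignored when `counts` is given.
#' @param covariates Path to a covariate CSV or data frame; optional.
#' @param counts Path to a counts CSV ([read_counts_csv()]) or a matrix for
#'   direct contingency-table analysis.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param subset Optional named list of covariate filters, e.g.
#'   `list(diagnosis = "stroke")`; rows not matching every filter are
#'   dropped before testing.
#' @return Invisibly, the written file paths with the results tibble as
#'   attribute `"results"`.
#' @export
run_associate <- function(outcomes = NULL, covariates = NULL, counts = NULL,
                          out_dir, config = run_config(), subset = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(counts)) {
    m <- if (is.character(counts)) read_counts_csv(counts) else
      check_counts(counts)
    ta <- table_association(m, conf_level = config$conf_level)
    res <- tibble(
      term = "counts_table", test = "chi_square", statistic = ta$statistic,
      df = ta$df, p_value = ta$p_value, effect_size = ta$cramers_v,
      effect_label = ta$v_label, odds_ratio = ta$odds_ratio,
      conf_low = ta$conf_low, conf_high = ta$conf_high, n = ta$n
    )
    if (!is.na(ta$fisher_p)) {
      res <- bind_rows(res, tibble(
        term = "counts_table", test = "fisher_exact", statistic = NA_real_,
        df = NA_real_, p_value = ta$fisher_p, effect_size = ta$cramers_v,
        effect_label = ta$v_label, odds_ratio = NA_real_,
        conf_low = NA_real_, conf_high = NA_real_, n = ta$n
      ))
    }
  } else {
    if (is.null(outcomes)) abort("Provide `outcomes` or `counts`.")
    out <- if (is.character(outcomes)) {
      o <- as_tibble(read.csv(outcomes, stringsAsFactors = FALSE))
      o$patient_id <- as.character(o$patient_id)
      o
    } else as_tibble(outcomes)
    if (!is.null(covariates)) {
      cov <- if (is.character(covariates)) read_covariates_csv(covariates)
        else as_tibble(covariates)
      cov$patient_id <- as.character(cov$patient_id)
      only_out <- setdiff(out$patient_id, cov$patient_id)
      only_cov <- setdiff(cov$patient_id, out$patient_id)
      if (length(only_out) || length(only_cov)) {
        abort(paste0(
          "Join failure between outcomes and covariates. ",
          if (length(only_out)) paste0("No covariates for: ",
            paste(utils::head(only_out, 5L), collapse = ", "), ". ") else "",
          if (length(only_cov)) paste0("No outcomes for: ",
            paste(utils::head(only_cov, 5L), collapse = ", "), ".") else ""),
          class = "rehabspc_error_join")
      }
      out <- left_join(out, cov, by = "patient_id")
    }
    if (!is.null(subset)) {
      for (k in names(subset)) {
        if (!k %in% names(out)) {
          abort(paste0("Subset column not found: ", k))
        }
        out <- out[out[[k]] %in% subset[[k]], , drop = FALSE]
      }
    }
    res <- associate(out, conf_level = config$conf_level)
  }
  paths <- list(results = file.path(out_dir, "results.csv"),
                report = file.path(out_dir, "report.txt"),
                log = file.path(out_dir, "run.log"))
  write.csv(as.data.frame(res), paths$results, row.names = FALSE)
  writeLines(format_association_report(res, subset), paths$report)
  write_run_log(paths$log, stage = "associate", config = unclass(config),
                seed = config$seed, extra = c(n_tests = nrow(res)))
  r <- invisible(paths)
  attr(r, "results") <- res
  r
}

# internal: human-readable report text
format_association_report <- function(res, subset = NULL) {
  lines <- c("Predictor association report",
             paste0("Tests run: ", nrow(res),
                    " (alpha = 0.05 two-tailed, no multiplicity adjustment)"))
  if (!is.null(subset)) {
    lines <- c(lines, paste0("Subgroup: ",
      paste(names(subset), unlist(subset), sep = " = ", collapse = ", ")))
  }
  lines <- c(lines, "")
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    l <- sprintf("%-24s %-20s", r$term, r$test)
    if (!is.na(r$statistic)) {
      l <- paste0(l, sprintf(" stat = %8.3f", r$statistic))
    }
    if (!is.na(r$p_value)) l <- paste0(l, sprintf("  p = %.4f", r$p_value))
    if (!is.na(r$effect_size)) {
      l <- paste0(l, sprintf("  ES = %.3f", r$effect_size))
      if (!is.na(r$effect_label)) l <- paste0(l, " (", r$effect_label, ")")
    }
    if (!is.na(r$odds_ratio)) {
      l <- paste0(l, sprintf("  OR = %.3f", r$odds_ratio))
      if (!is.na(r$conf_low)) {
        l <- paste0(l, sprintf(" [%.3f, %.3f]", r$conf_low, r$conf_high))
      }
    }
    lines <- c(lines, l)
  }
  lines
}

# internal: append-style structured run log
write_run_log <- function(path, stage, config, seed, extra = NULL) {
  lines <- c(
    paste0("stage: ", stage),
    paste0("package_version: ",
           as.character(utils::packageVersion("rehabspc"))),
    paste0("r_version: ", R.version.string),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("config_hash: ", rlang::hash(config))
  )
  if (!is.null(extra)) {
    lines <- c(lines, paste0(names(extra), ": ", unname(extra)))
  }
  writeLines(lines, path)
  invisible(path)
}
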
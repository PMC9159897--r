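#' Baseline centreline of an individual control chart
#'
#' The charts used here freeze the baseline at the first two observations of
#' a patient's series: the centreline is their arithmetic mean. This suits
#' early-rehabilitation monitoring, where a long pre-intervention baseline is
#' not available and the remaining sessions must all be evaluated against the
#' chart rather than absorbed into it.
#'
#' @param scores Numeric vector of repeated measurements in session order.
#' @return The centreline value (mean of the first two observations).
#' @examples
#' baseline_centreline(c(31, 38, 41, 44))
#' @export
baseline_centreline <- function(scores) {
  check_scores(scores, min_n = 2L)
  mean(scores[1:2])
}

#' Pooled within-pair sigma from cohort baseline pairs
#'
#' Estimates the common short-term standard deviation from the first two
#' observations of every patient in a cohort. Each pair \eqn{(x_1, x_2)}
#' contributes its within-pair variance \eqn{(x_1 - x_2)^2 / 2} (one degree of
#' freedom per pair), and the pooled estimate is
#' \deqn{\hat\sigma = \sqrt{\frac{1}{m}\sum_{i=1}^m (x_{1i} - x_{2i})^2 / 2}.}
#' Pooling across the cohort stabilises what would otherwise be a two-point
#' estimate of spread for each individual chart.
#'
#' @param x1,x2 Numeric vectors: the first and second baseline observation of
#'   each patient (recycled against each other must be equal length).
#' @return The pooled sigma (non-negative scalar).
#' @seealso [moving_range_sigma()] for the per-patient alternative.
#' @examples
#' pooled_sigma(c(0, 5, 3), c(2, 5, 7)) # sqrt((2 + 0 + 8) / 3)
#' @export
pooled_sigma <- function(x1, x2) {
  if (length(x1) == 0L || length(x2) == 0L) {
    abort("At least one baseline pair is required to pool sigma.",
          class = "rehabspc_error_empty")
  }
  if (length(x1) != length(x2)) {
    abort("`x1` and `x2` must have the same length.")
  }
  if (!all(is.finite(x1)) || !all(is.finite(x2))) {
    abort("Baseline observations must be finite.")
  }
  sqrt(mean((x1 - x2)^2 / 2))
}

#' Individual moving-range sigma from one baseline pair
#'
#' The classical individuals-chart estimate based on the average moving range:
#' with a single pair the moving range is \eqn{|x_1 - x_2|} and sigma is
#' \eqn{|x_1 - x_2| / d_2} with \eqn{d_2 = 1.128} for ranges of two.
#' Vectorised over pairs (one sigma per patient).
#'
#' @inheritParams pooled_sigma
#' @return Numeric vector of per-patient sigma estimates.
#' @export
moving_range_sigma <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    abort("`x1` and `x2` must have the same length.")
  }
  abs(x1 - x2) / 1.128
}

#' Construct an individual control chart
#'
#' Builds the chart object used by [detect_signals()]: a centreline, a sigma,
#' control limits at centreline \eqn{\pm 3\sigma} and warning limits at
#' centreline \eqn{\pm 2\sigma}.
#'
#' `control_chart()` takes the centreline and sigma directly;
#' `build_chart()` derives the centreline from a score series (mean of its
#' first two observations, see [baseline_centreline()]) and attaches the
#' supplied sigma.
#'
#' @param centreline Chart centreline, on the score scale.
#' @param sigma Non-negative process standard deviation on the score scale.
#' @param baseline_n Number of observations frozen as baseline (default 2).
#' @param sigma_strategy Tag recording how sigma was estimated
#'   (`"pooled"` or `"moving-range"`); informational.
#' @return An object of class `spc_chart` with fields `centreline`, `sigma`,
#'   `ucl`, `lcl` (3-sigma control limits), `uwl`, `lwl` (2-sigma warning
#'   limits), `baseline_n` and `sigma_strategy`.
#' @examples
#' control_chart(50, 4)
#' build_chart(c(31, 38, 41, 44), sigma = 2.5)
#' @export
control_chart <- function(centreline, sigma, baseline_n = 2L,
                          sigma_strategy = "pooled") {
  if (!is.numeric(centreline) || length(centreline) != 1L ||
      !is.finite(centreline)) {
    abort("`centreline` must be a single finite number.")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    abort("`sigma` must be a single non-negative number.",
          class = "rehabspc_error_sigma")
  }
  structure(
    list(
      centreline = centreline,
      sigma = sigma,
      ucl = centreline + 3 * sigma,
      lcl = centreline - 3 * sigma,
      uwl = centreline + 2 * sigma,
      lwl = centreline - 2 * sigma,
      baseline_n = as.integer(baseline_n),
      sigma_strategy = sigma_strategy
    ),
    class = "spc_chart"
  )
}

#' @rdname control_chart
#' @param scores Numeric vector of repeated measurements in session order.
#' @export
build_chart <- function(scores, sigma, sigma_strategy = "pooled") {
  control_chart(baseline_centreline(scores), sigma,
                sigma_strategy = sigma_strategy)
}

#' @export
print.spc_chart <- function(x, ...) {
  cat("Individual control chart (baseline n = ", x$baseline_n, ", sigma: ",
      x$sigma_strategy, ")\n", sep = "")
  cat(sprintf("  centreline %.3f, sigma %.3f\n", x$centreline, x$sigma))
  cat(sprintf("  control limits [%.3f, %.3f], warning limits [%.3f, %.3f]\n",
              x$lcl, x$ucl, x$lwl, x$uwl))
  invisible(x)
}

#' @export
tidy.spc_chart <- function(x, ...) {
  tibble(
    centreline = x$centreline, sigma = x$sigma,
    lcl = x$lcl, ucl = x$ucl, lwl = x$lwl, uwl = x$uwl,
    baseline_n = x$baseline_n, sigma_strategy = x$sigma_strategy
  )
}

# internal: validate a score series
check_scores <- function(scores, min_n = 2L, warn_short = FALSE,
                         patient = NULL) {
  if (!is.numeric(scores)) abort("`scores` must be numeric.")
  if (!all(is.finite(scores))) abort("`scores` must be finite.")
  if (length(scores) < min_n) {
    abort(
      sprintf("A series needs at least %d observations (got %d)%s.",
              min_n, length(scores),
              if (is.null(patient)) "" else paste0(" for patient ", patient)),
      class = "rehabspc_error_short_series"
    )
  }
  if (warn_short && length(scores) < 8L) {
    warn(
      sprintf(
        "Series %shas %d observations; the chart design assumes a minimum of 8 repeated measurements.",
        if (is.null(patient)) "" else paste0("for patient ", patient, " "),
        length(scores)
      ),
      class = "rehabspc_warning_short_series"
    )
  }
  invisible(scores)
}
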
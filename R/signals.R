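#' Detect run-rule signals on an individual chart
#'
#' Scans the post-baseline observations of a series against two rules:
#' \describe{
#'   \item{`single-point-3sd`}{one data point strictly outside a 3-sigma
#'     control limit;}
#'   \item{`two-of-three-2sd`}{at least 2 of 3 consecutive evaluated points at
#'     or beyond the same 2-sigma warning limit (the signal is attributed to
#'     the last index of the window).}
#' }
#' The first `baseline_n` observations (default two) define the chart and are
#' excluded from evaluation, so the earliest index that can signal is
#' `baseline_n + 1` and the earliest 2-of-3 window is made of the first three
#' evaluated points. A point exactly on the 3-sigma limit does not fire the
#' first rule ("outside"); a point exactly on the 2-sigma line does count for
#' the second ("at or beyond"). When sigma is zero the warning zones collapse
#' onto the centreline; a warning-zone point must then still lie strictly
#' beyond the centreline, so a perfectly constant series never signals.
#' Observations are windowed in observed order; gaps in the session labels
#' are treated as consecutive.
#'
#' With `direction = "improvement"` (the default) only above-centreline
#' signals are returned, since a higher score means better performance and the
#' outcome of interest is improvement. Use `"both"` to also flag
#' deterioration.
#'
#' @param scores Numeric vector of measurements in session order (including
#'   the baseline pair).
#' @param chart An [`spc_chart`][control_chart] built from this series'
#'   baseline.
#' @param direction `"improvement"` (above-centreline signals only) or
#'   `"both"`.
#' @return A tibble with one row per signal: `index` (position in the
#'   series), `rule`, `side` (`"above"`/`"below"`) and `score` at that index.
#'   Zero rows mean no signal.
#' @examples
#' ch <- control_chart(50, 4)
#' detect_signals(c(50, 50, 60, 51, 59), ch)
#' @export
detect_signals <- function(scores, chart,
                           direction = c("improvement", "both")) {
  direction <- match.arg(direction)
  stopifnot(inherits(chart, "spc_chart"))
  check_scores(scores, min_n = chart$baseline_n)
  n <- length(scores)
  eval_idx <- seq_len(n)[-seq_len(chart$baseline_n)]

  sig <- list()
  # rule i: single point strictly outside a 3-sigma limit
  for (i in eval_idx) {
    if (scores[i] > chart$ucl) {
      sig[[length(sig) + 1L]] <- list(index = i, rule = "single-point-3sd",
                                      side = "above")
    } else if (scores[i] < chart$lcl) {
      sig[[length(sig) + 1L]] <- list(index = i, rule = "single-point-3sd",
                                      side = "below")
    }
  }
  # rule ii: >= 2 of 3 consecutive evaluated points at or beyond the same
  # 2-sigma warning line; attributed to the window's last index
  if (length(eval_idx) >= 3L) {
    for (w in 3:length(eval_idx)) {
      win <- scores[eval_idx[(w - 2):w]]
      if (sum(win >= chart$uwl & win > chart$centreline) >= 2L) {
        sig[[length(sig) + 1L]] <- list(index = eval_idx[w],
                                        rule = "two-of-three-2sd",
                                        side = "above")
      }
      if (sum(win <= chart$lwl & win < chart$centreline) >= 2L) {
        sig[[length(sig) + 1L]] <- list(index = eval_idx[w],
                                        rule = "two-of-three-2sd",
                                        side = "below")
      }
    }
  }
  out <- if (length(sig) == 0L) {
    tibble(index = integer(), rule = character(), side = character(),
           score = double())
  } else {
    tibble(
      index = vapply(sig, function(s) as.integer(s$index), integer(1)),
      rule = vapply(sig, `[[`, character(1), "rule"),
      side = vapply(sig, `[[`, character(1), "side"),
      score = scores[vapply(sig, function(s) as.integer(s$index), integer(1))]
    )
  }
  if (direction == "improvement") out <- out[out$side == "above", ]
  arrange(out, .data$index, .data$rule)
}

#' Dichotomize a signal set into CHANGE / NO CHANGE
#'
#' A patient is labelled `CHANGE` when at least one improvement signal was
#' detected on their chart, and `NO_CHANGE` otherwise (fluctuation between
#' sessions without a rule violation).
#'
#' @param signals A signal tibble from [detect_signals()] run with
#'   `direction = "improvement"`.
#' @return A factor of length 1 with levels `CHANGE`, `NO_CHANGE`.
#' @export
classify_outcome <- function(signals) {
  stopifnot(is.data.frame(signals))
  factor(if (nrow(signals) > 0L) "CHANGE" else "NO_CHANGE",
         levels = c("CHANGE", "NO_CHANGE"))
}

#' Exact per-series improvement-signal probability under a stable process
#'
#' Computes, for an in-control series of i.i.d. Gaussian measurements, the
#' probability that at least one improvement (above-centreline) signal fires
#' over the evaluated part of the chart — the per-series false-alarm rate of
#' the rule set.
#'
#' With `baseline = "estimated"` the centreline is the mean of the first two
#' observations, so it carries an error \eqn{u \sim N(0, \sigma^2/2)};
#' conditional on \eqn{u} the evaluated points are independent, and the
#' no-signal probability is computed exactly by a Markov recursion over the
#' 2-of-3 run rule (tracking which of the last two points sat at or beyond
#' the warning line) and then integrated over \eqn{u}. With
#' `baseline = "known"` the chart parameters are taken as the true process
#' parameters (`u = 0`), in which case the per-point 3-sigma exceedance is
#' the textbook 0.00135.
#'
#' @param n_sessions Total series length including the two baseline
#'   observations.
#' @param sigma_ratio Ratio of the sigma used for the limits to the true
#'   process sigma (1 when the chart sigma is correct).
#' @param baseline `"estimated"` (centreline from the first two points) or
#'   `"known"`.
#' @return Probability in \[0, 1\] that the series raises at least one
#'   improvement signal.
#' @examples
#' signal_probability(9)
#' signal_probability(9, baseline = "known")
#' @export
signal_probability <- function(n_sessions, sigma_ratio = 1,
                               baseline = c("estimated", "known")) {
  baseline <- match.arg(baseline)
  stopifnot(n_sessions >= 3, sigma_ratio > 0)
  k <- n_sessions - 2L # evaluated points

  # P(no signal | centreline error u), in units of the true sigma
  no_signal_given_u <- function(u) {
    a3 <- pnorm(3 * sigma_ratio + u) # P(point below the 3-sigma limit)
    a2 <- pnorm(2 * sigma_ratio + u) # P(point below the 2-sigma line)
    pa <- 1 - a3                     # fires rule i (absorbing)
    pb <- a3 - a2                    # warning zone: counts for rule ii
    pc <- a2                         # below the warning line
    # state = probability mass on (B[i-1], B[i]) among surviving paths,
    # where B marks a point at or beyond the warning line
    st <- matrix(0, 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
    st["0", "0"] <- pc
    st["0", "1"] <- pb
    if (k == 1L) return(sum(st))
    st2 <- matrix(0, 2, 2, dimnames = dimnames(st))
    st2["0", "0"] <- st["0", "0"] * pc
    st2["0", "1"] <- st["0", "0"] * pb
    st2["1", "0"] <- st["0", "1"] * pc
    st2["1", "1"] <- st["0", "1"] * pb
    st <- st2
    if (k >= 3L) {
      for (i in 3:k) {
        nx <- matrix(0, 2, 2, dimnames = dimnames(st))
        # new point in warning zone: survives only if neither of the last
        # two was (otherwise 2 of 3 at/beyond the line)
        nx["0", "1"] <- st["0", "0"] * pb
        # new point below the line: survives unless both of the last two were
        nx["0", "0"] <- (st["0", "0"] + st["1", "0"]) * pc
        nx["1", "0"] <- st["0", "1"] * pc
        st <- nx
      }
    }
    sum(st)
  }

  if (baseline == "known") {
    return(1 - no_signal_given_u(0))
  }
  # integrate over u ~ N(0, 1/2) (baseline mean of two observations)
  f <- function(u) {
    vapply(u, no_signal_given_u, numeric(1)) * dnorm(u, sd = sqrt(0.5))
  }
  1 - stats::integrate(f, -8, 8, rel.tol = 1e-9)$value
}

#' @importFrom stats dnorm integrate
NULL
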
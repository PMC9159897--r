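#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on an r-by-c count table, without continuity
#' correction (the convention used throughout this package so that effect
#' sizes and odds ratios refer to the same statistic); Yates' correction for
#' 2-by-2 tables is available behind a flag.
#'
#' @param counts Matrix (or table / data frame of counts) with r >= 2 rows
#'   and c >= 2 columns of non-negative counts. A zero row or column margin
#'   is a degenerate table and an error.
#' @param correct Apply Yates' continuity correction (2x2 only). Default
#'   `FALSE`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `cramers_v`,
#'   `v_label` (effect-size band: weak <= 0.2 < moderate < 0.6 <= strong).
#' @examples
#' chi_square_test(rbind(c(27, 5), c(15, 12)))
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- check_counts(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Degenerate table: a row or column margin is zero.",
          class = "rehabspc_error_degenerate")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  n <- sum(counts)
  v <- cramers_v(unname(ct$statistic), n, nrow(counts), ncol(counts))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    n = n,
    cramers_v = v,
    v_label = label_cramers_v(v)
  )
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum, over all
#' tables with the observed margins, of hypergeometric probabilities no
#' larger than that of the observed table.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(rbind(c(27, 5), c(15, 12)))
#' @export
fisher_exact <- function(counts) {
  counts <- check_counts(counts)
  if (!all(dim(counts) == c(2L, 2L))) {
    abort("`counts` must be a 2x2 table.", class = "rehabspc_error_shape")
  }
  unname(fisher.test(counts)$p.value)
}

#' Cramer's V effect size
#'
#' \eqn{V = \sqrt{\chi^2 / (N \cdot \min(r - 1, c - 1))}}, the
#' chi-square-based association effect size on \[0, 1\].
#'
#' @param statistic Pearson chi-square statistic.
#' @param n Total count.
#' @param nrow,ncol Table dimensions.
#' @return V in \[0, 1\].
#' @examples
#' cramers_v(5.930, 59, 2, 2)
#' @export
cramers_v <- function(statistic, n, nrow, ncol) {
  stopifnot(n > 0, min(nrow - 1, ncol - 1) >= 1)
  sqrt(statistic / (n * min(nrow - 1, ncol - 1)))
}

#' Effect-size band labels
#'
#' Conventional interpretation bands. For Cramer's V: weak (<= 0.2),
#' moderate (0.2 to 0.6), strong (>= 0.6); a boundary value of 0.2 is weak
#' and 0.6 is strong. For eta squared: small (< 0.06), medium (0.06 to
#' 0.14), large (>= 0.14).
#'
#' @param v,eta_squared Effect-size values (vectorised).
#' @return Character vector of band labels.
#' @export
label_cramers_v <- function(v) {
  ifelse(v <= 0.2, "weak", ifelse(v < 0.6, "moderate", "strong"))
}

#' @rdname label_cramers_v
#' @export
label_eta_squared <- function(eta_squared) {
  ifelse(eta_squared < 0.06, "small",
         ifelse(eta_squared < 0.14, "medium", "large"))
}

#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with exposure on the rows and outcome on the columns, the
#' cross-product odds ratio of column 2 relative to column 1, comparing row 1
#' against row 2:
#' \eqn{OR = (n_{12}/n_{11}) / (n_{22}/n_{21})}. In the treatment-by-outcome
#' orientation used here (rows = treatment arms, first row the arm of
#' interest; columns = CHANGE, NO_CHANGE) this is the odds of NO CHANGE in
#' arm 1 over arm 2, and its reciprocal — also returned — is the familiar
#' "odds of CHANGE are x times higher in arm 1" headline.
#'
#' The 95 percent interval is Woolf's: \eqn{\exp(\ln OR \pm z_{0.975}
#' \sqrt{\sum 1/n_{ij}})}. It requires all four cells positive; with a zero
#' cell the interval is returned as `NA` unless `correction = TRUE` adds 0.5
#' to every cell (Haldane-Anscombe) for both the estimate and the interval.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @param conf_level Confidence level (default 0.95).
#' @param correction Add 0.5 to every cell when any cell is zero.
#' @return One-row tibble: `odds_ratio`, `conf_low`, `conf_high`,
#'   `reciprocal`, `conf_level`, `ci_available`.
#' @examples
#' odds_ratio(rbind(c(27, 5), c(15, 12)))
#' @export
odds_ratio <- function(counts, conf_level = 0.95, correction = FALSE) {
  counts <- check_counts(counts)
  if (!all(dim(counts) == c(2L, 2L))) {
    abort("`counts` must be a 2x2 table.", class = "rehabspc_error_shape")
  }
  x <- counts
  zero <- any(x == 0)
  if (zero && correction) x <- x + 0.5
  or <- (x[1, 2] / x[1, 1]) / (x[2, 2] / x[2, 1])
  if (any(x == 0)) {
    ci <- c(NA_real_, NA_real_)
    avail <- FALSE
  } else {
    z <- qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(sum(1 / x))
    ci <- exp(log(or) + c(-1, 1) * z * se)
    avail <- TRUE
  }
  tibble(
    odds_ratio = or, conf_low = ci[1], conf_high = ci[2],
    reciprocal = 1 / or, conf_level = conf_level, ci_available = avail
  )
}

#' Full association bundle for a contingency table
#'
#' Runs the chi-square test with Cramer's V, and for 2x2 tables adds
#' Fisher's exact p and the odds ratio with Woolf interval — the statistic
#' set reported for each exposure-by-outcome cross-tabulation in the
#' analysis this package implements.
#'
#' @inheritParams chi_square_test
#' @param conf_level Confidence level for the odds-ratio interval.
#' @return One-row tibble combining [chi_square_test()], [fisher_exact()]
#'   and [odds_ratio()] columns (the latter two `NA` for tables larger than
#'   2x2).
#' @examples
#' table_association(rbind(c(27, 5), c(15, 12)))
#' @export
table_association <- function(counts, correct = FALSE, conf_level = 0.95) {
  counts <- check_counts(counts)
  out <- chi_square_test(counts, correct = correct)
  if (all(dim(counts) == c(2L, 2L))) {
    out$fisher_p <- fisher_exact(counts)
    out <- dplyr::bind_cols(out, odds_ratio(counts, conf_level = conf_level))
  } else {
    out$fisher_p <- NA_real_
    out$odds_ratio <- NA_real_
    out$conf_low <- NA_real_
    out$conf_high <- NA_real_
    out$reciprocal <- NA_real_
    out$conf_level <- conf_level
    out$ci_available <- FALSE
  }
  out
}

#' One-way analysis of variance with eta squared
#'
#' Standard one-way decomposition with the grouping factor as the
#' explanatory variable (here typically the CHANGE / NO CHANGE label) and a
#' numeric score as the response. Returns the F statistic, degrees of
#' freedom, p-value and the effect size
#' \eqn{\eta^2 = SS_{between} / SS_{total}}.
#'
#' When every observation is identical across all groups the decomposition
#' is 0/0; the test is then reported as F = 0 with p = 1 (no evidence of any
#' group difference).
#'
#' @param data Data frame.
#' @param response Column with the numeric response (tidy-eval).
#' @param group Column with the grouping factor (tidy-eval).
#' @param conf_level If non-`NULL`, also return a noncentral-F confidence
#'   interval for eta squared at this level (`eta_conf_low`/`eta_conf_high`).
#' @return One-row tibble: `f_statistic`, `df_between`, `df_within`,
#'   `p_value`, `eta_squared`, `eta_label`, and optionally the interval.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' one_way_anova(d, y, g)
#' @export
one_way_anova <- function(data, response, group, conf_level = NULL) {
  y <- dplyr::pull(data, {{ response }})
  g <- factor(dplyr::pull(data, {{ group }}))
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  if (!any(tabulate(g) >= 2L)) {
    abort("At least one group needs two or more observations.")
  }
  ss_total <- sum((y - mean(y))^2)
  gm <- tapply(y, g, mean)
  ss_between <- sum(tabulate(g) * (gm - mean(y))^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  if (ss_total == 0) {
    f <- 0
    p <- 1
    eta <- 0
  } else {
    ss_within <- ss_total - ss_between
    f <- (ss_between / df1) / (ss_within / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
    eta <- ss_between / ss_total
  }
  out <- tibble(
    f_statistic = f, df_between = df1, df_within = df2, p_value = p,
    eta_squared = eta, eta_label = label_eta_squared(eta)
  )
  if (!is.null(conf_level)) {
    ci <- eta_squared_ci(f, df1, df2, conf_level = conf_level)
    out$eta_conf_low <- ci[1]
    out$eta_conf_high <- ci[2]
  }
  out
}

#' Noncentral-F confidence interval for eta squared
#'
#' Inverts the noncentral-F distribution: finds the noncentrality values
#' whose upper/lower tail probability at the observed F equals the interval
#' bounds, then maps noncentrality to eta squared via
#' \eqn{\eta^2 = \lambda / (\lambda + df_1 + df_2 + 1)}. Lower bound is
#' clamped at 0 when the observed F is small.
#'
#' @param f Observed F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @param conf_level Confidence level.
#' @return Length-2 numeric vector (lower, upper).
#' @export
eta_squared_ci <- function(f, df1, df2, conf_level = 0.95) {
  alpha <- 1 - conf_level
  ncp_for <- function(target) {
    # smallest/largest ncp with P(F' <= f | ncp) == target
    g <- function(l) pf(f, df1, df2, ncp = l) - target
    if (g(0) < 0) return(0)
    upper <- 1
    while (g(upper) > 0 && upper < 1e6) upper <- upper * 2
    stats::uniroot(g, c(0, upper), tol = 1e-8)$root
  }
  lo <- ncp_for(1 - alpha / 2) # ncp making observed f the upper alpha/2 point
  hi <- ncp_for(alpha / 2)
  lam_to_eta <- function(l) l / (l + df1 + df2 + 1)
  c(lam_to_eta(lo), lam_to_eta(hi))
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation between two numeric columns, with the p-value
#' from the t transform on n - 2 degrees of freedom. Used as the exploratory
#' screen relating each baseline cognitive test to the dichotomous outcome.
#'
#' @param data Data frame.
#' @param x,y Numeric columns (tidy-eval).
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @examples
#' pearson_correlation(data.frame(a = 1:4, b = c(2, 1, 4, 3)), a, b)
#' @export
pearson_correlation <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 3L) abort("Need at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Correlation undefined: a variable has zero variance.",
          class = "rehabspc_error_degenerate")
  }
  ct <- cor.test(xv, yv, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(xv))
}

#' Linear-probability regression of a binary outcome
#'
#' Ordinary least squares with the 0/1 outcome as the response — the
#' linear-probability formulation used when a dichotomized improvement label
#' is regressed on baseline cognitive predictors. Returns a fitted object
#' with [tidy()] (coefficients, SEs, t, p) and [glance()] (R-squared,
#' overall F with its degrees of freedom and p).
#'
#' @param data Data frame containing the response and predictors.
#' @param formula Model formula, e.g. `change ~ tmt4 + cwit4`; the response
#'   may be a 0/1 numeric or a two-level factor (first level coded 1).
#' @return An object of class `lp_model` wrapping the `lm` fit.
#' @examples
#' d <- data.frame(y = c(1, 0, 1, 1, 0, 1), x = c(3, 1, 4, 4, 2, 5))
#' glance(lp_regression(d, y ~ x))
#' @export
lp_regression <- function(data, formula) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(y) != 2L) abort("A factor response must have two levels.")
    data[[as.character(formula[[2]])]] <- as.numeric(y == levels(y)[1])
  } else if (!all(y %in% c(0, 1))) {
    abort("The response must be binary (0/1 or a two-level factor).")
  }
  fit <- lm(formula, data = data)
  if (any(is.na(coef(fit)))) {
    abort("Rank-deficient design: drop collinear predictors.",
          class = "rehabspc_error_rank")
  }
  structure(list(fit = fit, formula = formula), class = "lp_model")
}

#' @export
tidy.lp_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p_value = sm[, "Pr(>|t|)"]
  )
}

#' @export
glance.lp_model <- function(x, ...) {
  sm <- summary(x$fit)
  fs <- sm$fstatistic
  tibble(
    r_squared = sm$r.squared,
    f_statistic = unname(fs["value"]),
    df_model = unname(fs["numdf"]),
    df_residual = unname(fs["dendf"]),
    p_value = pf(fs["value"], fs["numdf"], fs["dendf"], lower.tail = FALSE),
    n = length(sm$residuals)
  )
}

#' @export
print.lp_model <- function(x, ...) {
  g <- glance(x)
  cat("Linear-probability model: ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  R^2 = %.3f, F(%d, %d) = %.3f, p = %.4f\n", g$r_squared,
              g$df_model, g$df_residual, g$f_statistic, g$p_value))
  invisible(x)
}

#' Linear-by-linear association (trend) statistic
#'
#' Mantel-Haenszel trend statistic for ordered categories:
#' \eqn{M^2 = (N - 1) r^2}, where r is the Pearson correlation between the
#' row and column scores of the N individual observations, referred to
#' chi-square with 1 df. Detects a monotone dose-response style association
#' that an omnibus chi-square can miss.
#'
#' @param counts r-by-c count matrix with ordered rows and columns.
#' @param row_scores,col_scores Numeric scores for the ordered categories
#'   (defaults 1..r and 1..c). Constant scores are degenerate and an error.
#' @return One-row tibble: `statistic`, `df` (= 1), `p_value`, `n`.
#' @examples
#' linear_by_linear(rbind(c(10, 0), c(0, 10)))
#' @export
linear_by_linear <- function(counts, row_scores = NULL, col_scores = NULL) {
  counts <- check_counts(counts)
  r <- nrow(counts)
  c <- ncol(counts)
  if (is.null(row_scores)) row_scores <- seq_len(r)
  if (is.null(col_scores)) col_scores <- seq_len(c)
  stopifnot(length(row_scores) == r, length(col_scores) == c)
  if (length(unique(row_scores)) < 2L || length(unique(col_scores)) < 2L) {
    abort("Degenerate scores: need at least two distinct values.",
          class = "rehabspc_error_degenerate")
  }
  n <- sum(counts)
  w <- as.vector(counts)
  rs <- rep(row_scores, times = c)
  cs <- rep(col_scores, each = r)
  mr <- sum(w * rs) / n
  mc <- sum(w * cs) / n
  sxy <- sum(w * (rs - mr) * (cs - mc))
  sxx <- sum(w * (rs - mr)^2)
  syy <- sum(w * (cs - mc)^2)
  if (sxx == 0 || syy == 0) {
    abort("Degenerate table: no score variation in rows or columns.",
          class = "rehabspc_error_degenerate")
  }
  rho <- sxy / sqrt(sxx * syy)
  stat <- (n - 1) * rho^2
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE), n = n)
}

# internal: coerce to a validated count matrix
check_counts <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (inherits(counts, "table")) counts <- unclass(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix or table.")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("Counts must be finite and non-negative.")
  }
  if (sum(counts) <= 0) {
    abort("Empty table: total count must be positive.",
          class = "rehabspc_error_degenerate")
  }
  counts
}
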
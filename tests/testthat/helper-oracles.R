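# Independent oracles used by the property and acceptance tests.
# Deliberately written as naive enumerations / closed forms, separate from
# the package's own code paths.

# exhaustive signal scan: every evaluated index for the 3-sigma rule, every
# 3-window of evaluated indices for the 2-of-3 rule
oracle_signals <- function(scores, centreline, sigma, baseline_n = 2L) {
  ucl <- centreline + 3 * sigma
  lcl <- centreline - 3 * sigma
  uwl <- centreline + 2 * sigma
  lwl <- centreline - 2 * sigma
  ev <- setdiff(seq_along(scores), seq_len(baseline_n))
  rows <- data.frame(index = integer(), rule = character(),
                     side = character(), stringsAsFactors = FALSE)
  for (i in ev) {
    if (scores[i] > ucl) {
      rows <- rbind(rows, data.frame(index = i, rule = "single-point-3sd",
                                     side = "above"))
    }
    if (scores[i] < lcl) {
      rows <- rbind(rows, data.frame(index = i, rule = "single-point-3sd",
                                     side = "below"))
    }
  }
  if (length(ev) >= 3L) {
    for (w in seq(3, length(ev))) {
      idx <- ev[(w - 2):w]
      if (sum(scores[idx] >= uwl & scores[idx] > centreline) >= 2) {
        rows <- rbind(rows, data.frame(index = ev[w],
                                       rule = "two-of-three-2sd",
                                       side = "above"))
      }
      if (sum(scores[idx] <= lwl & scores[idx] < centreline) >= 2) {
        rows <- rbind(rows, data.frame(index = ev[w],
                                       rule = "two-of-three-2sd",
                                       side = "below"))
      }
    }
  }
  rows[order(rows$index, rows$rule, rows$side), , drop = FALSE]
}

# closed-form Pearson chi-square for a 2x2 table
oracle_chisq_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# two-sided Fisher p by full enumeration over tables with fixed margins
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  amin <- max(0, r1 + c1 - n)
  amax <- min(r1, c1)
  prob <- function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }
  p_obs <- prob(m[1, 1])
  ps <- vapply(amin:amax, prob, numeric(1))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# OLS by normal equations
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# linear-by-linear statistic by expanding the table into N scored pairs
oracle_linear_by_linear <- function(m, row_scores = seq_len(nrow(m)),
                                    col_scores = seq_len(ncol(m))) {
  rs <- rep(rep(row_scores, times = ncol(m)), times = as.vector(m))
  cs <- rep(rep(col_scores, each = nrow(m)), times = as.vector(m))
  (length(rs) - 1) * cor(rs, cs)^2
}

# random 2x2 table with all margins positive
random_2x2 <- function(n_max = 200) {
  repeat {
    n <- sample(4:n_max, 1)
    m <- matrix(as.vector(rmultinom(1, n, prob = runif(4, 0.05, 1))), 2, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# random measurement series around a chart, with occasional level shifts
random_series_case <- function() {
  n <- sample(3:30, 1)
  centre <- runif(1, 20, 50)
  sigma <- runif(1, 0.5, 5)
  scores <- centre + rnorm(n, 0, sigma * runif(1, 0.5, 2))
  if (runif(1) < 0.5) {
    cp <- sample(3:n, 1)
    scores[cp:n] <- scores[cp:n] + sample(c(-1, 1), 1) * runif(1, 0, 5) * sigma
  }
  list(scores = scores, chart = control_chart(centre, sigma))
}

signals_as_df <- function(tbl) {
  d <- as.data.frame(tbl[, c("index", "rule", "side")])
  d <- d[order(d$index, d$rule, d$side), , drop = FALSE]
  rownames(d) <- NULL
  d
}
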
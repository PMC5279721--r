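#' Construct a comparison result
#'
#' Container for one statistical comparison between two groups: the metric,
#' group labels and sizes (after missing-value removal), per-group summaries
#' (medians or fractions), the test used, its tail, statistic and p-value.
#'
#' @param metric name of the compared metric.
#' @param groups character vector of two group labels.
#' @param n integer vector of two group sizes after missing-value removal.
#' @param summaries numeric vector of two group summaries (median or fraction).
#' @param test test name.
#' @param tail one of `"two-tailed"`, `"one-tailed-greater"`,
#'   `"one-tailed-less"`.
#' @param statistic test statistic.
#' @param p_value p-value in `[0, 1]`.
#' @param summary_type `"median"` or `"fraction"`.
#' @return an object of class `comparison_result`.
#' @export
comparison_result <- function(metric, groups, n, summaries, test, tail,
                              statistic, p_value, summary_type = "median") {
  stopifnot(length(groups) == 2, length(n) == 2, length(summaries) == 2)
  if (!is.finite(p_value) || p_value < 0 || p_value > 1) {
    stop("comparison_result: p-value must lie in [0, 1]")
  }
  structure(
    list(
      metric = as.character(metric),
      groups = as.character(groups),
      n = as.integer(n),
      summaries = as.numeric(summaries),
      summary_type = summary_type,
      test = test,
      tail = tail,
      statistic = as.numeric(statistic),
      p_value = as.numeric(p_value),
      stars = significance_stars(p_value)
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "%s: %s (n=%d, %s=%.4g) vs %s (n=%d, %s=%.4g)\n  %s, %s: statistic=%.4g, p=%.4g %s\n",
    x$metric, x$groups[1], x$n[1], x$summary_type, x$summaries[1],
    x$groups[2], x$n[2], x$summary_type, x$summaries[2],
    x$test, x$tail, x$statistic, x$p_value, x$stars
  ))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(
    metric = x$metric,
    group_a = x$groups[1], group_b = x$groups[2],
    n_a = x$n[1], n_b = x$n[2],
    summary_type = x$summary_type,
    summary_a = x$summaries[1], summary_b = x$summaries[2],
    test = x$test, tail = x$tail,
    statistic = x$statistic, p_value = x$p_value, stars = x$stars,
    stringsAsFactors = FALSE
  )
}

# Number of size-nx subsets of the doubled-rank multiset d with each possible
# rank sum: dynamic program over items, tracking (count chosen, sum). Ranks
# are doubled so average ranks from ties stay integral.
rank_sum_counts <- function(d, nx) {
  maxs <- sum(d)
  f <- matrix(0, nrow = nx + 1, ncol = maxs + 1)
  f[1, 1] <- 1
  for (v in d) {
    for (j in rev(seq_len(nx))) {
      if (v == 0) {
        f[j + 1, ] <- f[j + 1, ] + f[j, ]
      } else {
        idx <- (v + 1):(maxs + 1)
        f[j + 1, idx] <- f[j + 1, idx] + f[j, idx - v]
      }
    }
  }
  f[nx + 1, ]
}

#' Mann-Whitney rank-sum test with exact small-sample null
#'
#' Two-sample rank-sum (Mann-Whitney U) test. For small samples
#' (`n_x + n_y <= 20` by default, and always when `exact = TRUE`) the p-value
#' is computed from the exact permutation distribution of the rank sum,
#' handling ties via average ranks (the distribution is enumerated over the
#' observed rank multiset by dynamic programming). Larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' Tails are stated with respect to `x`: `"one-tailed-greater"` tests whether
#' `x` tends to exceed `y`.
#'
#' @param x,y numeric samples; missing values are dropped.
#' @param tail alternative hypothesis tail.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` chooses by total sample size.
#' @param metric,groups labels stored in the result.
#' @return a [comparison_result] with the U statistic of `x`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4), tail = "one-tailed-less")$p_value # 1/6
#' @export
rank_sum_test <- function(x, y,
                          tail = c("two-tailed", "one-tailed-greater", "one-tailed-less"),
                          exact = NULL, metric = "value", groups = c("x", "y")) {
  tail <- match.arg(tail)
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  if (length(x) == 0 || length(y) == 0) {
    stop("rank_sum_test: each sample must contain at least one non-missing value")
  }
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  u <- w - nx * (nx + 1) / 2
  if (is.null(exact)) exact <- n <= 20

  if (exact) {
    d <- as.integer(round(2 * r))
    cnt <- rank_sum_counts(d, nx)
    total <- choose(n, nx)
    w2 <- as.integer(round(2 * w))
    s <- seq_along(cnt) - 1L
    p_greater <- sum(cnt[s >= w2]) / total
    p_less <- sum(cnt[s <= w2]) / total
    test <- "Mann-Whitney (exact)"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p_greater <- 1
      p_less <- 1
    } else {
      sigma <- sqrt(sigma2)
      p_greater <- pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE)
      p_less <- pnorm((u - mu + 0.5) / sigma)
    }
    test <- "Mann-Whitney (normal approximation)"
  }
  p <- switch(tail,
    `one-tailed-greater` = p_greater,
    `one-tailed-less` = p_less,
    `two-tailed` = min(1, 2 * min(p_greater, p_less))
  )
  comparison_result(
    metric = metric, groups = groups, n = c(nx, ny),
    summaries = c(median(x), median(y)),
    test = test, tail = tail, statistic = u, p_value = p
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test of association in the 2x2 table
#' `rbind(c(a, b), c(c, d))`, computed by direct enumeration of the
#' hypergeometric distribution over the table support. The two-tailed
#' p-value follows the probability-mass rule: the sum of probabilities of
#' tables no more probable than the observed one. One-tailed alternatives
#' refer to the direction of the (1,1) cell.
#'
#' @param a,b,c,d nonnegative integer cell counts (rows are groups, columns
#'   are flag status).
#' @param tail alternative hypothesis tail.
#' @param metric,groups labels stored in the result.
#' @return a [comparison_result]; the statistic is the sample odds ratio and
#'   the summaries are the per-row fractions `a/(a+b)` and `c/(c+d)`.
#' @examples
#' fisher_2x2(3, 0, 0, 3)$p_value # 0.1
#' @export
fisher_2x2 <- function(a, b, c, d, tail = c("two-tailed", "one-tailed-greater", "one-tailed-less"),
                       metric = "flag", groups = c("row1", "row2")) {
  tail <- match.arg(tail)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_2x2: cell counts must be nonnegative integers")
  }
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  col2 <- b + d
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    stop("fisher_2x2: all row and column margins must be positive")
  }
  supp <- max(0, col1 - row2):min(col1, row1)
  probs <- dhyper(supp, row1, row2, col1)
  p_obs <- dhyper(a, row1, row2, col1)
  p_two <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  p_greater <- sum(probs[supp >= a])
  p_less <- sum(probs[supp <= a])
  p <- switch(tail,
    `two-tailed` = p_two,
    `one-tailed-greater` = min(1, p_greater),
    `one-tailed-less` = min(1, p_less)
  )
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  res <- comparison_result(
    metric = metric, groups = groups, n = c(row1, row2),
    summaries = c(a / row1, c / row2),
    test = "Fisher exact", tail = tail,
    statistic = or, p_value = p, summary_type = "fraction"
  )
  res$table <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  res
}

all_permutations <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_permutations(v[-i]), deparse.level = 0)
  }))
}

#' Spearman rank correlation
#'
#' Spearman's rho on paired observations (average ranks for ties). The
#' two-sided p-value is exact (full permutation enumeration) for `n < 10`
#' and uses the t approximation for `n >= 10`.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return a list with `rho`, `p`, `n` and `method`.
#' @examples
#' spearman_corr(1:4, c(2, 1, 4, 3))$rho # 0.6
#' @export
spearman_corr <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- as.numeric(x[keep])
  y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3) stop("spearman_corr: need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("spearman_corr: correlation undefined for constant input")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 10) {
    idx <- all_permutations(seq_len(n))
    ymat <- matrix(ry[t(idx)], nrow = n)
    rhos <- as.vector(cor(rx, ymat))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else if (abs(rho) >= 1) {
    p <- 0
    method <- "t approximation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Significance markers for p-values
#'
#' Star (or plus) banding used throughout figure annotations: three symbols
#' for `p < 1e-6`, two for `p < 1e-3`, one for `p < 0.05`, none otherwise.
#'
#' @param p p-value in `[0, 1]`.
#' @param symbol marker symbol, `"*"` for between-class comparisons or
#'   `"+"` for comparisons against the genome-wide background.
#' @return character marker.
#' @export
significance_stars <- function(p, symbol = "*") {
  stopifnot(length(p) == 1, is.finite(p), p >= 0, p <= 1)
  k <- if (p < 1e-6) 3L else if (p < 1e-3) 2L else if (p < 0.05) 1L else 0L
  strrep(symbol, k)
}
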
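# Statistical layer: Pearson chi-square cross-table test, Welch/pooled
# two-sample t-test, coefficient of variation, Cronbach's alpha. All four
# are written out from the textbook formulas so every reported statistic
# is recomputable from the counts that travel with it.

#' Chi-square test of an r x c cross table
#'
#' Pearson chi-square on a matrix of nonnegative counts, expected counts
#' from row/column margins. No continuity correction by default (codon
#' tallies are large); Yates' correction is available for 2x2 tables via
#' `correct = TRUE`. The minimum expected count is reported, and a warning
#' is emitted when it falls below 5, but the test still runs.
#'
#' @param table Numeric matrix of nonnegative counts, at least 2x2, with
#'   no all-zero row or column.
#' @param correct Apply Yates' continuity correction (2x2 only).
#' @return A `cross_table_result`: list with `statistic`, `df`, `p_value`,
#'   `table_dims`, `min_expected` and the `observed` table.
#' @export
chi_square_cross_table <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("cross table must be at least 2x2", call. = FALSE)
  }
  if (any(!is.finite(table)) || any(table < 0)) {
    stop("cross table must contain finite nonnegative counts", call. = FALSE)
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate cross table: all-zero row or column", call. = FALSE)
  }
  n <- sum(table)
  expected <- outer(rs, cs) / n
  dev <- abs(table - expected)
  if (correct) {
    if (!all(dim(table) == c(2L, 2L))) {
      stop("continuity correction only applies to 2x2 tables", call. = FALSE)
    }
    dev <- pmax(dev - 0.5, 0)
  }
  statistic <- sum(dev^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  min_expected <- min(expected)
  if (min_expected < 5) {
    warning(
      "minimum expected count ", signif(min_expected, 3),
      " is below 5; chi-square approximation may be poor",
      call. = FALSE
    )
  }
  structure(
    list(
      statistic = statistic,
      df = df,
      p_value = pchisq(statistic, df, lower.tail = FALSE),
      table_dims = dim(table),
      min_expected = min_expected,
      observed = table
    ),
    class = "cross_table_result"
  )
}

#' @export
print.cross_table_result <- function(x, ...) {
  cat(
    "<chi-square cross table> X2 =", signif(x$statistic, 6),
    ", df =", x$df, ", p =", signif(x$p_value, 4), "\n"
  )
  invisible(x)
}

#' Two-sample t-test
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` gives
#' the pooled-variance test). Two-sided. Identical constant groups give
#' t = 0, p = 1.
#'
#' @param xs,ys Numeric vectors, each with at least 2 values; `NA`s are
#'   dropped.
#' @param var_equal Use the pooled-variance form.
#' @return List with `t`, `df` and `p_value`.
#' @export
two_sample_t_test <- function(xs, ys, var_equal = FALSE) {
  xs <- xs[!is.na(xs)]
  ys <- ys[!is.na(ys)]
  nx <- length(xs)
  ny <- length(ys)
  if (nx < 2L || ny < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  mx <- mean(xs)
  my <- mean(ys)
  vx <- var(xs)
  vy <- var(ys)
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    a <- vx / nx
    b <- vy / ny
    se <- sqrt(a + b)
    df <- if (se == 0) nx + ny - 2 else {
      (a + b)^2 / (a^2 / (nx - 1) + b^2 / (ny - 1))
    }
  }
  if (se == 0) {
    tval <- if (mx == my) 0 else sign(mx - my) * Inf
  } else {
    tval <- (mx - my) / se
  }
  p <- if (is.infinite(tval)) 0 else 2 * pt(-abs(tval), df)
  list(t = tval, df = df, p_value = p)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector, at least 2 non-missing values.
#' @return The CV, or `NA_real_` when the mean is 0.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("need at least 2 values for a coefficient of variation",
      call. = FALSE
    )
  }
  m <- mean(values)
  if (m == 0) {
    return(NA_real_)
  }
  sd(values) / m
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of `k` items measured over the same
#' cases: `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`,
#' with sample (n - 1) variances.
#'
#' @param m Numeric matrix, items in rows, cases in columns; at least 2
#'   items and 2 cases.
#' @return Alpha, or `NA_real_` when the total-score variance is 0.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  k <- nrow(m)
  if (k < 2L || ncol(m) < 2L) {
    stop("need at least 2 items and 2 cases", call. = FALSE)
  }
  item_var <- apply(m, 1L, var)
  total_var <- var(colSums(m))
  if (total_var == 0) {
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(item_var) / total_var)
}
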
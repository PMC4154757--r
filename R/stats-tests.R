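test_result <- function(statistic, p_value, df, n_used, flag = NULL) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 n_used = n_used, flag = flag),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> stat = %.6g, p = %.4g, df = %s, n = %d%s\n",
              x$statistic, x$p_value, paste(signif(x$df, 6), collapse = "/"),
              x$n_used, if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' One-way fixed-effects ANOVA
#'
#' Classical F test of equal group means: F = (SSB/(k-1)) / (SSW/(n-k))
#' with p from the upper tail of F(k-1, n-k).  Degenerate inputs where
#' the between-group sum of squares vanishes return F = 0, p = 1; zero
#' within-group variance with separated means returns F = Inf, p = 0.
#'
#' @param values Numeric response.
#' @param groups Group labels (k >= 2 levels, each with >= 2 members).
#' @return A `test_result` with `df = c(k-1, n-k)`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (length(groups) != n) stopf("values and groups differ in length")
  if (k < 2L) stopf("ANOVA needs at least 2 groups")
  sizes <- tabulate(groups, k)
  if (any(sizes < 2L)) stopf("every group needs at least 2 members")
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(sizes * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssb <= 0) return(test_result(0, 1, c(df1, df2), n))
  if (ssw <= 0) return(test_result(Inf, 0, c(df1, df2), n))
  f <- (ssb / df1) / (ssw / df2)
  test_result(f, stats::pf(f, df1, df2, lower.tail = FALSE), c(df1, df2), n)
}

#' Welch's two-sample t test (unequal variances)
#'
#' Two-sided test with the Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @return A `test_result`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stopf("Welch test needs >= 2 values per sample")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy <= 0) {
    if (mean(x) == mean(y)) return(test_result(0, 1, Inf, nx + ny))
    stopf("both samples are degenerate (zero variance)")
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  test_result(t, p, df, nx + ny)
}

# mid-ranks (average ranks for ties)
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (tie-corrected); the
#' two-sided p-value uses t = rho * sqrt((n-2)/(1-rho^2)) on n-2
#' degrees of freedom.  The t approximation is used rather than exact
#' permutation because the intended cohort sizes (n near 88) make
#' enumeration unnecessary.
#'
#' @param x,y Numeric vectors, n >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y differ in length")
  if (n < 3L) stopf("Spearman needs n >= 3")
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stopf("rho undefined: a vector is completely tied")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q_(i) = min_(j >= i) p_(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stopf("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q
}
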
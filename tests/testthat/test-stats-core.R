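library(survival)

test_that("one-way ANOVA matches the hand-computed F oracle and aov", {
  r <- anova_oneway(c(1, 2, 3, 2, 3, 4, 6, 7, 8), rep(c("a", "b", "c"), each = 3))
  # hand evaluation: SSB = 42, SSW = 6, F = (42/2)/(6/6) = 21
  expect_equal(r$statistic, 21, tolerance = 1e-12)
  expect_equal(r$p_value, pf(21, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(r$p_value, 0.001953125, tolerance = 1e-10)

  # degenerate: identical values in every group
  r0 <- anova_oneway(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(anova_oneway(1:5, c("a", "a", "b", "b", "c")), "2 members")

  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    sizes <- sample(2:8, k, replace = TRUE)
    g <- factor(rep(seq_len(k), sizes))
    v <- rnorm(sum(sizes), mean = as.integer(g) * runif(1, 0, 2))
    mine <- anova_oneway(v, g)
    ref <- anova(aov(v ~ g))
    expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("two-group ANOVA equals the pooled-variance t test", {
  set.seed(102)
  for (i in 1:200) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    pa <- anova_oneway(c(x, y), rep(1:2, c(n1, n2)))$p_value
    pt <- t.test(x, y, var.equal = TRUE)$p.value
    expect_equal(pa, pt, tolerance = 1e-12)
  }
})

test_that("Welch's t matches the direct formula and t.test", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8, 10)
  r <- welch_t(x, y)
  # independent formula evaluation
  se2 <- var(x) / 4 + var(y) / 5
  t_oracle <- (mean(x) - mean(y)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 5)^2 / 4)
  expect_equal(r$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(r$df, df_oracle, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(abs(t_oracle), df_oracle, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_equal(welch_t(x, x)$p_value, 1)
  swapped <- welch_t(y, x)
  expect_equal(swapped$statistic, -r$statistic)
  expect_equal(swapped$p_value, r$p_value)

  set.seed(103)
  for (i in 1:100) {
    a <- rnorm(sample(2:12, 1)); b <- rnorm(sample(2:12, 1), sd = runif(1, .5, 2))
    mine <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Spearman rho is the Pearson correlation of mid-ranks", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)

  x <- c(1, 1, 2, 2, 3, 3); y <- c(0, 1, 0, 1, 1, 1)
  # hand mid-ranks: rx = (1.5,1.5,3.5,3.5,5.5,5.5), ry = (1.5,4.5,1.5,4.5,4.5,4.5)
  rx <- c(1.5, 1.5, 3.5, 3.5, 5.5, 5.5); ry <- c(1.5, 4.5, 1.5, 4.5, 4.5, 4.5)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  r <- spearman_cor(x, y)
  expect_equal(r$rho, rho_oracle, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "tied")

  set.seed(104)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    a <- sample(1:5, n, replace = TRUE)   # heavy ties
    b <- a + rnorm(n)
    mine <- spearman_cor(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }
})

test_that("BH step-up matches hand evaluation and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(105)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p order
  }
})

test_that("logrank matches the hand-tabulated risk-set oracle", {
  # A: deaths at 1,2,3; B: death at 4, censored at 5,6
  sd <- surv_data(c(1, 2, 3, 4, 5, 6),
                  c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  g <- rep(c("A", "B"), each = 3)
  # hand tabulation: O-E = 0.5+0.6+0.75 = 1.85, V = .25+.24+.1875 = 0.6775
  r <- logrank_test(g, sd)
  expect_equal(r$statistic, 1.85^2 / 0.6775, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(1.85^2 / 0.6775, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # label swap symmetry
  expect_equal(logrank_test(rev(g), surv_data(rev(sd$times), rev(sd$events)))$p_value,
               r$p_value)
  # identical groups
  sd2 <- surv_data(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, TRUE, FALSE), 2))
  expect_equal(logrank_test(rep(c("A", "B"), each = 3), sd2)$statistic, 0)
  # no events
  r0 <- logrank_test(g, surv_data(1:6, rep(FALSE, 6)))
  expect_equal(r0$p_value, 1)
  expect_equal(r0$flag, "no_events")
})

test_that("logrank agrees with survival::survdiff across random instances", {
  set.seed(106)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    n <- sample((3 * k):40, 1)
    g <- factor(sample(seq_len(k), n, replace = TRUE))
    while (nlevels(droplevels(g)) < k) g <- factor(sample(seq_len(k), n, replace = TRUE))
    sd <- random_surv(n)
    if (!any(sd$events)) next
    mine <- logrank_test(g, sd)
    ref <- survival::survdiff(survival::Surv(sd$times, sd$events) ~ g)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
    expect_equal(mine$df, k - 1)
  }
})

test_that("Kaplan-Meier matches hand product-limit and survfit", {
  # times 1, 2+, 3 with events at 1 and 3
  sd <- surv_data(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  km <- km_curve(sd)
  expect_equal(km$event_times, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0), tolerance = 1e-12)
  expect_equal(km_eval(km, c(0.5, 1, 2.5, 4)), c(1, 2 / 3, 2 / 3, 0))

  # no events: S = 1 everywhere
  expect_equal(length(km_curve(surv_data(1:4, rep(FALSE, 4)))$event_times), 0)

  set.seed(107)
  for (i in 1:100) {
    sd <- random_surv(sample(3:30, 1))
    km <- km_curve(sd)
    fit <- survival::survfit(survival::Surv(sd$times, sd$events) ~ 1)
    ref_t <- fit$time[fit$n.event > 0]
    ref_s <- fit$surv[fit$n.event > 0]
    expect_equal(km$event_times, ref_t)
    expect_equal(km$survival, ref_s, tolerance = 1e-12)
    # uncensored data: S(t) is the empirical survival fraction
    sd_all <- surv_data(sd$times, rep(TRUE, length(sd$times)))
    km2 <- km_curve(sd_all)
    for (t in km2$event_times) {
      expect_equal(km_eval(km2, t), mean(sd_all$times > t), tolerance = 1e-12)
    }
  }
})

test_that("binary Cox matches a grid-search partial-likelihood oracle", {
  pll <- function(b, x, t, e) {            # Breslow partial log-likelihood
    s <- 0
    for (tt in sort(unique(t[e]))) {
      ev <- e & t == tt
      s <- s + b * sum(x[ev]) - sum(ev) * log(sum(exp(b * x[t >= tt])))
    }
    s
  }
  set.seed(108)
  checked <- 0
  for (i in 1:200) {
    n <- sample(4:6, 1)
    x <- rbinom(n, 1, 0.5)
    if (sum(x) == 0 || sum(x) == n) next
    t <- round(rexp(n, 0.1), 2) + 0.5
    e <- runif(n) < 0.8
    if (sum(e & x == 1) == 0 || sum(e & x == 0) == 0) next  # monotone cases below
    fit <- cox_binary(x, surv_data(t, e))
    if (!fit$converged) next
    oracle <- optimize(function(b) -pll(b, x, t, e), c(-10, 10), tol = 1e-9)
    expect_lt(abs(fit$log_hr - oracle$minimum), 1e-6)
    ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = "breslow")
    expect_equal(fit$log_hr, unname(coef(ref)), tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 100)
})

test_that("binary Cox symmetry and monotone-likelihood handling", {
  set.seed(109)
  t <- round(rexp(20, 0.05), 1) + 1
  e <- runif(20) < 0.7
  x <- rbinom(20, 1, 0.5)
  f1 <- cox_binary(x, surv_data(t, e))
  f2 <- cox_binary(1 - x, surv_data(t, e))
  expect_equal(f1$log_hr, -f2$log_hr, tolerance = 1e-6)
  expect_equal(f1$hazard_ratio, 1 / f2$hazard_ratio, tolerance = 1e-6)
  # all events in group 1: monotone likelihood, flagged and bounded
  mono <- cox_binary(c(1, 1, 1, 0, 0, 0),
                     surv_data(c(1, 2, 3, 9, 9, 9),
                               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
  expect_false(mono$converged)
  expect_true(is.finite(mono$log_hr))
})

test_that("standardized PCA matches the correlation eigendecomposition", {
  set.seed(110)
  x <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), paste0("v", 1:3)))
  pc <- pca_standardized(x)
  ev <- eigen(cor(x), symmetric = TRUE)    # independent oracle
  npos <- sum(ev$values > 1e-10)
  expect_equal(pc$sdev[seq_len(npos)]^2 / sum(pc$sdev^2),
               ev$values[seq_len(npos)] / sum(ev$values[ev$values > -1e-10]),
               tolerance = 1e-8)
  for (j in seq_len(min(2, npos))) {
    expect_equal(abs(pc$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # reconstruction of the standardized data
  expect_equal(pc$scores %*% t(pc$loadings),
               scale(x), tolerance = 1e-8, ignore_attr = TRUE)
  # perfectly correlated pair
  y <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  expect_equal(pca_standardized(y)$variance_proportion[1], 1, tolerance = 1e-10)
  # proportions sum to 1, cumulative non-decreasing
  z <- matrix(rnorm(50), 10, 5)
  pz <- pca_standardized(z)
  expect_equal(sum(pz$variance_proportion), 1, tolerance = 1e-12)
  expect_true(all(diff(pz$cumulative_proportion) >= -1e-15))
  # agreement with prcomp up to component signs
  pp <- prcomp(z, scale. = TRUE)
  expect_equal(abs(pz$loadings), abs(unclass(pp$rotation)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # duplicating samples leaves loadings unchanged
  pd <- pca_standardized(rbind(z, z))
  expect_equal(abs(pd$loadings), abs(pz$loadings), tolerance = 1e-8)
  # zero-variance variable dropped with warning
  expect_warning(pv <- pca_standardized(cbind(z, const = 1)), "zero-variance")
  expect_equal(ncol(pv$loadings), ncol(pz$loadings))
})

test_that("complete-linkage clustering matches hclust and hand cases", {
  # two identical items merge at height 0
  d0 <- hclust_complete(rbind(a = c(1, 1), b = c(1, 1)))
  expect_equal(d0$height, 0)
  # collinear points 0, 1, 10: first merge (1,2) at 1, then at 10
  d1 <- hclust_complete(matrix(c(0, 1, 10), 3, 1))
  expect_equal(d1$height, c(1, 10))
  expect_equal(d1$merge[1, ], c(-1L, -2L))

  set.seed(111)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    mine <- hclust_complete(x)
    expect_true(all(diff(mine$height) >= -1e-12))
    ref <- hclust(dist(x), method = "complete")
    expect_equal(mine$height, ref$height, tolerance = 1e-10)
    # same partition at every merge height (labels may differ)
    for (k in c(2, min(4, n))) {
      a <- cutree(as_hclust(mine), k)
      b <- cutree(ref, k)
      expect_equal(length(unique(paste(a, b))), length(unique(b)))
    }
  }
})

test_that("row scaling centers, scales, and is affine-invariant", {
  x <- rbind(a = c(1, 2, 3), b = c(10, 40, 10))
  s <- row_scale(x)
  expect_equal(unname(rowMeans(s)), c(0, 0), tolerance = 1e-14)
  expect_equal(unname(apply(s, 1, sd)), c(1, 1), tolerance = 1e-14)
  expect_equal(row_scale(s), s, tolerance = 1e-12)
  expect_equal(unname(row_scale(rbind(3 * x[1, ] + 7))), unname(s[1, , drop = FALSE]),
               tolerance = 1e-12)
  expect_error(row_scale(rbind(c(1, 1, 1))), "zero-variance")
})
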
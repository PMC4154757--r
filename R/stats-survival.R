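#' k-sample logrank test
#'
#' Observed-minus-expected event counts over the risk sets at each
#' distinct event time, with the hypergeometric variance (tie
#' corrected); the statistic is the quadratic form of the first k-1
#' group contrasts against the estimated covariance, chi-squared on
#' k-1 degrees of freedom.  With two groups this reduces to
#' (O - E)^2 / V.  A dataset with no events returns p = 1 with flag
#' `"no_events"` so genome-wide scans never abort.
#'
#' @param groups Group labels, k >= 2 nonempty levels.
#' @param sd A [surv_data]; any censoring horizon must already have
#'   been applied by the caller.
#' @return A `test_result` (chi-squared statistic, df = k-1).
#' @export
logrank_test <- function(groups, sd) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  n <- length(sd$times)
  if (length(groups) != n) stopf("groups and survival data differ in length")
  if (k < 2L) stopf("logrank needs at least 2 nonempty groups")
  if (!any(sd$events)) return(test_result(0, 1, k - 1L, n, flag = "no_events"))

  dt <- sort(unique(sd$times[sd$events]))
  g <- as.integer(groups)
  oe <- numeric(k)
  V <- matrix(0, k, k)
  for (t in dt) {
    at_risk <- sd$times >= t
    nt <- sum(at_risk)
    d <- sum(sd$events & sd$times == t)
    ngt <- tabulate(g[at_risk], k)
    dgt <- tabulate(g[sd$events & sd$times == t], k)
    oe <- oe + dgt - d * ngt / nt
    if (nt > 1) {
      frac <- ngt / nt
      V <- V + d * (nt - d) / (nt - 1) * (diag(frac, k) - tcrossprod(frac))
    }
  }
  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  chi <- tryCatch(
    drop(crossprod(oe[idx], solve(Vsub, oe[idx]))),
    error = function(e) {
      # singular covariance: generalized inverse via eigendecomposition
      ev <- eigen(Vsub, symmetric = TRUE)
      pos <- ev$values > max(ev$values, 0) * 1e-12
      if (!any(pos)) return(0)
      vi <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
      drop(crossprod(oe[idx], vi %*% oe[idx]))
    })
  chi <- max(chi, 0)
  test_result(chi, stats::pchisq(chi, k - 1L, lower.tail = FALSE), k - 1L, n)
}

#' Kaplan-Meier product-limit curve
#'
#' @param sd A [surv_data].
#' @return A `km_curve`: distinct event times, the survival step values
#'   just after each event time, and the at-risk count at each.
#' @export
km_curve <- function(sd) {
  dt <- sort(unique(sd$times[sd$events]))
  s <- numeric(length(dt))
  at_risk <- integer(length(dt))
  cur <- 1
  for (i in seq_along(dt)) {
    t <- dt[i]
    nt <- sum(sd$times >= t)
    d <- sum(sd$events & sd$times == t)
    cur <- cur * (1 - d / nt)
    s[i] <- cur
    at_risk[i] <- nt
  }
  structure(list(event_times = dt, survival = s, at_risk = at_risk,
                 n = length(sd$times)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param curve A `km_curve`.
#' @param t Times (months).
#' @return S(t), right-continuous.
#' @export
km_eval <- function(curve, t) {
  vapply(t, function(ti) {
    j <- sum(curve$event_times <= ti)
    if (j == 0L) 1 else curve$survival[j]
  }, numeric(1))
}

#' Write a Kaplan-Meier curve as a TSV step table
#' @param curve A `km_curve`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_km_curve <- function(curve, path) {
  df <- data.frame(time = c(0, curve$event_times),
                   survival = c(1, curve$survival),
                   at_risk = c(curve$n, curve$at_risk))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cox proportional hazards fit for a binary covariate
#'
#' Maximizes the Breslow partial likelihood by Newton iteration.  With
#' a single 0/1 covariate the risk-set sums reduce to counts, so the
#' score and information have closed forms.  A monotone likelihood
#' (all events in one group while the other remains at risk) is flagged
#' `converged = FALSE` and the estimate is reported at a bounded value.
#'
#' @param group 0/1 (or logical) covariate per patient.
#' @param sd A [surv_data] with at least one event and both groups
#'   nonempty.
#' @param bound Absolute bound on the log hazard ratio used when the
#'   likelihood is monotone.
#' @return A `cox_result`: `log_hr`, `hazard_ratio`, `se`, `converged`.
#' @export
cox_binary <- function(group, sd, bound = 15) {
  x <- as.integer(as.logical(group))
  n <- length(x)
  if (length(sd$times) != n) stopf("group and survival data differ in length")
  if (!any(x == 1L) || !any(x == 0L)) stopf("both groups must be nonempty")
  if (!any(sd$events)) stopf("Cox fit needs at least one event")

  dt <- sort(unique(sd$times[sd$events]))
  d <- d1 <- n0 <- n1 <- numeric(length(dt))
  for (i in seq_along(dt)) {
    t <- dt[i]
    at_risk <- sd$times >= t
    ev <- sd$events & sd$times == t
    d[i] <- sum(ev); d1[i] <- sum(ev & x == 1L)
    n1[i] <- sum(at_risk & x == 1L); n0[i] <- sum(at_risk & x == 0L)
  }
  score <- function(b) sum(d1) - sum(d * n1 * exp(b) / (n0 + n1 * exp(b)))
  info <- function(b) {
    eb <- exp(b)
    sum(d * n0 * n1 * eb / (n0 + n1 * eb)^2)
  }
  b <- 0
  converged <- FALSE
  for (iter in seq_len(100L)) {
    u <- score(b); i2 <- info(b)
    if (i2 <= 0) break
    step <- u / i2
    step <- sign(step) * min(abs(step), 2)   # damped Newton
    b <- b + step
    if (abs(b) > bound) { b <- sign(b) * bound; break }
    if (abs(step) < 1e-10) { converged <- TRUE; break }
  }
  se <- {
    i2 <- info(b)
    if (i2 > 0) 1 / sqrt(i2) else NA_real_
  }
  structure(list(log_hr = b, hazard_ratio = exp(b), se = se,
                 converged = converged),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> log HR = %.4f, exp(B) = %.4g%s\n", x$log_hr,
              x$hazard_ratio, if (x$converged) "" else " [not converged]"))
  invisible(x)
}
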
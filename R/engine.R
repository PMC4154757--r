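# Internal vectorized engine for the permutation screen.
#
# The permutation null fixes expression (and therefore every probe's
# median split) and permutes clinical rows against the sample columns.
# Both component tests then reduce to matrix products of a fixed
# probes x samples matrix with small per-permutation indicator
# matrices, which lets R = 1e3..1e5 repetitions run through BLAS
# instead of per-probe loops.  The scalar stats_core implementations
# are the reference; tests pin the two paths together.

# survival indicator structures for the two-group logrank.
# times/events must already carry any censoring horizon.
surv_structs <- function(times, events) {
  dt <- sort(unique(times[events]))
  tmat <- length(dt)
  if (tmat == 0L) {
    return(list(n = length(times), n_times = 0L))
  }
  E0 <- outer(times, dt, `==`) * events      # n x T event indicators
  R0 <- outer(times, dt, `>=`) * 1           # n x T at-risk indicators
  d <- colSums(E0)
  nrisk <- colSums(R0)
  vfac <- d * (nrisk - d) / pmax(nrisk - 1, 1)
  list(n = length(times), n_times = tmat, E0 = E0, R0 = R0,
       d = d, nrisk = nrisk, vfac = vfac)
}

# two-group logrank p-values for every row of a binary matrix Z
# (probes x samples, 1 = high group), given precomputed structures.
# D1/N1 may be supplied when already computed by a batched product.
logrank_p_rows <- function(Z, ss, D1 = NULL, N1 = NULL) {
  nr <- nrow(Z %||% D1)
  if (ss$n_times == 0L) {
    return(list(p = rep(1, nr), chi = rep(0, nr), degenerate = rep(TRUE, nr)))
  }
  if (is.null(D1)) D1 <- Z %*% ss$E0
  if (is.null(N1)) N1 <- Z %*% ss$R0
  O <- rowSums(D1)
  E <- drop(N1 %*% (ss$d / ss$nrisk))
  A <- sweep(N1, 2L, ss$nrisk, `/`)
  V <- drop((A * (1 - A)) %*% ss$vfac)
  ok <- V > 1e-300
  chi <- ifelse(ok, (O - E)^2 / V, 0)
  p <- ifelse(ok, stats::pchisq(chi, 1L, lower.tail = FALSE), 1)
  list(p = p, chi = chi, degenerate = !ok)
}

# one-way ANOVA p-values for every row of X (probes x samples) over the
# groups encoded by indicator matrix G (samples x k; rows outside the
# tested cohort all-zero).  X2 = X*X may be precomputed.
anova_p_rows <- function(X, G, X2 = NULL, S1 = NULL, sq = NULL) {
  ngrp <- colSums(G)
  k <- ncol(G)
  ntot <- sum(ngrp)
  if (any(ngrp < 2L)) stopf("every ANOVA group needs at least 2 members")
  if (is.null(X2)) X2 <- X * X
  if (is.null(S1)) S1 <- X %*% G
  if (is.null(sq)) sq <- drop(X2 %*% rowSums(G))
  tot <- rowSums(S1)
  sst <- sq - tot^2 / ntot
  ssb <- drop((S1 * S1) %*% (1 / ngrp)) - tot^2 / ntot
  ssb <- pmax(ssb, 0)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- ntot - k
  f <- ifelse(ssw > 0, (ssb / df1) / (ssw / df2), ifelse(ssb > 0, Inf, 0))
  p <- ifelse(ssw > 0, stats::pf(f, df1, df2, lower.tail = FALSE),
              ifelse(ssb > 0, 0, 1))
  list(p = p, f = f)
}

# indicator matrix (n x k) of membership in the given subtype levels
subtype_indicator <- function(subtype, levels) {
  G <- vapply(levels, function(l) as.numeric(subtype == l),
              numeric(length(subtype)))
  dimnames(G) <- list(NULL, levels)
  G
}
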
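#' The integrated screening statistic p' = p1 x p2
#'
#' Product of the subtype-discrimination ANOVA p-value and the
#' median-split logrank p-value.  p' is a screening score, not a
#' p-value; it is calibrated against the permutation null of
#' [build_null] / [adjust_screening].
#'
#' @param p1,p2 p-values in \[0, 1\] (vectorized).
#' @return p1 * p2.
#' @export
integrated_statistic <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) {
    stopf("p1 and p2 must lie in [0, 1]")
  }
  p1 * p2
}

# align clinical rows to the expression sample columns and precompute
# everything the screen and its permutation null share
screen_context <- function(m_log, m_bin, clinical,
                           survival_cohort = c("all", "discrimination"),
                           horizon = 50,
                           subtypes = discrimination_subtypes()) {
  survival_cohort <- match.arg(survival_cohort)
  if (!identical(probe_ids(m_log), probe_ids(m_bin))) {
    stopf("log and binarized matrices must share the same probes")
  }
  if (!identical(sample_ids(m_log), sample_ids(m_bin))) {
    stopf("log and binarized matrices must share the same samples")
  }
  idx <- match(sample_ids(m_log), clinical$patient_id)
  if (anyNA(idx)) stopf("clinical table does not cover all samples")
  clin <- clinical[idx, ]
  present <- intersect(subtypes, unique(clin$subtype))
  if (length(present) < 2L) stopf("fewer than 2 discrimination subtypes present")
  G0 <- subtype_indicator(clin$subtype, present)
  surv_idx <- if (survival_cohort == "all") seq_len(nrow(clin)) else
    which(clin$subtype %in% present)
  sd <- apply_censor_horizon(
    surv_data(clin$survival_time[surv_idx], clin$death_event[surv_idx]),
    horizon)
  X <- m_log$signals
  Z <- m_bin$signals[, surv_idx, drop = FALSE]
  zr <- rowSums(Z)
  degenerate <- zr == 0 | zr == ncol(Z)
  list(X = X, X2 = X * X, Z = Z, G0 = G0, clin = clin,
       surv_idx = surv_idx, sd = sd, ss = surv_structs(sd$times, sd$events),
       degenerate = degenerate, survival_cohort = survival_cohort,
       horizon = horizon, subtypes = present)
}

# observed per-probe p1, p2
screen_stats <- function(ctx) {
  a <- anova_p_rows(ctx$X, ctx$G0, X2 = ctx$X2)
  lr <- logrank_p_rows(ctx$Z, ctx$ss)
  list(p1 = a$p, p2 = lr$p, degenerate = ctx$degenerate | lr$degenerate)
}

# minimum p' over valid probes for one explicit permutation sig
# (sample j is assigned clinical row sig[j]).  Generic path used for
# the "discrimination" survival cohort, where the logrank cohort is
# re-derived from the permuted subtype labels each repetition.
perm_min_pprime <- function(ctx, sig, m_bin_full) {
  a <- anova_p_rows(ctx$X, ctx$G0[sig, , drop = FALSE], X2 = ctx$X2)
  subtype_p <- ctx$clin$subtype[sig]
  cols <- if (ctx$survival_cohort == "all") seq_along(sig) else
    which(subtype_p %in% ctx$subtypes)
  sd <- apply_censor_horizon(
    surv_data(ctx$clin$survival_time[sig][cols],
              ctx$clin$death_event[sig][cols]), ctx$horizon)
  Z <- m_bin_full[, cols, drop = FALSE]
  lr <- logrank_p_rows(Z, surv_structs(sd$times, sd$events))
  zr <- rowSums(Z)
  valid <- !(ctx$degenerate | zr == 0 | zr == ncol(Z))
  min(a$p[valid] * lr$p[valid])
}

#' Screen every probe with the integrated statistic
#'
#' Per probe, p1 is the one-way ANOVA p-value of the log2 signals over
#' the discrimination subtypes (UPS, MFS, MLS, SS by default), p2 is
#' the two-group logrank p-value of the median split over the survival
#' cohort with the censoring horizon applied, and the integrated
#' statistic is p' = p1 x p2.  Probes whose median split puts every
#' patient in one group are flagged `degenerate` and excluded from
#' ranking and from the null minima.
#'
#' @param m_log Log2-transformed [expr_mat].
#' @param m_bin Median-binarized [expr_mat] (same probes and samples).
#' @param clinical Clinical table covering all samples.
#' @param survival_cohort `"all"` (default): the logrank uses all
#'   patients; `"discrimination"`: restrict to the four discrimination
#'   subtypes.
#' @param horizon Censoring horizon in months (default 50).
#' @return A `screening_result` data.frame: `probe_id`, `p_anova`,
#'   `p_logrank`, `p_integrated`, `degenerate`.
#' @export
screen_probes <- function(m_log, m_bin, clinical,
                          survival_cohort = c("all", "discrimination"),
                          horizon = 50) {
  ctx <- screen_context(m_log, m_bin, clinical, survival_cohort, horizon)
  st <- screen_stats(ctx)
  out <- data.frame(probe_id = probe_ids(m_log), p_anova = st$p1,
                    p_logrank = st$p2,
                    p_integrated = integrated_statistic(st$p1, st$p2),
                    degenerate = st$degenerate, stringsAsFactors = FALSE)
  out$p_anova[out$degenerate] <- NA_real_
  out$p_logrank[out$degenerate] <- NA_real_
  out$p_integrated[out$degenerate] <- NA_real_
  class(out) <- c("screening_result", "data.frame")
  attr(out, "survival_cohort") <- ctx$survival_cohort
  attr(out, "horizon") <- horizon
  out
}

#' Build the permutation null of per-repetition minimum p'
#'
#' For each repetition the clinical rows (subtype, survival, event,
#' grade, metastasis — the whole record) are permuted jointly against
#' the fixed expression columns; the discrimination subset is re-derived
#' from the permuted labels; p' is recomputed for every probe and its
#' minimum recorded.  Median splits are fixed by the expression data
#' and are not recomputed inside repetitions.
#'
#' @inheritParams screen_probes
#' @param R Number of repetitions.
#' @param seed RNG seed (recorded in the result).
#' @param permutations Optional list of explicit permutations of the
#'   clinical rows (each an integer vector); overrides `R` and the RNG.
#'   `seq_len(n)` is the identity permutation.
#' @param chunk Permutations per BLAS batch (performance only).
#' @return A `perm_null`: `null_min` (length R), `R`, `seed`.
#' @export
build_null <- function(m_log, m_bin, clinical, R = 1000L, seed = 1L,
                       survival_cohort = c("all", "discrimination"),
                       horizon = 50, permutations = NULL, chunk = 100L) {
  ctx <- screen_context(m_log, m_bin, clinical, survival_cohort, horizon)
  n <- nrow(ctx$clin)
  if (is.null(permutations)) {
    if (R < 1L) stopf("R must be >= 1")
    set.seed(seed)
    permutations <- lapply(seq_len(R), function(i) sample.int(n))
  }
  R <- length(permutations)
  null_min <- numeric(R)
  valid <- !ctx$degenerate
  if (!any(valid)) stopf("every probe is degenerate; null undefined")
  if (ctx$survival_cohort != "all") {
    # the logrank cohort depends on the permuted labels; generic path
    for (r in seq_len(R)) {
      null_min[r] <- perm_min_pprime(ctx, permutations[[r]], m_bin$signals)
    }
    return(structure(list(null_min = null_min, R = R, seed = seed),
                     class = "perm_null"))
  }
  # fast path: survival cohort is all samples, so permuting clinical
  # rows only row-permutes the fixed event/at-risk indicator matrices
  ss <- ctx$ss
  kG <- ncol(ctx$G0)
  tS <- if (ss$n_times > 0L) ss$n_times else 0L
  g0 <- rowSums(ctx$G0)
  for (start in seq(1L, R, by = chunk)) {
    idx <- start:min(start + chunk - 1L, R)
    B <- length(idx)
    Gbig <- matrix(0, n, kG * B)
    EObig <- if (tS > 0L) matrix(0, n, tS * B)
    RObig <- if (tS > 0L) matrix(0, n, tS * B)
    gbig <- matrix(0, n, B)
    for (b in seq_len(B)) {
      sig <- permutations[[idx[b]]]
      Gbig[, (b - 1L) * kG + seq_len(kG)] <- ctx$G0[sig, , drop = FALSE]
      gbig[, b] <- g0[sig]
      if (tS > 0L) {
        EObig[, (b - 1L) * tS + seq_len(tS)] <- ss$E0[sig, , drop = FALSE]
        RObig[, (b - 1L) * tS + seq_len(tS)] <- ss$R0[sig, , drop = FALSE]
      }
    }
    S1big <- ctx$X %*% Gbig
    sqbig <- ctx$X2 %*% gbig
    D1big <- if (tS > 0L) ctx$Z %*% EObig
    N1big <- if (tS > 0L) ctx$Z %*% RObig
    for (b in seq_len(B)) {
      S1 <- S1big[, (b - 1L) * kG + seq_len(kG), drop = FALSE]
      a <- anova_p_rows(ctx$X, ctx$G0, X2 = ctx$X2, S1 = S1,
                        sq = sqbig[, b])
      if (tS > 0L) {
        lr <- logrank_p_rows(NULL, ss,
                             D1 = D1big[, (b - 1L) * tS + seq_len(tS),
                                        drop = FALSE],
                             N1 = N1big[, (b - 1L) * tS + seq_len(tS),
                                        drop = FALSE])
        p2 <- lr$p
      } else {
        p2 <- rep(1, nrow(ctx$Z))
      }
      null_min[idx[b]] <- min(a$p[valid] * p2[valid])
    }
  }
  structure(list(null_min = null_min, R = R, seed = seed),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null> R = %d, min = %.3g, median = %.3g\n", x$R,
              min(x$null_min), stats::median(x$null_min)))
  invisible(x)
}

#' Convert observed p' values to permutation-adjusted p-values
#'
#' p_adjusted is the exceedance fraction of the observed p' in the
#' null distribution of per-repetition minima: #\{r : null_min_r <=
#' p'\} / R.  When the count is zero the probe's adjusted p is below
#' the simulation's resolution; it is reported as 1/R with
#' `reported_lt = TRUE` (displayed as "<1/R", e.g. "<1.00E-05" at
#' R = 100,000).
#'
#' @param sr A `screening_result` from [screen_probes].
#' @param null A `perm_null` from [build_null].
#' @return The `screening_result` with `p_adjusted`, `reported_lt`,
#'   and `p_adjusted_display` columns added.
#' @export
adjust_screening <- function(sr, null) {
  if (!length(null$null_min)) stopf("null distribution is empty")
  srt <- sort(null$null_min)
  counts <- findInterval(sr$p_integrated, srt)
  counts[is.na(sr$p_integrated)] <- NA_integer_
  lt <- !is.na(counts) & counts == 0L
  p_adj <- counts / null$R
  p_adj[lt] <- 1 / null$R
  sr$p_adjusted <- p_adj
  sr$reported_lt <- lt
  sr$p_adjusted_display <- ifelse(is.na(p_adj), NA_character_,
                                  paste0(ifelse(lt, "<", ""),
                                         format_sci(p_adj)))
  attr(sr, "R") <- null$R
  sr
}

#' Write a screening table as TSV
#'
#' Columns follow the usual screening-report layout: probe, optional
#' accession and gene symbol from an annotation, p1, p2, p', adjusted p
#' (with the "<1/R" display convention).
#'
#' @param sr An adjusted `screening_result`.
#' @param path Output path.
#' @param ann Optional annotation for accession/symbol columns.
#' @return Invisibly, the path.
#' @export
write_screening <- function(sr, path, ann = NULL) {
  out <- as.data.frame(sr)
  if (!is.null(ann)) {
    i <- match(out$probe_id, ann$probe_id)
    out <- cbind(out[, "probe_id", drop = FALSE],
                 accession = ann$accession[i],
                 gene_symbol = ann$gene_symbol[i],
                 out[, setdiff(names(out), "probe_id")])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percentile threshold-scan survival screen within one cohort
#'
#' For each probe, the expression signal is split at each percentile
#' threshold (30th..80th by default); the best (smallest) logrank
#' p-value over thresholds is taken, and the multiple testing over
#' thresholds x probes is corrected by a permutation null: each
#' repetition permutes the cohort's clinical rows and records the
#' minimum p over the whole threshold x probe grid (the joint minimum;
#' `scope = "per_probe"` restricts each probe's null to its own
#' thresholds).
#'
#' @param m An [expr_mat] restricted to the cohort of interest (linear
#'   or log signals; splits are quantile-based so either works).
#' @param sd A [surv_data] for the same cohort (horizon already
#'   applied, or supply `horizon`).
#' @param thresholds_pct Percentile thresholds to scan.
#' @param R Permutation repetitions.
#' @param seed RNG seed.
#' @param horizon Optional censoring horizon to apply to `sd`.
#' @param scope `"joint"` (default) or `"per_probe"` null minima.
#' @return A `threshold_scan` data.frame: `probe_id`,
#'   `best_threshold_pct`, `p_best`, `p_adjusted`, `reported_lt`, plus
#'   attributes `per_threshold` (full p grid) and `null_min`.
#' @export
threshold_scan <- function(m, sd, thresholds_pct = c(30, 40, 50, 60, 70, 80),
                           R = 1000L, seed = 1L, horizon = NULL,
                           scope = c("joint", "per_probe")) {
  scope <- match.arg(scope)
  if (!is.null(horizon)) sd <- apply_censor_horizon(sd, horizon)
  n <- ncol(m$signals)
  if (length(sd$times) != n) stopf("cohort and survival data differ in size")
  if (n < 4L) stopf("threshold scan needs at least 4 patients")

  # split grid: one binary row per probe x threshold
  probes <- probe_ids(m)
  grid <- expand.grid(probe = seq_along(probes), pct = thresholds_pct,
                      KEEP.OUT.ATTRS = FALSE)
  Z <- matrix(0, nrow(grid), n)
  keep <- logical(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    x <- m$signals[grid$probe[r], ]
    thr <- stats::quantile(x, grid$pct[r] / 100, type = 7L, names = FALSE)
    z <- as.numeric(x > thr)
    keep[r] <- any(z == 1) && any(z == 0)
    Z[r, ] <- z
  }
  if (!any(keep)) stopf("every threshold split is degenerate")
  ss <- surv_structs(sd$times, sd$events)
  obs <- logrank_p_rows(Z[keep, , drop = FALSE], ss)
  pgrid <- rep(NA_real_, nrow(grid))
  pgrid[keep] <- obs$p

  per_thr <- matrix(pgrid, nrow = length(probes),
                    dimnames = list(probes, paste0("pct", thresholds_pct)))
  p_best <- apply(per_thr, 1L, function(v) if (all(is.na(v))) NA else
    min(v, na.rm = TRUE))
  best_pct <- apply(per_thr, 1L, function(v) if (all(is.na(v))) NA else
    thresholds_pct[which.min(v)])

  # permutation null over the same fixed split grid
  set.seed(seed)
  Zk <- Z[keep, , drop = FALSE]
  probe_of_row <- grid$probe[keep]
  null_min <- if (scope == "joint") numeric(R) else
    matrix(NA_real_, R, length(probes))
  for (r in seq_len(R)) {
    sig <- sample.int(n)
    ssp <- ss
    if (ss$n_times > 0L) {
      ssp$E0 <- ss$E0[sig, , drop = FALSE]
      ssp$R0 <- ss$R0[sig, , drop = FALSE]
    }
    pr <- logrank_p_rows(Zk, ssp)$p
    if (scope == "joint") {
      null_min[r] <- min(pr)
    } else {
      null_min[r, ] <- vapply(seq_along(probes), function(i) {
        v <- pr[probe_of_row == i]
        if (length(v)) min(v) else NA_real_
      }, numeric(1))
    }
  }
  adj <- rep(NA_real_, length(probes))
  lt <- rep(FALSE, length(probes))
  for (i in seq_along(probes)) {
    if (is.na(p_best[i])) next
    nm <- if (scope == "joint") null_min else null_min[, i]
    cnt <- sum(nm <= p_best[i], na.rm = TRUE)
    lt[i] <- cnt == 0L
    adj[i] <- max(cnt, 1L) / R
  }
  out <- data.frame(probe_id = probes, best_threshold_pct = best_pct,
                    p_best = p_best, p_adjusted = adj, reported_lt = lt,
                    stringsAsFactors = FALSE)
  class(out) <- c("threshold_scan", "data.frame")
  attr(out, "per_threshold") <- per_thr
  attr(out, "null_min") <- null_min
  attr(out, "R") <- R
  attr(out, "seed") <- seed
  out
}
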
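#' Spearman correlation of each probe with grade and metastasis
#'
#' Per probe: Spearman rank correlation (mid-ranks, t-approximation
#' p-value) of the expression signal against the histological grade
#' (1-3) and against metastasis coded 0/1.  Constant probes, or a
#' clinical covariate with a single value, are flagged instead of
#' raising an error.
#'
#' @param m An [expr_mat] (log or linear signals; ranks are invariant
#'   to monotone transforms).
#' @param clinical Clinical table covering all samples.
#' @return A data.frame: `probe_id`, `rho_grade`, `p_grade`,
#'   `rho_metastasis`, `p_metastasis`, `flag`.
#' @export
correlate_clinical <- function(m, clinical) {
  idx <- match(sample_ids(m), clinical$patient_id)
  if (anyNA(idx)) stopf("clinical table does not cover all samples")
  grade <- clinical$grade[idx]
  meta <- as.numeric(clinical$metastasis[idx])
  one <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA, NA))
    s <- spearman_cor(x, y)
    c(s$rho, s$p_value)
  }
  res <- t(apply(m$signals, 1L, function(x) c(one(x, grade), one(x, meta))))
  out <- data.frame(probe_id = probe_ids(m), rho_grade = res[, 1L],
                    p_grade = res[, 2L], rho_metastasis = res[, 3L],
                    p_metastasis = res[, 4L], stringsAsFactors = FALSE)
  out$flag <- ifelse(is.na(out$rho_grade) | is.na(out$rho_metastasis),
                     "undefined", "")
  out
}

#' Pairwise Welch tests between subtypes with per-pair BH q-values
#'
#' For each subtype pair, Welch's t test is applied to every probe's
#' log2 signals and the Benjamini-Hochberg step-up is applied across
#' the probes within that pair (each comparison column is its own
#' multiple-testing family).
#'
#' @param m_log Log2-transformed [expr_mat].
#' @param clinical Clinical table covering all samples.
#' @param pairs List of 2-vectors of subtype codes; default the three
#'   comparisons against UPS.
#' @param alpha Significance level on q (default 0.05).
#' @return A `pairwise_table` data.frame in long form: `probe_id`,
#'   `comparison`, `p_welch`, `q_bh`, `significant`.
#' @export
pairwise_compare <- function(m_log, clinical,
                             pairs = list(c("UPS", "MFS"), c("UPS", "SS"),
                                          c("UPS", "MLS")),
                             alpha = 0.05) {
  idx <- match(sample_ids(m_log), clinical$patient_id)
  if (anyNA(idx)) stopf("clinical table does not cover all samples")
  subtype <- clinical$subtype[idx]
  out <- do.call(rbind, lapply(pairs, function(pr) {
    a <- which(subtype == pr[1L]); b <- which(subtype == pr[2L])
    if (!length(a) || !length(b)) {
      stopf("subtype %s absent from cohort", pr[!c(length(a), length(b))][1L])
    }
    p <- apply(m_log$signals, 1L, function(x) welch_t(x[a], x[b])$p_value)
    data.frame(probe_id = probe_ids(m_log),
               comparison = paste(pr, collapse = "-"),
               p_welch = p, q_bh = bh_adjust(p), stringsAsFactors = FALSE)
  }))
  out$significant <- out$q_bh < alpha
  rownames(out) <- NULL
  class(out) <- c("pairwise_table", "data.frame")
  out
}

#' Classify probes into Venn regions over the three comparisons
#'
#' Each probe is assigned to one of the 2^3 - 1 regions of the Venn
#' diagram of its significant comparisons (or `"none"`); the overlap
#' flag marks probes whose gene symbol appears in a reference
#' signature list.
#'
#' @param pt A `pairwise_table` covering all three comparisons.
#' @param reference_list Character vector of gene symbols (e.g. the
#'   shipped prognostic-signature overlap fixture).
#' @param ann Optional annotation mapping probe ids to gene symbols;
#'   without it the probe ids themselves are matched.
#' @return A data.frame: `probe_id`, `region` (comparison names joined
#'   by "+", or "none"), `in_reference`.
#' @export
venn_classify <- function(pt, reference_list = character(), ann = NULL) {
  comps <- sort(unique(pt$comparison))
  wide <- lapply(comps, function(cc) {
    sub <- pt[pt$comparison == cc, ]
    stats::setNames(sub$significant, sub$probe_id)
  })
  probes <- unique(pt$probe_id)
  sig <- vapply(wide, function(w) as.logical(w[probes]), logical(length(probes)))
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1L)
  region <- apply(sig, 1L, function(s) {
    if (!any(s, na.rm = TRUE)) "none" else
      paste(comps[which(s)], collapse = "+")
  })
  symbols <- if (is.null(ann)) probes else
    ann$gene_symbol[match(probes, ann$probe_id)]
  in_ref <- vapply(symbols, function(s) {
    any(strsplit(s %||% "", "/", fixed = TRUE)[[1L]] %in% reference_list)
  }, logical(1))
  data.frame(probe_id = probes, region = region, in_reference = in_ref,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a heatmap-ready scaled matrix with probe and sample dendrograms
#'
#' Rows (probes) are centered and scaled to unit variance; probes and
#' samples are clustered by complete linkage on Euclidean distances.
#' Zero-variance probes are dropped with a warning.  Rendering is left
#' to any plotting layer.
#'
#' @param m_log Log2-transformed [expr_mat].
#' @param probes Probe ids to include (default all).
#' @param clinical Optional clinical table used to attach subtype
#'   labels to samples.
#' @return List: `scaled` (probes x samples), `probe_dendro`,
#'   `sample_dendro` (class `dendro`), `probe_order`, `sample_order`,
#'   `subtype` (per ordered sample, if clinical given).
#' @export
heatmap_export <- function(m_log, probes = probe_ids(m_log),
                           clinical = NULL) {
  x <- m_log$signals[probes, , drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L) stopf("need at least 2 probes and 2 samples")
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0)) {
    warnf("dropping %d zero-variance probe(s)", sum(s == 0))
    x <- x[s > 0, , drop = FALSE]
  }
  scaled <- row_scale(x)
  pd <- hclust_complete(scaled)
  sdd <- hclust_complete(t(scaled))
  out <- list(scaled = scaled, probe_dendro = pd, sample_dendro = sdd,
              probe_order = rownames(scaled)[pd$order],
              sample_order = colnames(scaled)[sdd$order])
  if (!is.null(clinical)) {
    out$subtype <- clinical$subtype[match(out$sample_order,
                                          clinical$patient_id)]
  }
  out
}

#' PCA projection of samples over a probe panel
#'
#' Standardized PCA of the samples-by-probes matrix, with subtype
#' labels attached to the scores and the eigenvector / variance table
#' assembled for export.
#'
#' @param m_log Log2-transformed [expr_mat].
#' @param probes Probe ids forming the panel (>= 2).
#' @param clinical Clinical table covering all samples.
#' @param standardize Passed to [pca_standardized].
#' @return List: `pca` (a `pca_result`), `scores` (data.frame with
#'   `patient_id`, `subtype`, PC columns), `variance_table`
#'   (eigenvectors, standard deviation, proportion and cumulative
#'   proportion of variance).
#' @export
pca_project <- function(m_log, probes, clinical, standardize = TRUE) {
  if (length(probes) < 2L) stopf("PCA needs at least 2 probes")
  x <- t(m_log$signals[probes, , drop = FALSE])
  if (nrow(x) < 3L) stopf("PCA projection needs at least 3 samples")
  pc <- pca_standardized(x, standardize = standardize)
  idx <- match(rownames(x), clinical$patient_id)
  scores <- data.frame(patient_id = rownames(x),
                       subtype = clinical$subtype[idx],
                       as.data.frame(pc$scores), stringsAsFactors = FALSE)
  vt <- rbind(as.data.frame(pc$loadings),
              `Standard deviation` = pc$sdev,
              `Proportion of Variance` = pc$variance_proportion,
              `Cumulative Proportion` = pc$cumulative_proportion)
  list(pca = pc, scores = scores, variance_table = vt)
}

#' Kaplan-Meier curves and logrank test by histological subtype
#'
#' One product-limit curve per subtype plus the k-sample logrank
#' p-value across them; with a single subtype the test is skipped with
#' a flag and the curve still produced.
#'
#' @param clinical Clinical table (already restricted to the subtypes
#'   of interest, e.g. the four discrimination subtypes).
#' @param horizon Censoring horizon in months.
#' @return List: `curves` (named list of `km_curve`), `logrank`
#'   (a `test_result`, or `NULL` with `flag = "single_group"`).
#' @export
subtype_km <- function(clinical, horizon = 50) {
  sd <- apply_censor_horizon(clinical_surv(clinical), horizon)
  subs <- unique(clinical$subtype)
  curves <- lapply(stats::setNames(subs, subs), function(s) {
    i <- clinical$subtype == s
    km_curve(surv_data(sd$times[i], sd$events[i]))
  })
  lr <- if (length(subs) >= 2L) logrank_test(clinical$subtype, sd) else NULL
  list(curves = curves, logrank = lr,
       flag = if (length(subs) < 2L) "single_group" else NULL)
}

#' Survival split on one probe: KM curves, logrank and Cox hazard ratio
#'
#' Splits patients into positive (above threshold) and negative groups
#' on one probe's signal, then reports both Kaplan-Meier curves, the
#' two-group logrank p-value, and the binary-covariate Cox hazard
#' ratio exp(B).
#'
#' @param m An [expr_mat].
#' @param probe Probe id.
#' @param sd A [surv_data] aligned with the matrix's samples (horizon
#'   already applied, or supply `horizon`).
#' @param split Either a numeric signal threshold (group is signal >
#'   split) or a logical/0-1 vector giving the high group directly.
#' @param horizon Optional censoring horizon to apply.
#' @return List: `km_high`, `km_low`, `logrank` (`test_result`), `cox`
#'   (`cox_result`), `n_high`, `n_low`.
#' @export
km_by_gene <- function(m, probe, sd, split, horizon = NULL) {
  if (!is.null(horizon)) sd <- apply_censor_horizon(sd, horizon)
  x <- m$signals[probe, ]
  grp <- if (is.numeric(split) && length(split) == 1L) x > split
         else as.logical(split)
  if (!any(grp) || all(grp)) stopf("split does not yield two nonempty groups")
  hi <- surv_data(sd$times[grp], sd$events[grp])
  lo <- surv_data(sd$times[!grp], sd$events[!grp])
  list(km_high = km_curve(hi), km_low = km_curve(lo),
       logrank = logrank_test(grp, sd),
       cox = cox_binary(grp, sd),
       n_high = sum(grp), n_low = sum(!grp))
}
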
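#' Remove control and cross-hybridizing probes
#'
#' @param m An [expr_mat].
#' @param ann Annotation data.frame covering every probe of `m`.
#' @return The matrix restricted to unflagged probes, order preserved.
#' @export
exclude_flagged <- function(m, ann) {
  idx <- match(probe_ids(m), ann$probe_id)
  if (anyNA(idx)) {
    stopf("probe(s) missing from annotation: %s",
          paste(utils::head(probe_ids(m)[is.na(idx)], 3L), collapse = ", "))
  }
  keep <- !(ann$is_control[idx] | ann$is_cross_hyb[idx])
  if (!any(keep)) warnf("all probes are flagged; result is empty")
  subset_probes(m, keep)
}

#' Filter probes by absent-call fraction
#'
#' A probe is removed when the fraction of samples with an Absent
#' detection call reaches `max_absent_fraction` (default 0.5, i.e. 44
#' of 88 samples).  Marginal calls count as not-absent by default.
#' When the matrix carries no calls the filter is a no-op.
#'
#' @param m An [expr_mat].
#' @param max_absent_fraction Removal threshold on the absent fraction.
#' @param strict If `TRUE`, remove only probes whose absent fraction
#'   strictly exceeds the threshold (the ">50%" reading); default
#'   `FALSE` removes at the threshold as well (the "44/88" reading).
#' @param marginal_absent Count Marginal calls as absent (default
#'   `FALSE`).
#' @return The filtered matrix.
#' @export
absent_call_filter <- function(m, max_absent_fraction = 0.5,
                               strict = FALSE, marginal_absent = FALSE) {
  if (is.null(m$calls)) return(m)
  absent <- m$calls == "A"
  if (marginal_absent) absent <- absent | m$calls == "M"
  frac <- rowMeans(absent)
  keep <- if (strict) frac <= max_absent_fraction else frac < max_absent_fraction
  subset_probes(m, keep)
}

#' Filter probes by 5th-to-95th percentile signal range
#'
#' Probes whose (hi_pct − lo_pct) percentile signal range is below
#' `min_range` are removed.  Percentiles use linear interpolation at
#' fractional order-statistic index (n−1)·pct/100 by default
#' (`method = "linear"`, the common statistical-software convention);
#' `method = "nearest"` uses the nearest-rank definition.
#'
#' @param m An [expr_mat] with at least 2 samples.
#' @param lo_pct,hi_pct Percentile bounds (defaults 5 and 95).
#' @param min_range Minimum retained range in signal units
#'   (default 2000).
#' @param method Percentile convention.
#' @return The filtered matrix.
#' @export
range_filter <- function(m, lo_pct = 5, hi_pct = 95, min_range = 2000,
                         method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (ncol(m$signals) < 2L) stopf("range filter needs at least 2 samples")
  type <- if (method == "linear") 7L else 1L
  qs <- apply(m$signals, 1L, stats::quantile,
              probs = c(lo_pct, hi_pct) / 100, type = type, names = FALSE)
  keep <- (qs[2L, ] - qs[1L, ]) >= min_range
  subset_probes(m, keep)
}

#' Restrict probes to a disease-gene knowledge map
#' @param m An [expr_mat].
#' @param km A [knowledge_map]; probes outside `km$probe_ids` are
#'   removed.
#' @return The filtered matrix.
#' @export
knowledge_filter <- function(m, km) {
  if (!length(km$probe_ids)) stopf("knowledge map is empty")
  keep <- probe_ids(m) %in% km$probe_ids
  if (!any(keep)) warnf("no probes intersect the knowledge map; result is empty")
  subset_probes(m, keep)
}

#' Log-transform signals
#'
#' Replaces every signal by log2(signal + 1); the +1 offset keeps
#' zero signals finite and preserves ordering.
#'
#' @param m An [expr_mat].
#' @return The transformed matrix (detection calls carried through).
#' @export
log_transform <- function(m) {
  expr_mat(log2(m$signals + 1), m$calls)
}

#' Binarize each probe at its median
#'
#' Per probe, samples strictly above the probe's median (across all
#' supplied samples) are coded 1, the rest 0.  With an even sample
#' count the median is the mean of the two middle order statistics;
#' values equal to the median go to the low group.
#'
#' @param m An [expr_mat] with at least 2 samples.
#' @return An [expr_mat] of 0/1 values.
#' @export
binarize_by_median <- function(m) {
  if (ncol(m$signals) < 2L) stopf("binarization needs at least 2 samples")
  med <- apply(m$signals, 1L, stats::median)
  expr_mat((m$signals > med) + 0, m$calls)
}

#' Run the full probe-reduction cascade
#'
#' Applies, in fixed order: control/cross-hybridization exclusion,
#' absent-call filter, percentile-range filter, knowledge-map filter.
#' Each stage is a pure subset operation.
#'
#' @param m An [expr_mat].
#' @param ann Probe annotation.
#' @param km A [knowledge_map].
#' @param max_absent_fraction,strict Passed to [absent_call_filter].
#' @param min_range Passed to [range_filter].
#' @return A list of class `filter_report`: the filtered matrix
#'   (`expr`), per-stage removal counts (`counts`), and surviving probe
#'   ids (`probes_remaining`).
#' @export
prefilter <- function(m, ann, km, max_absent_fraction = 0.5,
                      strict = FALSE, min_range = 2000) {
  n0 <- nrow(m$signals)
  m1 <- exclude_flagged(m, ann)
  flag_ids <- setdiff(probe_ids(m), probe_ids(m1))
  n_control <- sum(ann$is_control[match(flag_ids, ann$probe_id)])
  m2 <- absent_call_filter(m1, max_absent_fraction, strict)
  m3 <- range_filter(m2, min_range = min_range)
  m4 <- knowledge_filter(m3, km)
  counts <- c(control = n_control,
              cross_hyb = nrow(m$signals) - nrow(m1$signals) - n_control,
              absent_call = nrow(m1$signals) - nrow(m2$signals),
              low_range = nrow(m2$signals) - nrow(m3$signals),
              not_in_knowledge = nrow(m3$signals) - nrow(m4$signals))
  stopifnot(sum(counts) == n0 - nrow(m4$signals))
  structure(list(expr = m4, counts = counts,
                 probes_remaining = probe_ids(m4)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  removed %-16s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("  remaining            %d\n", length(x$probes_remaining)))
  invisible(x)
}

#' Write a filter report as TSV (stage, removed, remaining)
#' @param report A `filter_report`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_filter_report <- function(report, path) {
  total <- length(report$probes_remaining) + sum(report$counts)
  df <- data.frame(stage = names(report$counts),
                   removed = as.integer(report$counts),
                   remaining = total - cumsum(as.integer(report$counts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
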
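#' Configuration for an end-to-end pipeline run
#'
#' @param paths Optional named list of input file paths (`signals`,
#'   `calls`, `clinical`, `annotation`, `knowledge`); when `NULL` the
#'   synthetic generator is used (`simulate = TRUE`).
#' @param simulate Generate inputs with [generate_dataset].
#' @param sim SimulationConfig used when simulating.
#' @param R Permutation repetitions for the null.
#' @param seed Master seed; stage seeds are derived from it.
#' @param alpha Significance level on the adjusted p (in (0,1)).
#' @param survival_cohort Passed to [screen_probes] / [build_null].
#' @param thresholds Percentiles for the within-subtype threshold scan.
#' @param scan_subtype Subtype for the threshold scan (default UPS);
#'   `NULL` disables the scan.
#' @param out_dir Output directory.
#' @param min_range,max_absent_fraction Prefilter settings.
#' @param quiet Suppress per-stage messages.
#' @return A `run_config` list.
#' @export
run_config <- function(paths = NULL, simulate = is.null(paths),
                       sim = sim_config(), R = 1000L, seed = 1L,
                       alpha = 0.05,
                       survival_cohort = c("all", "discrimination"),
                       thresholds = c(30, 40, 50, 60, 70, 80),
                       scan_subtype = "UPS", out_dir = tempfile("sarcorun"),
                       min_range = 2000, max_absent_fraction = 0.5,
                       quiet = FALSE) {
  survival_cohort <- match.arg(survival_cohort)
  if (R < 1L) stopf("R must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0, 1)")
  structure(list(paths = paths, simulate = simulate, sim = sim,
                 R = as.integer(R), seed = as.integer(seed), alpha = alpha,
                 survival_cohort = survival_cohort, thresholds = thresholds,
                 scan_subtype = scan_subtype, out_dir = out_dir,
                 min_range = min_range,
                 max_absent_fraction = max_absent_fraction, quiet = quiet),
            class = "run_config")
}

stage_msg <- function(cfg, fmt, ...) {
  if (!cfg$quiet) message(sprintf(paste0("[sarcoscreen] ", fmt), ...))
}

#' Run the full pipeline: simulate/read, filter, screen, downstream
#'
#' Stages run in the canonical order (input acquisition, prefilter
#' cascade, log transform + median binarization, integrated screen,
#' permutation null + adjustment, downstream characterization of the
#' selected probes, within-subtype threshold scan), writing every
#' stage output as TSV/CSV into `cfg$out_dir` together with a manifest
#' of seeds, counts and file checksums.  Re-running with an identical
#' config and seed reproduces every output byte for byte.
#'
#' @param cfg A [run_config].
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  if (cfg$simulate) {
    stage_msg(cfg, "simulate: seed %d", cfg$sim$seed)
    ds <- generate_dataset(cfg$sim)
    write_clinical(ds$clinical, out("clinical.csv"))
    write_expression(ds$expr, out("signals.tsv"), out("calls.tsv"))
    write_annotation(ds$annotation, out("annotation.tsv"))
    utils::write.table(ds$truth, out("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    has <- lengths(ds$annotation$mim_numbers) > 0
    km_pairs <- data.frame(
      mim_id = unlist(ds$annotation$mim_numbers[has]),
      probe_id = rep(ds$annotation$probe_id[has],
                     lengths(ds$annotation$mim_numbers[has])))
    utils::write.table(km_pairs, out("knowledge.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    expr <- ds$expr; clinical <- ds$clinical; ann <- ds$annotation
    km <- ds$knowledge
  } else {
    p <- cfg$paths
    stage_msg(cfg, "read: %s", p$signals)
    expr <- read_expression(p$signals, p$calls)
    clinical <- read_clinical(p$clinical)
    ann <- read_annotation(p$annotation)
    km <- read_knowledge_map(p$knowledge)
  }

  stage_msg(cfg, "filter: %d probes in", nrow(expr$signals))
  frep <- prefilter(expr, ann, km, cfg$max_absent_fraction,
                   min_range = cfg$min_range)
  write_filter_report(frep, out("filter_report.tsv"))
  m <- frep$expr
  if (nrow(m$signals) < 1L) stopf("stage filter: no probes survive")
  m_log <- log_transform(m)
  m_bin <- binarize_by_median(m)
  write_expression(m, out("filtered_signals.tsv"))
  write_expression(m_log, out("log_signals.tsv"))
  write_expression(m_bin, out("binarized.tsv"))

  stage_msg(cfg, "screen: %d probes, R = %d", nrow(m$signals), cfg$R)
  sr <- screen_probes(m_log, m_bin, clinical, cfg$survival_cohort)
  null <- build_null(m_log, m_bin, clinical, R = cfg$R,
                     seed = derive_seed(cfg$seed, 3L),
                     survival_cohort = cfg$survival_cohort)
  sr <- adjust_screening(sr, null)
  write_screening(sr, out("screening.tsv"), ann)
  utils::write.table(data.frame(null_min = null$null_min),
                     out("null_distribution.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  selected <- sr$probe_id[!is.na(sr$p_adjusted) & sr$p_adjusted < cfg$alpha]
  stage_msg(cfg, "selected %d probes at adjusted p < %g",
            length(selected), cfg$alpha)

  down <- NULL
  if (length(selected) >= 2L) {
    stage_msg(cfg, "downstream: %d probes", length(selected))
    msel <- subset_probes(m, match(selected, probe_ids(m)))
    msel_log <- subset_probes(m_log, match(selected, probe_ids(m_log)))
    corr <- correlate_clinical(msel, clinical)
    utils::write.table(corr, out("correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pw <- tryCatch(pairwise_compare(msel_log, clinical, alpha = cfg$alpha),
                   error = function(e) NULL)
    venn <- NULL
    if (!is.null(pw)) {
      utils::write.table(pw, out("pairwise.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      venn <- venn_classify(pw, ann = ann)
      utils::write.table(venn, out("venn.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    hm <- heatmap_export(msel_log, clinical = clinical)
    write_dendro(hm$probe_dendro, out("probe_dendrogram.tsv"))
    write_dendro(hm$sample_dendro, out("sample_dendrogram.tsv"))
    pcp <- pca_project(m_log, selected, clinical)
    utils::write.table(cbind(rowname = rownames(pcp$variance_table),
                             pcp$variance_table),
                       out("pca_table.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(pcp$scores, out("pca_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    down <- list(correlations = corr, pairwise = pw, venn = venn,
                 heatmap = hm, pca = pcp)
  }

  disc <- clinical[clinical$subtype %in% discrimination_subtypes(), ]
  skm <- subtype_km(disc)
  for (s in names(skm$curves)) {
    write_km_curve(skm$curves[[s]], out(sprintf("km_%s.tsv", s)))
  }

  scan <- NULL
  if (!is.null(cfg$scan_subtype) &&
      sum(clinical$subtype == cfg$scan_subtype) >= 4L &&
      length(selected) >= 1L) {
    stage_msg(cfg, "threshold scan in %s", cfg$scan_subtype)
    cols <- which(clinical$subtype[match(sample_ids(m),
                                         clinical$patient_id)] ==
                  cfg$scan_subtype)
    msub <- expr_mat(m$signals[selected, cols, drop = FALSE])
    csub <- clinical[match(colnames(msub$signals), clinical$patient_id), ]
    scan <- threshold_scan(msub, clinical_surv(csub), cfg$thresholds,
                           R = cfg$R, seed = derive_seed(cfg$seed, 4L),
                           horizon = 50)
    utils::write.table(as.data.frame(scan), out("threshold_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- sort(list.files(cfg$out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    stringsAsFactors = FALSE)
  header <- data.frame(file = c("#seed", "#R", "#alpha", "#n_patients",
                                "#n_probes_in", "#n_probes_screened",
                                "#n_selected"),
                       md5 = c(cfg$seed, cfg$R, cfg$alpha, nrow(clinical),
                               length(frep$probes_remaining) +
                                 sum(frep$counts),
                               length(frep$probes_remaining),
                               length(selected)))
  utils::write.table(rbind(header, manifest), out("manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_msg(cfg, "done: %s", cfg$out_dir)
  invisible(list(clinical = clinical, screening = sr, null = null,
                 selected = selected, filter = frep, downstream = down,
                 subtype_km = skm, scan = scan,
                 manifest = rbind(header, manifest), out_dir = cfg$out_dir))
}
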
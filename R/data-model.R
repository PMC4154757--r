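#' Construct an expression matrix object
#'
#' The central data container: a probes x samples grid of non-negative
#' MAS5-scaled signal values, with an optional parallel grid of
#' detection calls in \{P, M, A\} (present / marginal / absent).
#'
#' @param signals Numeric matrix, probes as rows, samples as columns;
#'   rownames are probe ids, colnames are sample ids.
#' @param calls Optional character matrix of the same dimensions with
#'   values in "P", "M", "A".
#' @return An object of class `expr_mat` with elements `signals` and
#'   `calls`.
#' @export
expr_mat <- function(signals, calls = NULL) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  # an empty dimension cannot carry names (R drops zero-length dimnames)
  if ((nrow(signals) > 0L && is.null(rownames(signals))) ||
      (ncol(signals) > 0L && is.null(colnames(signals)))) {
    stopf("signals must carry probe ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(signals))) stopf("duplicate probe ids")
  if (anyDuplicated(colnames(signals))) stopf("duplicate sample ids")
  if (anyNA(signals)) stopf("signals contain missing values")
  if (any(signals < 0)) {
    bad <- which(signals < 0, arr.ind = TRUE)[1L, ]
    stopf("negative signal at probe '%s', sample '%s'",
          rownames(signals)[bad[1L]], colnames(signals)[bad[2L]])
  }
  if (!is.null(calls)) {
    calls <- as.matrix(calls)
    if (!identical(dim(calls), dim(signals))) {
      stopf("calls dimensions (%d x %d) differ from signals (%d x %d)",
            nrow(calls), ncol(calls), nrow(signals), ncol(signals))
    }
    bad <- !(calls %in% c("P", "M", "A"))
    if (any(bad)) {
      idx <- which(matrix(bad, nrow(calls)), arr.ind = TRUE)[1L, ]
      stopf("unknown detection call '%s' at probe '%s', sample '%s'",
            calls[idx[1L], idx[2L]], rownames(signals)[idx[1L]],
            colnames(signals)[idx[2L]])
    }
    dimnames(calls) <- dimnames(signals)
  }
  structure(list(signals = signals, calls = calls), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d probes x %d samples%s\n",
              nrow(x$signals), ncol(x$signals),
              if (is.null(x$calls)) "" else " (with detection calls)"))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$signals)

#' Probe and sample identifiers of an expression matrix
#' @param m An `expr_mat`.
#' @return Character vector of ids.
#' @export
probe_ids <- function(m) rownames(m$signals)

#' @rdname probe_ids
#' @export
sample_ids <- function(m) colnames(m$signals)

#' Subset an expression matrix by probe index or name
#' @param m An [expr_mat].
#' @param keep Integer, logical or character index of probes to keep.
#' @return The subsetted [expr_mat], detection calls kept aligned.
#' @export
subset_probes <- function(m, keep) {
  expr_mat(m$signals[keep, , drop = FALSE],
           if (!is.null(m$calls)) m$calls[keep, , drop = FALSE])
}

#' Read an expression matrix (and optional detection calls) from TSV
#'
#' Signals are tab-separated with probe ids in the first column and a
#' header row of sample ids; the calls file, if given, has the same
#' layout with cells in \{P, M, A\}.
#'
#' @param path_signals Path to the signal TSV.
#' @param path_calls Optional path to the detection-call TSV.
#' @return An [expr_mat].
#' @export
read_expression <- function(path_signals, path_calls = NULL) {
  sig <- utils::read.delim(path_signals, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(sig[, -1L, drop = FALSE])
  rownames(m) <- as.character(sig[[1L]])
  calls <- NULL
  if (!is.null(path_calls)) {
    cl <- utils::read.delim(path_calls, check.names = FALSE,
                            colClasses = "character")
    calls <- as.matrix(cl[, -1L, drop = FALSE])
    rownames(calls) <- as.character(cl[[1L]])
    if (!identical(rownames(calls), rownames(m)) ||
        !identical(colnames(calls), colnames(m))) {
      stopf("calls file ids do not match signals file ids")
    }
  }
  expr_mat(m, calls)
}

#' Write an expression matrix (and calls) to TSV
#' @param m An [expr_mat].
#' @param path_signals Output path for signals.
#' @param path_calls Optional output path for calls.
#' @return Invisibly, `m`.
#' @export
write_expression <- function(m, path_signals, path_calls = NULL) {
  write_id_matrix(m$signals, path_signals, "probe_id")
  if (!is.null(path_calls)) {
    if (is.null(m$calls)) stopf("matrix has no calls to write")
    write_id_matrix(m$calls, path_calls, "probe_id")
  }
  invisible(m)
}

write_id_matrix <- function(mat, path, id_col) {
  df <- data.frame(mat[, 0, drop = FALSE], check.names = FALSE)
  df[[id_col]] <- rownames(mat)
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a clinical table from CSV
#'
#' Required columns: `patient_id`, `subtype`, `gender`, `age`, `grade`,
#' `metastasis`, `survival_time`, `death_event`.  Categorical values are
#' normalized case-insensitively; booleans accept 0/1, true/false,
#' yes/no.
#'
#' @param path Path to the CSV file.
#' @return A validated clinical `data.frame`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_clinical(df)
}

#' Validate (and normalize) a clinical data.frame
#' @param df A data.frame with the clinical columns of [read_clinical].
#' @return The validated data.frame.
#' @export
as_clinical <- function(df) {
  req <- c("patient_id", "subtype", "gender", "age", "grade",
           "metastasis", "survival_time", "death_event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stopf("clinical table lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- df[, req]
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) stopf("duplicate patient ids")
  df$subtype <- toupper(trimws(df$subtype))
  bad <- setdiff(unique(df$subtype), sts_subtypes())
  if (length(bad)) stopf("unknown subtype token(s): %s", paste(bad, collapse = ", "))
  df$gender <- tolower(trimws(df$gender))
  if (!all(df$gender %in% c("male", "female"))) stopf("gender must be male/female")
  df$age <- as.numeric(df$age)
  df$grade <- as.integer(df$grade)
  if (!all(df$grade %in% 1:3)) stopf("grade must be 1, 2 or 3")
  df$metastasis <- parse_bool(df$metastasis, "metastasis")
  df$survival_time <- as.numeric(df$survival_time)
  if (any(df$survival_time <= 0)) stopf("survival_time must be > 0")
  df$death_event <- parse_bool(df$death_event, "death_event")
  rownames(df) <- NULL
  df
}

#' Write a clinical table to CSV (booleans emitted as 0/1)
#' @param clinical A clinical data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  out$metastasis <- as.integer(out$metastasis)
  out$death_event <- as.integer(out$death_event)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe annotation table from TSV
#'
#' Columns: `probe_id`, `is_control`, `is_cross_hyb`, `gene_symbol`,
#' `accession`, `mim_numbers` (semicolon-joined MIM identifiers).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with `mim_numbers` as a list column.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  as_annotation(df)
}

#' Validate a probe annotation data.frame
#' @param df Data.frame with the columns of [read_annotation];
#'   `mim_numbers` may be a semicolon-joined character or a list column.
#' @return The validated data.frame (list-column `mim_numbers`).
#' @export
as_annotation <- function(df) {
  req <- c("probe_id", "is_control", "is_cross_hyb", "gene_symbol",
           "accession", "mim_numbers")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stopf("annotation lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- df[, req]
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id)) stopf("duplicate probe ids in annotation")
  df$is_control <- parse_bool(df$is_control, "is_control")
  df$is_cross_hyb <- parse_bool(df$is_cross_hyb, "is_cross_hyb")
  if (!is.list(df$mim_numbers)) {
    df$mim_numbers <- lapply(strsplit(as.character(df$mim_numbers), ";",
                                      fixed = TRUE),
                             function(x) unique(x[nzchar(x)]))
  }
  rownames(df) <- NULL
  df
}

#' Write a probe annotation table to TSV
#' @param ann Annotation data.frame ([as_annotation]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_annotation <- function(ann, path) {
  out <- ann
  out$is_control <- as.integer(out$is_control)
  out$is_cross_hyb <- as.integer(out$is_cross_hyb)
  out$mim_numbers <- vapply(out$mim_numbers, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a knowledge map (MIM id to probe id pairs) from TSV
#' @param path TSV with columns `mim_id`, `probe_id`, one pair per row.
#' @return An object of class `knowledge_map` with deduplicated
#'   `mim_ids` and `probe_ids` sets.
#' @export
read_knowledge_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("mim_id", "probe_id") %in% names(df))) {
    stopf("knowledge map needs columns mim_id and probe_id")
  }
  knowledge_map(df$mim_id, df$probe_id)
}

#' Construct a knowledge map
#' @param mim_ids Character vector of MIM identifiers selected by
#'   disease keywords.
#' @param probe_ids Character vector of probe ids mapped from the MIM
#'   list.
#' @return A `knowledge_map` object.
#' @export
knowledge_map <- function(mim_ids, probe_ids) {
  structure(list(mim_ids = unique(as.character(mim_ids)),
                 probe_ids = unique(as.character(probe_ids))),
            class = "knowledge_map")
}

#' Derive a knowledge map from an annotation's MIM assignments
#' @param ann Annotation data.frame; probes with at least one MIM
#'   number are taken as in-knowledge.
#' @return A `knowledge_map`.
#' @export
knowledge_map_from_annotation <- function(ann) {
  has <- lengths(ann$mim_numbers) > 0
  knowledge_map(unlist(ann$mim_numbers[has]), ann$probe_id[has])
}

#' Construct a survival dataset
#' @param times Follow-up times in months (> 0).
#' @param events Logical: death observed.
#' @param censor_horizon Administrative horizon in months used by
#'   [apply_censor_horizon]; default 50.
#' @return A `surv_data` object.
#' @export
surv_data <- function(times, events, censor_horizon = 50) {
  times <- as.numeric(times)
  events <- as.logical(events)
  if (length(times) != length(events)) stopf("times and events differ in length")
  if (any(times <= 0)) stopf("survival times must be > 0")
  if (anyNA(times) || anyNA(events)) stopf("missing survival values")
  structure(list(times = times, events = events,
                 censor_horizon = censor_horizon),
            class = "surv_data")
}

#' Apply an administrative censoring horizon
#'
#' Every follow-up time beyond the horizon is set to the horizon with
#' the event indicator cleared (follow-up past the horizon is treated
#' as censored); times at or below the horizon are untouched.  The
#' operation is idempotent.
#'
#' @param sd A [surv_data].
#' @param horizon Months; default the object's `censor_horizon`.
#' @return A censored [surv_data].
#' @export
apply_censor_horizon <- function(sd, horizon = sd$censor_horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0) {
    stopf("horizon must be a single positive number")
  }
  over <- sd$times > horizon
  sd$times[over] <- horizon
  sd$events[over] <- FALSE
  sd$censor_horizon <- horizon
  sd
}

#' Extract survival data from a clinical table
#' @param clinical Clinical data.frame.
#' @param censor_horizon Horizon in months stored on the result.
#' @return A [surv_data] in the clinical table's row order.
#' @export
clinical_surv <- function(clinical, censor_horizon = 50) {
  surv_data(clinical$survival_time, clinical$death_event, censor_horizon)
}
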
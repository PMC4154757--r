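#' Principal component analysis (standardized by default)
#'
#' Components of the column-standardized data (correlation-matrix PCA)
#' computed by singular value decomposition, ordered by decreasing
#' variance.  Standardization is the default because expression signal
#' scales span orders of magnitude; set `standardize = FALSE` for
#' covariance PCA.  Zero-variance variables are dropped with a
#' warning.  Sign convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param data Numeric matrix, samples as rows, variables as columns
#'   (>= 2 of each).
#' @param standardize Scale variables to unit variance (default TRUE).
#' @return A `pca_result`: `scores` (samples x components), `loadings`
#'   (variables x components, orthonormal), `sdev`,
#'   `variance_proportion`, `cumulative_proportion`, `dropped`
#'   (names of removed zero-variance variables).
#' @export
pca_standardized <- function(data, standardize = TRUE) {
  data <- as.matrix(data)
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stopf("PCA needs at least 2 samples and 2 variables")
  }
  v <- apply(data, 2L, stats::var)
  dropped <- colnames(data)[v == 0] %||% character()
  if (any(v == 0)) {
    warnf("dropping %d zero-variance variable(s)", sum(v == 0))
    data <- data[, v > 0, drop = FALSE]
    if (ncol(data) < 2L) stopf("fewer than 2 variables with positive variance")
  }
  x <- scale(data, center = TRUE, scale = standardize)
  sv <- svd(x)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  rot <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: dominant loading positive
  flip <- vapply(seq_len(ncomp), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(u, 2L, d * flip, `*`)
  sdev <- d / sqrt(nrow(x) - 1)
  prop <- sdev^2 / sum(sdev^2)
  dimnames(rot) <- list(colnames(data), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(data), paste0("PC", seq_len(ncomp)))
  structure(list(scores = scores, loadings = rot, sdev = sdev,
                 variance_proportion = prop,
                 cumulative_proportion = cumsum(prop), dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$sdev), 100 * x$variance_proportion[1L],
              if (length(x$sdev) > 1) 100 * x$variance_proportion[2L] else NA))
  invisible(x)
}

#' Agglomerative complete-linkage clustering on Euclidean distances
#'
#' Classical bottom-up agglomeration: at each step the pair of
#' clusters with the smallest complete-linkage (maximum pairwise
#' Euclidean) distance is merged; ties are broken lexicographically by
#' the pair of cluster creation indices, so results are deterministic
#' across platforms.  The merge table follows the [stats::hclust]
#' convention (negative entries are leaves, positive entries earlier
#' merges).
#'
#' @param data Numeric matrix, items as rows, features as columns.
#' @return A `dendro`: `merge` ((n-1) x 2), `height`, `order` (leaf
#'   order), `labels`.
#' @export
hclust_complete <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2L) stopf("clustering needs at least 2 items")
  d <- as.matrix(stats::dist(data, method = "euclidean"))
  diag(d) <- Inf
  # active cluster bookkeeping: id < 0 leaf, > 0 merge row
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- c(Inf, NA_integer_, NA_integer_)
    for (ai in seq_along(act)) {
      i <- act[ai]
      if (ai == length(act)) break
      js <- act[(ai + 1L):length(act)]
      dij <- d[i, js]
      jmin <- js[which.min(dij)]   # first minimum: lexicographic tie-break
      if (min(dij) < best[1L]) best <- c(min(dij), i, jmin)
    }
    i <- best[2L]; j <- best[3L]
    a <- id[i]; b <- id[j]
    # hclust convention: singletons before clusters, then by index
    before <- if (a < 0L && b < 0L) -a < -b else
      if (a < 0L || b < 0L) a < 0L else a < b
    merge[step, ] <- if (before) c(a, b) else c(b, a)
    height[step] <- best[1L]
    # complete linkage update: new distance is the max
    for (kk in act) {
      if (kk == i || kk == j) next
      d[i, kk] <- d[kk, i] <- max(d[i, kk], d[j, kk])
    }
    active[j] <- FALSE
    id[i] <- step
    members[[i]] <- c(members[[i]], members[[j]])
  }
  order <- dendro_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = rownames(data) %||% as.character(seq_len(n))),
            class = "dendro")
}

# leaf order by recursive expansion of the merge table
dendro_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Convert a `dendro` to a [stats::hclust] object
#' @param x A `dendro` from [hclust_complete].
#' @return An object of class `hclust`.
#' @export
as_hclust <- function(x) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "complete",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Write a dendrogram merge table as TSV
#' @param x A `dendro`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_dendro <- function(x, path) {
  df <- data.frame(step = seq_along(x$height), a = x$merge[, 1L],
                   b = x$merge[, 2L], height = x$height)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Center and scale each row to mean 0, standard deviation 1
#' @param data Numeric matrix; every row must have positive variance.
#' @return The row-standardized matrix.
#' @export
row_scale <- function(data) {
  data <- as.matrix(data)
  s <- apply(data, 1L, stats::sd)
  if (any(s == 0)) {
    stopf("zero-variance row(s): %s",
          paste(utils::head(rownames(data)[s == 0] %||%
                            which(s == 0), 3L), collapse = ", "))
  }
  (data - rowMeans(data)) / s
}
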
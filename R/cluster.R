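# Hierarchical clustering of the log-transformed normalized matrix:
# samples by average linkage on correlation distance, peptides by Ward
# linkage on Euclidean distance.

#' Log-transform a normalized abundance matrix
#'
#' Applies `ln(x + floor_offset)` entrywise. With the default offset 1e-5,
#' absent peptides (0) map to `ln(1e-5)`, putting detected and absent values
#' on one finite scale.
#'
#' @param matrix a [repertoire_matrix()] or a plain numeric matrix with
#'   entries in \[0, 1\].
#' @param floor_offset additive offset before taking the natural log.
#' @return Numeric matrix of log abundances.
#' @export
log_transform_matrix <- function(matrix, floor_offset = 1e-5) {
  vals <- if (inherits(matrix, "repertoire_matrix")) matrix$values else as.matrix(matrix)
  if (any(vals < 0)) stop("negative abundances cannot be log-transformed")
  log(vals + floor_offset)
}

#' Correlation distance between matrix columns
#'
#' `d(a, b) = 1 - Pearson(a, b)`. A zero-variance column has undefined
#' correlations; these are set to 0 (distance 1) with a warning.
#'
#' @param log_matrix numeric matrix (observations in rows).
#' @return A `dist` object over columns.
#' @export
correlation_distance <- function(log_matrix) {
  cc <- suppressWarnings(cor(log_matrix))
  if (anyNA(cc)) {
    warning("zero-variance column(s): undefined correlations set to 0")
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  }
  stats::as.dist(1 - cc)
}

#' Cluster samples (columns) of the log matrix
#'
#' Agglomerative clustering with average linkage on correlation distance,
#' mirroring the column ordering of repertoire heatmaps.
#'
#' @param log_matrix numeric matrix from [log_transform_matrix()].
#' @return List of class `cluster_result`: `tree` (an [stats::hclust] object),
#'   `order` (leaf permutation), `labels`, `method`, `distance`.
#' @export
cluster_columns <- function(log_matrix) {
  if (ncol(log_matrix) < 2L) stop("need at least 2 columns to cluster")
  hc <- hclust(correlation_distance(log_matrix), method = "average")
  structure(list(tree = hc, order = hc$order, labels = hc$labels,
                 method = "average", distance = "correlation"),
            class = "cluster_result")
}

#' Cluster peptides (rows) of the log matrix
#'
#' Ward linkage (`ward.D2`, i.e. Ward's minimum-variance criterion on
#' Euclidean distances) over the peptide rows.
#'
#' @param log_matrix numeric matrix from [log_transform_matrix()].
#' @return A `cluster_result` as in [cluster_columns()].
#' @export
cluster_rows <- function(log_matrix) {
  if (nrow(log_matrix) < 2L) {
    return(structure(list(tree = NULL, order = 1L,
                          labels = rownames(log_matrix),
                          method = "ward.D2", distance = "euclidean"),
                     class = "cluster_result"))
  }
  hc <- hclust(dist(log_matrix, method = "euclidean"), method = "ward.D2")
  structure(list(tree = hc, order = hc$order, labels = hc$labels,
                 method = "ward.D2", distance = "euclidean"),
            class = "cluster_result")
}

#' Cut a cluster tree into k groups
#' @param result a `cluster_result`.
#' @param k number of clusters.
#' @return Integer vector of cluster memberships named by label.
#' @export
cut_clusters <- function(result, k) {
  if (is.null(result$tree)) return(setNames(1L, result$labels))
  cutree(result$tree, k = k)
}

#' Cluster a repertoire matrix for heatmap-style display
#'
#' Log-transforms the matrix, clusters columns (samples, average linkage on
#' correlation distance) and rows (peptides, Ward on Euclidean), and returns
#' the orders plus the transformed matrix.
#'
#' @param matrix a [repertoire_matrix()].
#' @param floor_offset offset for [log_transform_matrix()].
#' @return List with `columns` and `rows` (`cluster_result`s), `log_matrix`,
#'   and `ordered` (the log matrix with rows/columns permuted).
#' @export
cluster_repertoire <- function(matrix, floor_offset = 1e-5) {
  lm <- log_transform_matrix(matrix, floor_offset)
  cols <- cluster_columns(lm)
  rows <- cluster_rows(lm)
  list(columns = cols, rows = rows, log_matrix = lm,
       ordered = lm[rows$order, cols$order, drop = FALSE])
}

#' Export a cluster tree as a Newick string
#'
#' @param result a `cluster_result` with a non-trivial tree.
#' @return Newick string (requires the `ape` package).
#' @export
export_newick <- function(result) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("Newick export requires the 'ape' package")
  }
  if (is.null(result$tree)) stop("trivial tree cannot be exported")
  ape::write.tree(ape::as.phylo(result$tree))
}

#' Serialize a cluster tree to a simple JSON merge-tree structure
#'
#' Emits the merge table as a list of `(children, height)` records, children
#' negative for leaves (hclust convention).
#'
#' @param result a `cluster_result`.
#' @return JSON string.
#' @export
cluster_tree_json <- function(result) {
  hc <- result$tree
  if (is.null(hc)) return(jsonlite::toJSON(list(), auto_unbox = TRUE))
  merges <- lapply(seq_len(nrow(hc$merge)), function(i) {
    list(children = hc$merge[i, ], height = hc$height[i])
  })
  jsonlite::toJSON(list(labels = hc$labels, merges = merges,
                        order = hc$order),
                   auto_unbox = TRUE, digits = NA)
}
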
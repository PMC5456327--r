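## Cross-study log2 fold-change matrix of overlapping features and its
## hierarchical clustering.

#' Build the cross-study fold-change matrix
#'
#' One row per overlapping cluster, one column per study, values
#' `log2(ratio)`; a cell is missing where a study did not report the
#' feature. Rows with fewer than two observed values cannot be clustered and
#' are dropped with a logged warning.
#'
#' @param features per-study feature tibble (harmonized or thresholded)
#'   carrying `cluster_id`, `study_id`, `ratio`.
#' @param overlap the overlap subset: a [find_overlaps()] tibble or a
#'   character vector of cluster ids. Must be non-empty.
#' @param studies study tibble for the column annotations (fluid, group).
#' @return list with `values` (numeric matrix, rows = clusters, columns =
#'   studies) and `annotation` (tibble: study_id, fluid, group, column
#'   order).
#' @export
build_matrix <- function(features, overlap, studies) {
  ids <- if (is.data.frame(overlap)) overlap$cluster_id else overlap
  if (length(ids) == 0) fm_domain_error("overlap subset is empty")
  fm_require_columns(features, c("cluster_id", "study_id", "ratio"), "features")
  df <- features[features$cluster_id %in% ids, , drop = FALSE]
  study_ids <- sort(unique(df$study_id))
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(study_ids),
                dimnames = list(ids, study_ids))
  mat[cbind(match(df$cluster_id, ids), match(df$study_id, study_ids))] <-
    log2(df$ratio)
  thin <- rowSums(!is.na(mat)) < 2
  if (any(thin)) {
    fm_log("cluster", sprintf(
      "dropping %d row(s) with fewer than 2 observed values: %s",
      sum(thin), paste(rownames(mat)[thin], collapse = ", ")))
    mat <- mat[!thin, , drop = FALSE]
  }
  if (nrow(mat) == 0) fm_domain_error("no cluster has >= 2 observed values")
  ann <- studies[match(study_ids, studies$study_id),
                 c("study_id", "fluid", "group")]
  list(values = mat, annotation = tibble::as_tibble(ann))
}

## pairwise-complete Euclidean distance, scaled to the full dimension the
## same way stats::dist scales under NAs: d = sqrt(sum_shared (x-y)^2 * p/m)
fm_pairwise_dist <- function(mat, min_overlap = 2) {
  n <- nrow(mat); p <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2) return(as.dist(d))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      m <- sum(shared)
      if (m < min_overlap) {
        fm_domain_error(sprintf(
          "rows '%s' and '%s' share only %d non-missing column(s); need >= %d",
          rownames(mat)[i], rownames(mat)[j], m, min_overlap))
      }
      d[i, j] <- d[j, i] <- sqrt(sum((mat[i, shared] - mat[j, shared])^2) * p / m)
    }
  }
  as.dist(d)
}

#' Hierarchically cluster the fold-change matrix
#'
#' Agglomerative clustering (via [stats::hclust()]) of the rows or columns of
#' the log2 fold-change matrix. Distances are Euclidean over the
#' pairwise-complete cells, scaled to the full dimension, with a minimum
#' shared-column requirement; any pair sharing fewer than `min_overlap`
#' observed cells is an error naming the offending rows. Output is
#' deterministic for fixed input; identical rows merge first at height 0.
#'
#' @param matrix a [build_matrix()] result, or a plain numeric matrix.
#' @param axis cluster `"rows"` (default) or `"columns"`.
#' @param linkage agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @param min_overlap minimum shared non-missing cells per pair (default 2).
#' @return an object of class `hclust` (merge order, heights, leaf order).
#' @export
hcluster <- function(matrix, axis = c("rows", "columns"),
                     linkage = "average", min_overlap = 2) {
  axis <- match.arg(axis)
  mat <- if (is.list(matrix) && !is.data.frame(matrix)) matrix$values else matrix
  if (axis == "columns") mat <- t(mat)
  if (nrow(mat) < 2) fm_domain_error("need at least 2 items to cluster")
  hclust(fm_pairwise_dist(mat, min_overlap = min_overlap), method = linkage)
}
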
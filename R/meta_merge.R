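## Cross-study merging: directionality consistency check, consensus
## averaging, and multi-source overlap selection.

#' Cross-study consistency check and consensus merging
#'
#' Within one patient group, a molecular cluster reported with the same
#' direction by every supporting study is merged into a single consensus
#' feature whose `mean_ratio` is the arithmetic mean of the supporting
#' ratios. A cluster observed with both directions across studies is a
#' contradiction: it is excluded from the consensus and reported in the
#' `removed` list. Consensus clusters and removed clusters always partition
#' the distinct input clusters. Groups (naive vs ERT) are never merged with
#' each other.
#'
#' @param features thresholded per-study feature tibble (see
#'   [apply_thresholds()]).
#' @param studies study tibble supplying fluid and group per study.
#' @param group which patient group to merge: `"naive"` or `"ERT"`.
#' @return list with `consensus` (tibble: cluster_id, group, mean_ratio,
#'   direction, n_studies, fluids, study_ids, tag, sorted by cluster_id) and
#'   `removed` (tibble of contradictory clusters with their per-direction
#'   study counts).
#' @export
consistency_merge <- function(features, studies, group) {
  group <- match.arg(group, fm_groups)
  fm_require_columns(features, c("cluster_id", "study_id", "ratio", "p_value"),
                     "features")
  if (!"tag" %in% names(features)) features$tag <- NA_character_
  meta <- studies[c("study_id", "fluid", "group")]
  df <- dplyr::inner_join(features, meta, by = "study_id",
                          relationship = "many-to-one")
  df <- df[df$group == group, , drop = FALSE]
  if (nrow(df) == 0) {
    empty_consensus <- tibble::tibble(
      cluster_id = character(), group = character(), mean_ratio = double(),
      direction = character(), n_studies = integer(), fluids = character(),
      study_ids = list(), tag = character())
    empty_removed <- tibble::tibble(cluster_id = character(),
                                    n_up = integer(), n_down = integer())
    return(list(consensus = empty_consensus, removed = empty_removed))
  }
  df$direction <- fm_direction(df$ratio)
  per_cluster <- dplyr::summarise(
    dplyr::group_by(df, .data$cluster_id),
    n_up = sum(.data$direction == "up"),
    n_down = sum(.data$direction == "down"),
    mean_ratio = mean(.data$ratio),
    n_studies = dplyr::n_distinct(.data$study_id),
    fluids = paste(sort(unique(.data$fluid)), collapse = ","),
    study_ids = list(sort(unique(.data$study_id))),
    tag = .data$tag[1],
    .groups = "drop"
  )
  contradictory <- per_cluster$n_up > 0 & per_cluster$n_down > 0
  removed <- per_cluster[contradictory, c("cluster_id", "n_up", "n_down")]
  removed <- removed[order(removed$cluster_id), , drop = FALSE]
  consensus <- per_cluster[!contradictory, , drop = FALSE]
  consensus$group <- group
  consensus$direction <- fm_direction(consensus$mean_ratio)
  consensus <- consensus[order(consensus$cluster_id),
                         c("cluster_id", "group", "mean_ratio", "direction",
                           "n_studies", "fluids", "study_ids", "tag")]
  fm_log("merge", sprintf(
    "%s group: %d consensus cluster(s), %d contradictory cluster(s) removed",
    group, nrow(consensus), nrow(removed)))
  list(consensus = tibble::as_tibble(consensus),
       removed = tibble::as_tibble(removed))
}

#' Select features supported by multiple sources
#'
#' Returns the clusters whose supporting evidence spans at least
#' `min_sources` distinct units — body fluids (urine/blood, the default,
#' matching "detected in at least two tissues/fluid sources") or individual
#' studies. Output is sorted by descending support, ties broken by
#' cluster_id, so repeated runs are byte-identical.
#'
#' @param features per-study feature tibble (thresholded; both groups).
#' @param studies study tibble supplying fluid per study.
#' @param min_sources minimum number of distinct supporting units (>= 1;
#'   default 2).
#' @param granularity `"fluid"` (default) or `"study"`.
#' @return tibble with columns `cluster_id`, `n_sources`.
#' @export
find_overlaps <- function(features, studies, min_sources = 2,
                          granularity = c("fluid", "study")) {
  granularity <- match.arg(granularity)
  if (!is.numeric(min_sources) || length(min_sources) != 1 || min_sources < 1) {
    fm_config_error("min_sources must be a single integer >= 1")
  }
  if (nrow(features) == 0) {
    return(tibble::tibble(cluster_id = character(), n_sources = integer()))
  }
  fm_require_columns(features, c("cluster_id", "study_id"), "features")
  df <- dplyr::inner_join(features, studies[c("study_id", "fluid")],
                          by = "study_id", relationship = "many-to-one")
  unit <- if (granularity == "fluid") df$fluid else df$study_id
  counts <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(cluster_id = df$cluster_id, unit = unit),
                    .data$cluster_id),
    n_sources = dplyr::n_distinct(.data$unit), .groups = "drop")
  out <- counts[counts$n_sources >= min_sources, , drop = FALSE]
  out <- out[order(-out$n_sources, out$cluster_id), , drop = FALSE]
  fm_log("merge", sprintf(
    "overlap selection (%s granularity, >= %d sources): %d cluster(s)",
    granularity, min_sources, nrow(out)))
  tibble::as_tibble(out)
}
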
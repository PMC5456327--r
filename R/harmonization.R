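## Harmonisation: alias -> cluster mapping, within-study collapsing of
## redundant entries, and platform-specific plus global significance filters.

#' Significance threshold configuration
#'
#' Fold-change thresholds are applied to the magnitude `max(r, 1/r)` of a
#' case/control ratio `r`, so up- and down-regulation are treated
#' symmetrically. The effective threshold for a feature is the larger of its
#' platform threshold and the global threshold.
#'
#' @param fc_transcriptomics fold-change threshold for transcriptomics
#'   platforms (default 2.0).
#' @param fc_prot_metab fold-change threshold for proteomics, peptidomics and
#'   metabolomics platforms (default 1.3).
#' @param fc_global global fold-change threshold applied to every platform
#'   (default 1.4, i.e. a 40% increase or decrease).
#' @param p_max p-value cutoff; features must satisfy `p_value < p_max`
#'   (default 0.05).
#' @return a list of class `fm_threshold_config`.
#' @export
threshold_config <- function(fc_transcriptomics = 2.0, fc_prot_metab = 1.3,
                             fc_global = 1.4, p_max = 0.05) {
  fcs <- c(fc_transcriptomics = fc_transcriptomics,
           fc_prot_metab = fc_prot_metab, fc_global = fc_global)
  if (any(!is.finite(fcs)) || any(fcs <= 1)) {
    fm_config_error("all fold-change thresholds must be finite and > 1")
  }
  if (!is.finite(p_max) || p_max <= 0 || p_max >= 1) {
    fm_config_error("p_max must lie strictly between 0 and 1")
  }
  structure(list(fc_transcriptomics = fc_transcriptomics,
                 fc_prot_metab = fc_prot_metab,
                 fc_global = fc_global, p_max = p_max),
            class = "fm_threshold_config")
}

#' Map raw identifiers to non-redundant molecular clusters
#'
#' Published identifiers (symbols, accessions, probe ids) are resolved
#' against the alias map; measurements whose `raw_id` is absent from the map
#' are routed to an `unmapped` side list (a normal outcome, not an error) so
#' the mapping funnel stays auditable.
#'
#' @param measurements measurement tibble (see [read_measurements()]).
#' @param alias_map alias tibble (see [read_alias_map()]).
#' @return list with `mapped` (measurements plus `cluster_id` and `tag`
#'   columns) and `unmapped` (the remaining measurements). The two row counts
#'   always sum to the input count.
#' @export
map_identifiers <- function(measurements, alias_map) {
  fm_require_columns(measurements, c("study_id", "raw_id", "ratio", "p_value"),
                     "measurements")
  hit <- measurements$raw_id %in% alias_map$raw_id
  mapped <- dplyr::inner_join(measurements, alias_map,
                              by = "raw_id", relationship = "many-to-one")
  unmapped <- measurements[!hit, , drop = FALSE]
  fm_log("harmonize", sprintf(
    "identifier mapping: %d of %d measurement(s) mapped to %d cluster(s); %d unmapped",
    nrow(mapped), nrow(measurements), dplyr::n_distinct(mapped$cluster_id),
    nrow(unmapped)))
  list(mapped = tibble::as_tibble(mapped), unmapped = tibble::as_tibble(unmapped))
}

## Fisher's combination of p-values (chi-square on 2k df); exact zeros are
## propagated as zero.
fm_fisher_combine <- function(p) {
  if (any(p == 0)) return(0)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Collapse redundant entries within each study
#'
#' Repeated reports of the same molecular cluster within one study (multiple
#' aliases, multiple probes) are combined into a single record whose ratio is
#' the arithmetic mean of the group's ratios. Groups whose members disagree
#' on direction (some above 1, some below) are dropped with a logged warning
#' rather than averaged across a contradiction. The operation is idempotent.
#'
#' @param mapped measurement tibble carrying `cluster_id` (and optionally
#'   `tag`) columns.
#' @param p_combine how to merge the group's p-values: `"min"` (default,
#'   keeps the strongest evidence) or `"fisher"` (Fisher's combination).
#' @param ratio_mean `"arithmetic"` (default) or `"geometric"`; the two can
#'   only differ in magnitude, never in direction, because direction
#'   conflicts are removed first.
#' @return list with `features` (one row per `(cluster_id, study_id)`:
#'   cluster_id, study_id, ratio, p_value, direction, tag) and `dropped`
#'   (tibble of direction-conflicted groups).
#' @export
collapse_within_study <- function(mapped, p_combine = c("min", "fisher"),
                                  ratio_mean = c("arithmetic", "geometric")) {
  p_combine <- match.arg(p_combine)
  ratio_mean <- match.arg(ratio_mean)
  fm_require_columns(mapped, c("study_id", "cluster_id", "ratio", "p_value"),
                     "mapped measurements")
  if (!"tag" %in% names(mapped)) mapped$tag <- NA_character_

  grouped <- dplyr::group_by(mapped, .data$study_id, .data$cluster_id)
  collapsed <- dplyr::summarise(
    grouped,
    n_dir = dplyr::n_distinct(fm_direction(.data$ratio)),
    ratio = if (ratio_mean == "arithmetic") mean(.data$ratio)
            else exp(mean(log(.data$ratio))),
    p_value = if (p_combine == "min") min(.data$p_value)
              else fm_fisher_combine(.data$p_value),
    tag = .data$tag[1],
    .groups = "drop"
  )
  conflicted <- collapsed$n_dir > 1
  dropped <- collapsed[conflicted, c("study_id", "cluster_id"), drop = FALSE]
  if (nrow(dropped) > 0) {
    fm_log("harmonize", sprintf(
      "within-study collapse: dropped %d group(s) with conflicting directions",
      nrow(dropped)))
  }
  features <- collapsed[!conflicted, , drop = FALSE]
  features$direction <- fm_direction(features$ratio)
  features <- features[order(features$cluster_id, features$study_id),
                       c("cluster_id", "study_id", "ratio", "p_value",
                         "direction", "tag")]
  list(features = tibble::as_tibble(features),
       dropped = tibble::as_tibble(dropped))
}

fm_platform_threshold <- function(platform, config) {
  ifelse(platform == "transcriptomics",
         config$fc_transcriptomics, config$fc_prot_metab)
}

#' Apply platform-specific and global significance thresholds
#'
#' A feature is retained iff `p_value < p_max` and its fold-change magnitude
#' `max(r, 1/r)` reaches both its platform threshold and the global
#' threshold, i.e. the larger of the two. Filtering is monotone in every
#' threshold and symmetric under `r -> 1/r`.
#'
#' @param features harmonized feature tibble (see [collapse_within_study()]).
#' @param studies study tibble supplying each study's platform.
#' @param config a [threshold_config()].
#' @return the retained rows of `features`, with `platform` and
#'   `fc_magnitude` columns added.
#' @export
apply_thresholds <- function(features, studies, config = threshold_config()) {
  stopifnot(inherits(config, "fm_threshold_config"))
  fm_require_columns(features, c("cluster_id", "study_id", "ratio", "p_value"),
                     "features")
  unknown <- setdiff(unique(features$study_id), studies$study_id)
  if (length(unknown) > 0) {
    fm_reference_error(sprintf("features reference unknown study_id: %s",
                               paste(unknown, collapse = ", ")))
  }
  platform <- setNames(studies$platform, studies$study_id)[features$study_id]
  magnitude <- fc_magnitude(features$ratio)
  effective <- pmax(fm_platform_threshold(platform, config), config$fc_global)
  keep <- features$p_value < config$p_max & magnitude >= effective
  out <- features
  out$platform <- platform
  out$fc_magnitude <- magnitude
  out <- out[keep, , drop = FALSE]
  fm_log("harmonize", sprintf(
    "thresholding: %d of %d feature(s) pass p < %s and fold-change filters",
    nrow(out), nrow(features), format(config$p_max)))
  tibble::as_tibble(out)
}
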
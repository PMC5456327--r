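## End-to-end orchestration: harmonization -> consensus merging -> tag
## summaries -> enrichment -> clustering -> disease/regulatory overlays,
## from one configuration, with per-stage artifacts and a run report.

#' Pipeline run configuration
#'
#' Inputs may be given as file paths (read with the package readers) or as
#' already-loaded objects; file paths are validated at configuration time.
#' Every analysis threshold is carried here so the run report can echo the
#' exact parameters used. All analysis stages are deterministic; the seed
#' only matters when the configuration is used to drive synthetic data.
#'
#' @param measurements measurement table path or tibble.
#' @param studies study table path or tibble.
#' @param alias_map alias map path or tibble.
#' @param gene_sets optional GMT path or named list of gene sets.
#' @param disease_table optional disease association path or tibble.
#' @param edge_files optional character vector of regulatory edge files, or
#'   an edge tibble.
#' @param outdir optional output directory for stage artifacts.
#' @param thresholds a [threshold_config()].
#' @param enrichment an [enrichment_config()].
#' @param min_sources,overlap_granularity overlap selection settings (see
#'   [find_overlaps()]).
#' @param linkage clustering linkage method (see [hcluster()]).
#' @param min_networks regulatory overlay network minimum (see
#'   [regulatory_overlay()]).
#' @param seed integer seed recorded in the report.
#' @return a list of class `fm_run_config`.
#' @export
run_config <- function(measurements, studies, alias_map,
                       gene_sets = NULL, disease_table = NULL,
                       edge_files = NULL, outdir = NULL,
                       thresholds = threshold_config(),
                       enrichment = enrichment_config(),
                       min_sources = 2,
                       overlap_granularity = c("fluid", "study"),
                       linkage = "average", min_networks = 2, seed = 1L) {
  overlap_granularity <- match.arg(overlap_granularity)
  if (!is.numeric(seed) || length(seed) != 1 || seed != as.integer(seed)) {
    fm_config_error("seed must be a single integer")
  }
  for (inp in list(measurements, studies, alias_map, gene_sets,
                   disease_table, edge_files)) {
    if (is.character(inp)) {
      missing <- inp[!file.exists(inp)]
      if (length(missing) > 0) {
        fm_config_error(sprintf("input file not found: %s",
                                paste(missing, collapse = ", ")))
      }
    }
  }
  structure(list(measurements = measurements, studies = studies,
                 alias_map = alias_map, gene_sets = gene_sets,
                 disease_table = disease_table, edge_files = edge_files,
                 outdir = outdir, thresholds = thresholds,
                 enrichment = enrichment, min_sources = min_sources,
                 overlap_granularity = overlap_granularity,
                 linkage = linkage, min_networks = min_networks,
                 seed = as.integer(seed)),
            class = "fm_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the [run_config()] arguments; threshold keys
#' (`fc_transcriptomics`, `fc_prot_metab`, `fc_global`, `p_max`,
#' `kappa_threshold`, `alpha`, `z_cutoff`) populate the nested configs.
#' Relative input paths are resolved against the YAML file's directory.
#'
#' @param path path to the YAML configuration.
#' @return a `fm_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) fm_config_error(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  }
  thr <- threshold_config(
    fc_transcriptomics = y$fc_transcriptomics %||% 2.0,
    fc_prot_metab = y$fc_prot_metab %||% 1.3,
    fc_global = y$fc_global %||% 1.4,
    p_max = y$p_max %||% 0.05)
  enr <- enrichment_config(
    kappa_threshold = y$kappa_threshold %||% 0.4,
    alpha = y$alpha %||% 0.05,
    z_cutoff = y$z_cutoff %||% 1.6449)
  run_config(
    measurements = resolve(y$measurements), studies = resolve(y$studies),
    alias_map = resolve(y$alias_map), gene_sets = resolve(y$gene_sets),
    disease_table = resolve(y$disease_table),
    edge_files = resolve(unlist(y$edge_files)),
    outdir = y$outdir, thresholds = thr, enrichment = enr,
    min_sources = y$min_sources %||% 2,
    overlap_granularity = y$overlap_granularity %||% "fluid",
    linkage = y$linkage %||% "average",
    min_networks = y$min_networks %||% 2,
    seed = y$seed %||% 1L)
}

fm_load_input <- function(x, reader, ...) {
  if (is.null(x) || !is.character(x)) return(x)
  reader(x, ...)
}

#' Run the full meta-analysis pipeline
#'
#' Executes, in order: identifier mapping, within-study collapsing,
#' significance thresholding, per-group consistency merging, functionality
#' tag summaries, gene-set enrichment with kappa term grouping and pathway
#' Z-scores, overlap selection and fold-change clustering, and disease /
#' regulatory overlays. Identical configuration and inputs give identical
#' outputs. When `outdir` is set, each stage's table is written as TSV.
#'
#' @param config a [run_config()] or the path to a YAML configuration.
#' @return a list of class `fm_run_report`: `parameters` (every threshold
#'   used), `funnel` (stage-by-stage record counts), per-group results
#'   (`consensus`, `removed`, `tags`, `enrichment`, `term_groups`,
#'   `zscores`, `diseases`, `overlay`), `overlap`, `matrix`, `trees`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "fm_run_config"))

  studies <- fm_load_input(config$studies, read_study_table)
  meas <- if (is.character(config$measurements)) {
    read_measurements(config$measurements, studies)$measurements
  } else config$measurements
  alias_map <- fm_load_input(config$alias_map, read_alias_map)
  gene_sets <- fm_load_input(config$gene_sets, read_gmt)
  disease_table <- fm_load_input(config$disease_table, read_disease_table)
  edges <- fm_load_input(config$edge_files, read_edges)

  ## B: harmonisation
  mapping <- map_identifiers(meas, alias_map)
  collapsed <- collapse_within_study(mapping$mapped)
  thresholded <- apply_thresholds(collapsed$features, studies, config$thresholds)

  ## C: cross-study merging, per group
  groups <- intersect(fm_groups, unique(studies$group))
  merged <- lapply(groups, function(g) consistency_merge(thresholded, studies, g))
  names(merged) <- groups

  per_group <- lapply(groups, function(g) {
    consensus <- merged[[g]]$consensus
    res <- list(consensus = consensus, removed = merged[[g]]$removed)
    res$tags <- if (nrow(consensus) > 0) summarize_tags(consensus, g) else NULL
    if (!is.null(gene_sets) && nrow(consensus) > 0) {
      directions <- setNames(consensus$direction, consensus$cluster_id)
      res$enrichment <- enrich_terms(consensus$cluster_id, gene_sets,
                                     directions = directions,
                                     config = config$enrichment)
      res$term_groups <- group_terms(res$enrichment, config$enrichment)
      res$zscores <- pathway_zscores(consensus$cluster_id, gene_sets,
                                     config = config$enrichment)
    }
    if (!is.null(disease_table) && nrow(consensus) > 0) {
      res$diseases <- rank_shared_genes(consensus$cluster_id, disease_table)
    }
    if (!is.null(edges) && nrow(consensus) > 0) {
      res$overlay <- regulatory_overlay(consensus$cluster_id, edges,
                                        min_networks = config$min_networks)
    }
    res
  })
  names(per_group) <- groups

  ## D: overlap selection and fold-change clustering (across all studies,
  ## restricted to consistently regulated clusters)
  group_of <- setNames(studies$group, studies$study_id)
  removed_pairs <- dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(cluster_id = merged[[g]]$removed$cluster_id, group = g)
  }))
  consistent <- thresholded[!paste(thresholded$cluster_id,
                                   group_of[thresholded$study_id]) %in%
                              paste(removed_pairs$cluster_id,
                                    removed_pairs$group), , drop = FALSE]
  overlap <- find_overlaps(consistent, studies,
                           min_sources = config$min_sources,
                           granularity = config$overlap_granularity)
  mat <- NULL; trees <- NULL
  if (nrow(overlap) >= 2) {
    mat <- tryCatch(build_matrix(consistent, overlap, studies),
                    fabrymeta_error = function(e) NULL)
    if (!is.null(mat) && nrow(mat$values) >= 2) {
      trees <- tryCatch(
        list(rows = hcluster(mat, "rows", linkage = config$linkage),
             columns = if (ncol(mat$values) >= 2)
               hcluster(mat, "columns", linkage = config$linkage) else NULL),
        fabrymeta_error = function(e) NULL)
    }
  }

  removed_total <- sum(vapply(merged, function(m) nrow(m$removed), integer(1)))
  consensus_total <- sum(vapply(merged, function(m) nrow(m$consensus), integer(1)))
  funnel <- tibble::tibble(
    stage = c("input_measurements", "mapped", "unmapped",
              "collapsed_features", "dropped_within_study",
              "thresholded_features", "consensus_clusters",
              "removed_contradictions", "overlapping_clusters"),
    n = c(nrow(meas), nrow(mapping$mapped), nrow(mapping$unmapped),
          nrow(collapsed$features), nrow(collapsed$dropped),
          nrow(thresholded), consensus_total, removed_total, nrow(overlap)))

  direction_totals <- dplyr::bind_rows(lapply(groups, function(g) {
    cons <- merged[[g]]$consensus
    in_group <- thresholded$study_id %in% studies$study_id[studies$group == g]
    tibble::tibble(group = g,
                   n_input_clusters = dplyr::n_distinct(
                     thresholded$cluster_id[in_group]),
                   n_consensus = nrow(cons),
                   n_up = sum(cons$direction == "up"),
                   n_down = sum(cons$direction == "down"),
                   n_removed = nrow(merged[[g]]$removed))
  }))

  parameters <- list(
    fc_transcriptomics = config$thresholds$fc_transcriptomics,
    fc_prot_metab = config$thresholds$fc_prot_metab,
    fc_global = config$thresholds$fc_global,
    p_max = config$thresholds$p_max,
    kappa_threshold = config$enrichment$kappa_threshold,
    alpha = config$enrichment$alpha,
    z_cutoff = config$enrichment$z_cutoff,
    min_sources = config$min_sources,
    overlap_granularity = config$overlap_granularity,
    linkage = config$linkage, min_networks = config$min_networks,
    seed = config$seed)

  report <- structure(list(parameters = parameters, funnel = funnel,
                           direction_totals = direction_totals,
                           groups = per_group, overlap = overlap,
                           matrix = mat, trees = trees,
                           unmapped = mapping$unmapped),
                      class = "fm_run_report")
  if (!is.null(config$outdir)) fm_write_report(report, config$outdir)
  report
}

## serialise every tabular stage output under outdir
fm_write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_table(report$funnel, file.path(outdir, "funnel.tsv"))
  write_table(report$direction_totals, file.path(outdir, "direction_totals.tsv"))
  write_table(report$overlap, file.path(outdir, "overlap.tsv"))
  params <- tibble::tibble(parameter = names(report$parameters),
                           value = vapply(report$parameters, function(x)
                             paste(format(x), collapse = ","), character(1)))
  write_table(params, file.path(outdir, "parameters.tsv"))
  flatten <- function(df) {
    listcols <- vapply(df, is.list, logical(1))
    for (nm in names(df)[listcols]) {
      df[[nm]] <- vapply(df[[nm]], function(x)
        paste(x, collapse = ","), character(1))
    }
    df
  }
  for (g in names(report$groups)) {
    res <- report$groups[[g]]
    for (nm in c("consensus", "removed", "tags", "enrichment",
                 "term_groups", "zscores", "diseases")) {
      if (!is.null(res[[nm]])) {
        write_table(flatten(res[[nm]]),
                    file.path(outdir, sprintf("%s_%s.tsv", g, nm)))
      }
    }
    if (!is.null(res$overlay) && nrow(res$overlay$edges) > 0) {
      write_table(res$overlay$edges,
                  file.path(outdir, sprintf("%s_overlay_edges.tsv", g)))
      write_sif(res$overlay$edges,
                file.path(outdir, sprintf("%s_overlay.sif", g)))
    }
  }
  if (!is.null(report$matrix)) {
    mat_df <- tibble::as_tibble(report$matrix$values, rownames = "cluster_id")
    write_table(mat_df, file.path(outdir, "expression_matrix.tsv"))
  }
  invisible(outdir)
}

#' @export
print.fm_run_report <- function(x, ...) {
  cat("Multi-omics meta-analysis run\n")
  cat("Parameters:",
      sprintf("FC %s (transcriptomics) / %s (prot+metab) / %s (global), p < %s;",
              x$parameters$fc_transcriptomics, x$parameters$fc_prot_metab,
              x$parameters$fc_global, x$parameters$p_max),
      sprintf("kappa >= %s, alpha %s, Z cutoff %s\n",
              x$parameters$kappa_threshold, x$parameters$alpha,
              x$parameters$z_cutoff))
  cat("Funnel:\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-24s %6d\n", x$funnel$stage[i], x$funnel$n[i]))
  }
  for (i in seq_len(nrow(x$direction_totals))) {
    d <- x$direction_totals[i, ]
    cat(sprintf("  %s group: %d consensus (%d up / %d down), %d contradictions removed\n",
                d$group, d$n_consensus, d$n_up, d$n_down, d$n_removed))
  }
  invisible(x)
}
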
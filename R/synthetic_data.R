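## Synthetic multi-study measurement tables with planted ground truth.
## The generator emulates published end-result tables (molecule lists with
## ratios and p-values), not instrument-level raw data: every planted signal
## lies above its platform's detection cutoff, because literature tables only
## report molecules that passed each study's own filters.

#' Default study design
#'
#' Eleven studies across two fluids (urine, blood) and two patient groups
#' (7 naive, 4 ERT), with platform and cohort-size composition mirroring the
#' curated multi-omics dataspace: proteomics, peptidomics, metabolomics and
#' transcriptomics studies, cohort sizes where published.
#'
#' @return a study design tibble usable as `study_design` in
#'   [synthetic_config()].
#' @export
default_study_design <- function() {
  tibble::tibble(
    study_id = sprintf("study%02d", 1:11),
    platform = c("proteomics", "proteomics", "transcriptomics",
                 "transcriptomics", "peptidomics", "peptidomics",
                 "metabolomics", "proteomics", "peptidomics",
                 "transcriptomics", "metabolomics"),
    fluid = c("urine", "blood", "blood", "blood", "urine", "blood",
              "urine", "blood", "urine", "blood", "urine"),
    group = c("naive", "ERT", "ERT", "naive", "naive", "naive",
              "ERT", "naive", "naive", "ERT", "naive"),
    n_case = c(11, NA, NA, NA, 20, 8, NA, 32, 35, NA, 16),
    n_control = c(12, NA, NA, NA, 10, 6, NA, 14, 89, NA, 16),
    ratio_convention = "ratio"
  )
}

#' Synthetic-data generator settings
#'
#' @param study_design study tibble (study_id, platform, fluid, group);
#'   default [default_study_design()], 11 studies over 2 fluids and 2 groups.
#' @param n_signal number of planted consistently-regulated signal clusters
#'   (default 60).
#' @param n_null number of null clusters with ratios centred at 1 and
#'   uniform p-values (default 60).
#' @param contradiction_fraction fraction (of `n_signal`) of additional
#'   clusters planted with opposing directions across studies, in `[0, 1)`
#'   (default 0.08).
#' @param min_support,max_support number of studies (within one group)
#'   supporting each planted cluster (defaults 2 and 4).
#' @param alias_max each cluster is published under 1..`alias_max` raw
#'   identifiers (default 3), emulating symbol/accession/probe redundancy.
#' @param signal_margin,signal_excess_mean,signal_excess_sd signal
#'   fold-change magnitudes are drawn per platform as
#'   `threshold * signal_margin * exp(|N(signal_excess_mean,
#'   signal_excess_sd)|)` where `threshold` is the platform's detection
#'   cutoff (the larger of the platform and global fold-change thresholds),
#'   so transcriptomics signals typically exceed FC 2 and
#'   proteomics/metabolomics signals FC 1.4.
#' @param alias_jitter log-scale standard deviation of the jitter between
#'   aliases of one cluster within one study (default 0.02).
#' @param null_sdlog log-scale spread of null ratios around 1 (default 0.15).
#' @param signal_p_max planted signal p-values are uniform on
#'   `(1e-8, signal_p_max)` (default 0.01); null p-values uniform on [0, 1].
#' @param thresholds a [threshold_config()] supplying the per-platform
#'   detection cutoffs that anchor the signal magnitudes.
#' @param n_terms,n_planted_terms,term_size,planted_fraction gene-set
#'   generation: number of terms (default 40), how many are planted enriched
#'   (default 5), member count range (default 8..25), and the fraction of a
#'   planted term's members drawn from true signal clusters (default 0.75;
#'   non-planted terms draw uniformly from the universe).
#' @param background_size number of additional never-measured background
#'   cluster ids included in the gene-set universe (default 300), emulating
#'   annotation collections whose terms mostly contain genes outside any
#'   given measured dataset.
#' @return a list of class `fm_synthetic_config`.
#' @export
synthetic_config <- function(study_design = default_study_design(),
                             n_signal = 60, n_null = 60,
                             contradiction_fraction = 0.08,
                             min_support = 2, max_support = 4,
                             alias_max = 3,
                             signal_margin = 1.15,
                             signal_excess_mean = 0.15,
                             signal_excess_sd = 0.25,
                             alias_jitter = 0.02,
                             null_sdlog = 0.15,
                             signal_p_max = 0.01,
                             thresholds = threshold_config(),
                             n_terms = 40, n_planted_terms = 5,
                             term_size = c(8, 25),
                             planted_fraction = 0.75,
                             background_size = 300) {
  if (!is.numeric(contradiction_fraction) || contradiction_fraction < 0 ||
      contradiction_fraction >= 1) {
    fm_config_error("contradiction_fraction must lie in [0, 1)")
  }
  if (min_support < 2) fm_config_error("min_support must be >= 2")
  if (n_signal < 0 || n_null < 0) fm_config_error("cluster counts must be >= 0")
  if (planted_fraction < 0 || planted_fraction > 1) {
    fm_config_error("planted_fraction must lie in [0, 1]")
  }
  fm_check_vocab(study_design$group, fm_groups, "group", "study_design")
  fm_check_vocab(study_design$platform, fm_platforms, "platform", "study_design")
  fm_check_vocab(study_design$fluid, fm_fluids, "fluid", "study_design")
  structure(list(study_design = study_design, n_signal = n_signal,
                 n_null = n_null,
                 contradiction_fraction = contradiction_fraction,
                 min_support = min_support, max_support = max_support,
                 alias_max = alias_max, signal_margin = signal_margin,
                 signal_excess_mean = signal_excess_mean,
                 signal_excess_sd = signal_excess_sd,
                 alias_jitter = alias_jitter, null_sdlog = null_sdlog,
                 signal_p_max = signal_p_max, thresholds = thresholds,
                 n_terms = n_terms, n_planted_terms = n_planted_terms,
                 term_size = term_size, planted_fraction = planted_fraction,
                 background_size = background_size),
            class = "fm_synthetic_config")
}

## sample() that never auto-expands a length-1 numeric vector
fm_resample <- function(x, size = 1) x[sample.int(length(x), size)]

## run code under a temporary RNG state so generation never disturbs the
## caller's random stream
fm_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## the detection cutoff anchoring a platform's published fold-changes
fm_detection_cutoff <- function(platform, thresholds) {
  pmax(fm_platform_threshold(platform, thresholds), thresholds$fc_global)
}

#' Generate synthetic multi-study measurement tables
#'
#' Produces measurement, study and alias tables in exactly the formats the
#' readers consume, plus a ground-truth record for test assertions. Planted
#' consensus clusters appear in at least two studies of one group with a
#' consistent direction; planted contradictions additionally have their
#' direction flipped in exactly one randomly chosen supporting study. Null
#' clusters have ratios centred at 1 and uniform p-values. Identical
#' `(config, seed)` give byte-identical output; a master seed derives one
#' substream seed per study.
#'
#' @param config a [synthetic_config()].
#' @param seed master integer seed.
#' @return list with `measurements`, `studies`, `alias_map` (tibbles matching
#'   [read_measurements()] / [read_alias_map()]) and `truth`, a list holding
#'   `consensus_features` (cluster_id, group, direction, mean_ratio),
#'   `contradictory_clusters` (cluster_id, group, flipped_study),
#'   `alias_groups`, `universe` (all cluster ids) and `seed`.
#' @export
generate_studies <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "fm_synthetic_config"))
  design <- config$study_design
  n_total <- config$n_signal + config$n_null +
    round(config$contradiction_fraction * config$n_signal)
  width <- max(4, nchar(as.character(max(n_total, 1))))
  cluster_ids <- sprintf(paste0("CL%0", width, "d"), seq_len(n_total))
  n_contra <- round(config$contradiction_fraction * config$n_signal)
  type <- rep(c("signal", "contradiction", "null"),
              c(config$n_signal, n_contra, config$n_null))

  plan <- fm_with_seed(seed, {
    groups_avail <- unique(design$group)
    group_sizes <- table(design$group)[groups_avail]
    ## clusters land in a group proportionally to its number of studies
    cl <- tibble::tibble(cluster_id = cluster_ids, type = type)
    cl$tag <- sample(fm_tags, n_total, replace = TRUE)
    cl$n_alias <- sample.int(config$alias_max, n_total, replace = TRUE)
    cl$group <- NA_character_
    cl$direction <- NA_character_
    planted <- which(cl$type != "null")
    eligible <- groups_avail[group_sizes >= config$min_support]
    if (length(planted) > 0 && length(eligible) == 0) {
      fm_config_error("no group has enough studies to support planted clusters")
    }
    if (length(planted) > 0) {
      cl$group[planted] <- sample(eligible, length(planted), replace = TRUE,
                                  prob = as.numeric(group_sizes[eligible]))
      cl$direction[planted] <- sample(c("up", "down"), length(planted),
                                      replace = TRUE)
    }
    assign_rows <- lapply(seq_len(n_total), function(i) {
      if (cl$type[i] == "null") {
        supp <- sample(design$study_id, sample.int(2, 1))
      } else {
        pool <- design$study_id[design$group == cl$group[i]]
        k <- fm_resample(seq(config$min_support,
                             min(config$max_support, length(pool))))
        supp <- sample(pool, k)
      }
      tibble::tibble(cluster_id = cl$cluster_id[i], study_id = supp)
    })
    assignment <- dplyr::bind_rows(assign_rows)
    flipped <- vapply(which(cl$type == "contradiction"), function(i) {
      supp <- assignment$study_id[assignment$cluster_id == cl$cluster_id[i]]
      sample(supp, 1)
    }, character(1))
    cl$flipped_study <- NA_character_
    cl$flipped_study[cl$type == "contradiction"] <- flipped
    list(clusters = cl, assignment = assignment)
  })
  cl <- plan$clusters
  assignment <- plan$assignment

  ## alias map (deterministic given the plan)
  alias_map <- dplyr::bind_rows(lapply(seq_len(n_total), function(i) {
    tibble::tibble(raw_id = paste0(cl$cluster_id[i], "_r",
                                   seq_len(cl$n_alias[i])),
                   cluster_id = cl$cluster_id[i], tag = cl$tag[i])
  }))
  if (nrow(alias_map) == 0) {
    alias_map <- tibble::tibble(raw_id = character(), cluster_id = character(),
                                tag = character())
  }

  ## per-study substreams draw the actual measurements
  cutoff <- fm_detection_cutoff(design$platform, config$thresholds)
  names(cutoff) <- design$study_id
  study_rows <- lapply(seq_len(nrow(design)), function(s) {
    sid <- design$study_id[s]
    rows_s <- assignment[assignment$study_id == sid, , drop = FALSE]
    if (nrow(rows_s) == 0) return(NULL)
    sub_seed <- (abs(seed) * 7919 + s) %% (.Machine$integer.max - 1)
    fm_with_seed(sub_seed, {
      dplyr::bind_rows(lapply(rows_s$cluster_id, function(cid) {
        info <- cl[cl$cluster_id == cid, ]
        if (info$type == "null") {
          base <- exp(rnorm(1, 0, config$null_sdlog))
          p_fun <- function(m) runif(m)
        } else {
          excess <- abs(rnorm(1, config$signal_excess_mean,
                              config$signal_excess_sd))
          magnitude <- cutoff[[sid]] * config$signal_margin * exp(excess)
          dir <- info$direction
          if (identical(info$flipped_study, sid)) {
            dir <- if (dir == "up") "down" else "up"
          }
          base <- if (dir == "up") magnitude else 1 / magnitude
          p_fun <- function(m) runif(m, 1e-8, config$signal_p_max)
        }
        m <- info$n_alias
        tibble::tibble(
          study_id = sid,
          raw_id = paste0(cid, "_r", seq_len(m)),
          ratio = base * exp(rnorm(m, 0, config$alias_jitter)),
          p_value = p_fun(m),
          cluster_id = cid)
      }))
    })
  })
  measurements <- dplyr::bind_rows(study_rows)
  if (nrow(measurements) == 0) {
    measurements <- tibble::tibble(study_id = character(), raw_id = character(),
                                   ratio = double(), p_value = double(),
                                   cluster_id = character())
  }
  measurements <- measurements[order(measurements$study_id,
                                     measurements$raw_id), , drop = FALSE]

  ## truth: planted per-study base ratios averaged within each cluster
  planted_ms <- dplyr::inner_join(
    measurements, cl[cl$type == "signal", c("cluster_id", "group", "direction")],
    by = "cluster_id")
  truth_consensus <- if (nrow(planted_ms) > 0) {
    per_study <- dplyr::summarise(
      dplyr::group_by(planted_ms, .data$cluster_id, .data$group,
                      .data$direction, .data$study_id),
      ratio = mean(.data$ratio), .groups = "drop")
    dplyr::summarise(
      dplyr::group_by(per_study, .data$cluster_id, .data$group, .data$direction),
      mean_ratio = mean(.data$ratio), n_studies = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(cluster_id = character(), group = character(),
                   direction = character(), mean_ratio = double(),
                   n_studies = integer())
  }

  truth <- list(
    consensus_features = tibble::as_tibble(truth_consensus),
    contradictory_clusters = tibble::as_tibble(
      cl[cl$type == "contradiction",
         c("cluster_id", "group", "direction", "flipped_study")]),
    alias_groups = alias_map,
    universe = cluster_ids,
    seed = seed
  )
  list(
    measurements = tibble::as_tibble(
      measurements[c("study_id", "raw_id", "ratio", "p_value")]),
    studies = design,
    alias_map = alias_map,
    truth = truth
  )
}

#' Generate a synthetic gene-set collection with planted enrichment
#'
#' Terms draw members from the cluster universe recorded in the truth
#' object, extended by `background_size` never-measured background cluster
#' ids (annotation collections mostly contain genes outside any given
#' measured dataset). A planted enriched term draws `planted_fraction` of its
#' members from the true signal clusters (and the rest from the remaining
#' universe); non-planted terms draw uniformly from the whole universe.
#'
#' @param truth the `truth` element of a [generate_studies()] result.
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `gene_sets` (named list, GMT-compatible) and
#'   `planted_terms` (character vector of the enriched term names).
#' @export
generate_gene_sets <- function(truth, config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "fm_synthetic_config"))
  universe <- truth$universe
  if (config$background_size > 0) {
    universe <- c(universe,
                  sprintf("BG%04d", seq_len(config$background_size)))
  }
  if (max(config$term_size) > length(universe)) {
    fm_config_error("term size range exceeds the universe size")
  }
  signal_pool <- truth$consensus_features$cluster_id
  fm_with_seed(seed + 104729L, {
    names_all <- sprintf("T%03d", seq_len(config$n_terms))
    planted <- sort(sample(names_all, min(config$n_planted_terms,
                                          config$n_terms)))
    gene_sets <- lapply(names_all, function(nm) {
      size <- fm_resample(seq(config$term_size[1], config$term_size[2]))
      if (nm %in% planted && length(signal_pool) > 0) {
        k_sig <- min(round(config$planted_fraction * size), length(signal_pool))
        sig <- sample(signal_pool, k_sig)
        rest <- sample(setdiff(universe, sig), size - k_sig)
        members <- sort(c(sig, rest))
      } else {
        members <- sort(sample(universe, size))
      }
      structure(members, description = "synthetic gene set")
    })
    names(gene_sets) <- names_all
    list(gene_sets = gene_sets, planted_terms = planted)
  })
}

#' Write the planted ground truth as plain-text tables
#'
#' @param truth the `truth` element of a [generate_studies()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(truth$consensus_features, file.path(dir, "truth_consensus.tsv"))
  write_table(truth$contradictory_clusters,
              file.path(dir, "truth_contradictions.tsv"))
  write_table(truth$alias_groups, file.path(dir, "truth_aliases.tsv"))
  invisible(dir)
}
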
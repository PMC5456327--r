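## Readers and writers for every external format the pipeline touches.
## One dialect everywhere: UTF-8, tab-separated, mandatory header row.
## Unknown extra columns are tolerated (curated literature tables carry
## heterogeneous annotations) but logged.

fm_read_tsv <- function(path, what) {
  if (!file.exists(path)) {
    fm_format_error(sprintf("%s file not found: %s", what, path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = c("", "NA", "N/A"))
  tibble::as_tibble(df)
}

fm_drop_extra_columns <- function(df, keep, what) {
  extra <- setdiff(names(df), keep)
  if (length(extra) > 0) {
    fm_log("io", sprintf("%s: ignoring %d unrecognised column(s): %s",
                         what, length(extra), paste(extra, collapse = ", ")))
  }
  df[intersect(keep, names(df))]
}

fm_parse_numeric <- function(x, column, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    fm_validation_error(sprintf("%s: column '%s' is not numeric at row %s",
                                what, column, paste(bad, collapse = ", ")))
  }
  out
}

#' Read a study metadata table
#'
#' One row per study: `study_id`, `platform` (transcriptomics, proteomics,
#' peptidomics or metabolomics), `fluid` (urine or blood), `group` (naive or
#' ERT), and optional cohort sizes `n_case` / `n_control`. An optional
#' `ratio_convention` column (`ratio`, the default, or `signed_fc`) declares
#' how that study's expression values are encoded; under `signed_fc` a value
#' of -2 means halved expression and is converted to the ratio 0.5 on read.
#'
#' @param path path to a tab-separated study table with a header row.
#' @return a tibble of study records.
#' @export
read_study_table <- function(path) {
  df <- fm_read_tsv(path, "study table")
  fm_require_columns(df, c("study_id", "platform", "fluid", "group"), "study table")
  keep <- c("study_id", "platform", "fluid", "group", "n_case", "n_control",
            "ratio_convention")
  df <- fm_drop_extra_columns(df, keep, "study table")
  if (!"n_case" %in% names(df)) df$n_case <- NA_character_
  if (!"n_control" %in% names(df)) df$n_control <- NA_character_
  if (!"ratio_convention" %in% names(df)) df$ratio_convention <- "ratio"
  df$ratio_convention[is.na(df$ratio_convention)] <- "ratio"
  fm_check_vocab(df$platform, fm_platforms, "platform", "study table")
  fm_check_vocab(df$fluid, fm_fluids, "fluid", "study table")
  fm_check_vocab(df$group, fm_groups, "group", "study table")
  fm_check_vocab(df$ratio_convention, c("ratio", "signed_fc"),
                 "ratio_convention", "study table")
  if (anyDuplicated(df$study_id)) {
    dup <- unique(df$study_id[duplicated(df$study_id)])
    fm_validation_error(sprintf("study table: duplicated study_id: %s",
                                paste(dup, collapse = ", ")))
  }
  df$n_case <- fm_parse_numeric(df$n_case, "n_case", "study table")
  df$n_control <- fm_parse_numeric(df$n_control, "n_control", "study table")
  tibble::as_tibble(df)
}

## signed fold-change -> positive case/control ratio: -x (x >= 1) means 1/x
fm_convert_signed_fc <- function(x, rows, what) {
  bad <- which(abs(x) < 1)
  if (length(bad) > 0) {
    fm_validation_error(sprintf(
      "%s: signed fold-change must have magnitude >= 1; offending row %s",
      what, paste(rows[bad], collapse = ", ")))
  }
  ifelse(x < 0, 1 / abs(x), x)
}

#' Read molecule measurement tables
#'
#' Reads a measurement file (columns `study_id`, `raw_id`, `ratio`,
#' `p_value`) together with its study metadata table and joins the two on
#' `study_id`. Repeated `(study_id, raw_id)` pairs are expected input
#' (redundant published entries) and pass through untouched; harmonisation
#' collapses them later. For studies declared `signed_fc` in the study table
#' the ratio column is converted to a positive case/control ratio on read.
#'
#' @param path path to the tab-separated measurement file.
#' @param study_table path to the study metadata file (see
#'   [read_study_table()]), or an already-read study tibble.
#' @param on_invalid `"error"` (default) stops at the first row violating the
#'   ratio/p-value invariants, citing its row number; `"reject"` drops such
#'   rows, logs the count, and returns them in the `rejected` element.
#' @return a list with elements `measurements` (tibble: study_id, raw_id,
#'   ratio, p_value), `studies` (tibble of study records) and `rejected`
#'   (tibble of dropped rows with a `reason` column).
#' @export
read_measurements <- function(path, study_table, on_invalid = c("error", "reject")) {
  on_invalid <- match.arg(on_invalid)
  studies <- if (is.character(study_table)) read_study_table(study_table) else study_table
  df <- fm_read_tsv(path, "measurement table")
  fm_require_columns(df, c("study_id", "raw_id", "ratio", "p_value"),
                     "measurement table")
  df <- fm_drop_extra_columns(df, c("study_id", "raw_id", "ratio", "p_value"),
                              "measurement table")
  df$.row <- seq_len(nrow(df))
  unknown <- setdiff(unique(df$study_id), studies$study_id)
  if (length(unknown) > 0) {
    fm_reference_error(sprintf(
      "measurement table: study_id not present in study table: %s",
      paste(unknown, collapse = ", ")))
  }
  df$ratio <- fm_parse_numeric(df$ratio, "ratio", "measurement table")
  df$p_value <- fm_parse_numeric(df$p_value, "p_value", "measurement table")

  convention <- setNames(studies$ratio_convention %||% rep("ratio", nrow(studies)),
                         studies$study_id)
  signed <- convention[df$study_id] == "signed_fc"
  if (any(signed)) {
    df$ratio[signed] <- fm_convert_signed_fc(df$ratio[signed], df$.row[signed],
                                             "measurement table")
  }

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$ratio) | df$ratio <= 0] <- "ratio must be > 0"
  reason[is.na(df$p_value) | df$p_value < 0 | df$p_value > 1] <-
    "p_value must lie in [0, 1]"
  bad <- which(!is.na(reason))
  if (length(bad) > 0 && on_invalid == "error") {
    fm_validation_error(sprintf("measurement table row %d: %s",
                                df$.row[bad[1]], reason[bad[1]]))
  }
  rejected <- df[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  if (length(bad) > 0) {
    df <- df[-bad, , drop = FALSE]
    fm_log("io", sprintf("rejected %d invalid measurement row(s); %d retained",
                         length(bad), nrow(df)))
  }
  list(
    measurements = tibble::as_tibble(df[c("study_id", "raw_id", "ratio", "p_value")]),
    studies = studies,
    rejected = tibble::as_tibble(rejected[c(".row", "study_id", "raw_id",
                                            "ratio", "p_value", "reason")])
  )
}

#' Read an identifier alias map
#'
#' Maps free-text published identifiers (gene symbols, protein accessions,
#' probe ids) to non-redundant molecular cluster labels, each carrying one
#' coarse functionality tag. Exact duplicate rows are collapsed; a `raw_id`
#' claiming two different clusters, or a cluster carrying two different tags,
#' is an error.
#'
#' @param path tab-separated file with columns `raw_id`, `cluster_id`, `tag`.
#' @return tibble with one row per distinct raw_id.
#' @export
read_alias_map <- function(path) {
  df <- fm_read_tsv(path, "alias map")
  fm_require_columns(df, c("raw_id", "cluster_id", "tag"), "alias map")
  df <- fm_drop_extra_columns(df, c("raw_id", "cluster_id", "tag"), "alias map")
  df <- dplyr::distinct(df)
  fm_check_vocab(df$tag, fm_tags, "functionality tag", "alias map")
  dup_raw <- unique(df$raw_id[duplicated(df$raw_id)])
  if (length(dup_raw) > 0) {
    fm_validation_error(sprintf(
      "alias map: raw_id mapped to more than one cluster: %s",
      paste(dup_raw, collapse = ", ")))
  }
  tag_per_cluster <- dplyr::distinct(df, .data$cluster_id, .data$tag)
  dup_tag <- unique(tag_per_cluster$cluster_id[duplicated(tag_per_cluster$cluster_id)])
  if (length(dup_tag) > 0) {
    fm_validation_error(sprintf(
      "alias map: cluster with more than one functionality tag: %s",
      paste(dup_tag, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>member...`.
#' Duplicate members within a line are deduplicated; a line with fewer than
#' three fields or no non-empty member is a format error naming the line.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of members; each element carries
#'   a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) fm_format_error(sprintf("GMT file not found: %s", path))
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      fm_format_error(sprintf("GMT line %d: expected at least 3 tab-separated fields", i))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      fm_format_error(sprintf("GMT line %d: gene set '%s' has no members", i, fields[[1]]))
    }
    if (fields[[1]] %in% names(sets)) {
      fm_format_error(sprintf("GMT line %d: duplicated set name '%s'", i, fields[[1]]))
    }
    sets[[fields[[1]]]] <- structure(members, description = fields[[2]])
  }
  sets
}

#' Write gene sets in GMT format
#'
#' @param gene_sets named list of member vectors (optionally with a
#'   `description` attribute per element, defaulting to the set name).
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    desc <- attr(gene_sets[[nm]], "description") %||% nm
    paste(c(nm, desc, as.character(gene_sets[[nm]])), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read regulator-target edge tables
#'
#' Each file is one regulatory interaction network (RegIN): tab-separated
#' columns `regulator`, `target`, `network_id`, `kind` (miRNA or TF). Edges
#' are deduplicated on (regulator, target, network_id); a regulator appearing
#' with two different kinds is an error.
#'
#' @param paths one or more edge file paths; rows are concatenated.
#' @return tibble of deduplicated edges.
#' @export
read_edges <- function(paths) {
  dfs <- lapply(paths, function(path) {
    df <- fm_read_tsv(path, "edge table")
    fm_require_columns(df, c("regulator", "target", "network_id", "kind"),
                       "edge table")
    fm_drop_extra_columns(df, c("regulator", "target", "network_id", "kind"),
                          "edge table")
  })
  df <- dplyr::bind_rows(dfs)
  fm_check_vocab(df$kind, fm_reg_kinds, "regulator kind", "edge table")
  n0 <- nrow(df)
  df <- dplyr::distinct(df, .data$regulator, .data$target, .data$network_id,
                        .keep_all = TRUE)
  if (nrow(df) < n0) {
    fm_log("io", sprintf("edge table: removed %d duplicated edge(s)", n0 - nrow(df)))
  }
  kinds <- dplyr::distinct(df, .data$regulator, .data$kind)
  dup <- unique(kinds$regulator[duplicated(kinds$regulator)])
  if (length(dup) > 0) {
    fm_validation_error(sprintf(
      "edge table: regulator listed with conflicting kinds: %s",
      paste(dup, collapse = ", ")))
  }
  tibble::as_tibble(df)
}

#' Read a disease-gene association table
#'
#' Local flat-file stand-in for a disease-gene database export: tab-separated
#' columns `disease_name` and `genes` (comma-separated gene/cluster list).
#'
#' @param path path to the table.
#' @return tibble with columns `disease_name` and `gene_set` (list column of
#'   character vectors).
#' @export
read_disease_table <- function(path) {
  df <- fm_read_tsv(path, "disease table")
  fm_require_columns(df, c("disease_name", "genes"), "disease table")
  df <- fm_drop_extra_columns(df, c("disease_name", "genes"), "disease table")
  gene_set <- lapply(strsplit(df$genes, ","), function(g) {
    g <- unique(trimws(g))
    g[nzchar(g)]
  })
  empty <- which(lengths(gene_set) == 0)
  if (length(empty) > 0) {
    fm_validation_error(sprintf("disease table row %s: empty gene set",
                                paste(empty, collapse = ", ")))
  }
  tibble::tibble(disease_name = df$disease_name, gene_set = gene_set)
}

#' Write a tab-separated table
#'
#' Thin wrapper around [readr::write_tsv()] so every artifact the pipeline
#' emits shares one dialect (UTF-8, tab-separated, header row).
#'
#' @param df data frame to write.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Export edges as a SIF network file
#'
#' Simple interaction format: `source<TAB>relation<TAB>target`, one edge per
#' line, suitable for Cytoscape-style network tools.
#'
#' @param edges tibble with columns `regulator`, `target` and (optionally)
#'   `kind`, used as the relation label (default `"regulates"`).
#' @param path output path.
#' @export
write_sif <- function(edges, path) {
  relation <- if ("kind" %in% names(edges)) edges$kind else
    rep("regulates", nrow(edges))
  lines <- paste(edges$regulator, relation, edges$target, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
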
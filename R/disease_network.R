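## Shared-gene disease ranking against a local disease-gene table, and
## regulator-target overlay with the minimum-two-networks rule.

#' Rank diseases by shared genes with a query
#'
#' For each disease in a local disease-gene association table, counts the
#' genes it shares with the query. Diseases sharing nothing are omitted;
#' results are sorted by descending shared count, ties broken alphabetically
#' by disease name, and each shared gene list is sorted alphabetically.
#'
#' @param query non-empty character vector of query genes/cluster ids.
#' @param diseases disease association tibble (see [read_disease_table()]).
#' @return tibble: disease_name, shared_count, shared_genes (list column),
#'   query_size.
#' @export
rank_shared_genes <- function(query, diseases) {
  query <- unique(query)
  if (length(query) == 0) fm_domain_error("query gene set is empty")
  fm_require_columns(diseases, c("disease_name", "gene_set"), "disease table")
  rows <- lapply(seq_len(nrow(diseases)), function(i) {
    shared <- sort(intersect(unique(diseases$gene_set[[i]]), query))
    if (length(shared) == 0) return(NULL)
    tibble::tibble(disease_name = diseases$disease_name[i],
                   shared_count = length(shared),
                   shared_genes = list(shared),
                   query_size = length(query))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(disease_name = character(), shared_count = integer(),
                          shared_genes = list(), query_size = integer()))
  }
  out <- out[order(-out$shared_count, out$disease_name), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Overlay regulatory edges onto a query gene set
#'
#' Restricts a collection of regulator-target edges (miRNA-target and
#' TF-target networks) to edges whose target lies in the query. Following
#' the CyTargetLinker convention, the overlay requires a minimum number of
#' distinct loaded networks (default 2); when fewer are loaded the result is
#' an empty overlay with an explanatory status, not an error.
#'
#' @param query character vector of target genes/cluster ids.
#' @param edges edge tibble (see [read_edges()]).
#' @param min_networks minimum distinct `network_id`s required (default 2).
#' @return list with `edges` (retained edge tibble), `regulators` (tibble of
#'   regulator, kind, n_targets), `n_networks` (distinct networks loaded) and
#'   `status` (`"ok"`, `"insufficient_networks"`, or `"no_targets"`).
#' @export
regulatory_overlay <- function(query, edges, min_networks = 2) {
  if (!is.numeric(min_networks) || length(min_networks) != 1 || min_networks < 1) {
    fm_config_error("min_networks must be a single integer >= 1")
  }
  fm_require_columns(edges, c("regulator", "target", "network_id", "kind"),
                     "edges")
  empty_edges <- edges[0, , drop = FALSE]
  empty_reg <- tibble::tibble(regulator = character(), kind = character(),
                              n_targets = integer())
  n_networks <- dplyr::n_distinct(edges$network_id)
  if (n_networks < min_networks) {
    fm_log("overlay", sprintf(
      "only %d regulatory network(s) loaded; %d required - returning empty overlay",
      n_networks, min_networks))
    return(list(edges = empty_edges, regulators = empty_reg,
                n_networks = n_networks, status = "insufficient_networks"))
  }
  kept <- edges[edges$target %in% unique(query), , drop = FALSE]
  kept <- kept[order(kept$regulator, kept$target, kept$network_id), , drop = FALSE]
  if (nrow(kept) == 0) {
    return(list(edges = kept, regulators = empty_reg,
                n_networks = n_networks, status = "no_targets"))
  }
  regulators <- dplyr::summarise(
    dplyr::group_by(kept, .data$regulator, .data$kind),
    n_targets = dplyr::n_distinct(.data$target), .groups = "drop")
  regulators <- regulators[order(-regulators$n_targets, regulators$regulator), ,
                           drop = FALSE]
  list(edges = tibble::as_tibble(kept),
       regulators = tibble::as_tibble(regulators),
       n_networks = n_networks, status = "ok")
}
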
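## Gene-set over-representation statistics: two-sided hypergeometric test,
## Holm (Bonferroni step-down) correction, Cohen's kappa term grouping,
## majority-direction term labels, and the MAPPFinder-style pathway Z-score.

#' Enrichment configuration
#'
#' @param kappa_threshold kappa similarity cutoff for term grouping, in
#'   `[-1, 1]` (default 0.4).
#' @param alpha significance level on Holm-adjusted p-values (default 0.05).
#' @param z_cutoff standard-normal critical value for the pathway Z-score
#'   (default 1.6449, the one-sided 5% critical value).
#' @param universe_policy `"geneset_union"` (default: the background is the
#'   union of all genes in the loaded collection) or `"explicit_list"` (the
#'   caller supplies the background).
#' @param two_sided `"doubling"` (default: twice the smaller tail, capped at
#'   1) or `"minlik"` (sum of outcomes no more likely than the observed one).
#' @param z_alternative `"greater"` (default, over-representation only) or
#'   `"two_sided"` for the Z-score significance flag.
#' @return a list of class `fm_enrichment_config`.
#' @export
enrichment_config <- function(kappa_threshold = 0.4, alpha = 0.05,
                              z_cutoff = 1.6449,
                              universe_policy = c("geneset_union", "explicit_list"),
                              two_sided = c("doubling", "minlik"),
                              z_alternative = c("greater", "two_sided")) {
  if (!is.numeric(kappa_threshold) || kappa_threshold < -1 || kappa_threshold > 1) {
    fm_config_error("kappa_threshold must lie in [-1, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    fm_config_error("alpha must lie strictly between 0 and 1")
  }
  if (!is.numeric(z_cutoff) || z_cutoff <= 0) {
    fm_config_error("z_cutoff must be > 0")
  }
  structure(list(kappa_threshold = kappa_threshold, alpha = alpha,
                 z_cutoff = z_cutoff,
                 universe_policy = match.arg(universe_policy),
                 two_sided = match.arg(two_sided),
                 z_alternative = match.arg(z_alternative)),
            class = "fm_enrichment_config")
}

fm_check_hyper_params <- function(k, n, K, N) {
  k <- fm_check_count(k, "k"); n <- fm_check_count(n, "n")
  K <- fm_check_count(K, "K"); N <- fm_check_count(N, "N")
  if (K > N || n > N) fm_domain_error("require K <= N and n <= N")
  if (k < max(0L, n + K - N) || k > min(n, K)) {
    fm_domain_error("k outside the hypergeometric support [max(0, n+K-N), min(n, K)]")
  }
  list(k = k, n = n, K = K, N = N)
}

#' Two-sided hypergeometric test
#'
#' Over/under-representation of a query of size `n` against a term of size
#' `K` inside a universe of size `N`, with overlap `k`. The default two-sided
#' p-value doubles the smaller of the two tails of the hypergeometric
#' distribution and caps at 1; `method = "minlik"` instead sums the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' @param k overlap count.
#' @param n query size within the universe.
#' @param K term size within the universe.
#' @param N universe size.
#' @param method `"doubling"` (default) or `"minlik"`.
#' @return the two-sided p-value, in `(0, 1]`.
#' @export
hypergeom_two_sided <- function(k, n, K, N, method = c("doubling", "minlik")) {
  method <- match.arg(method)
  p <- fm_check_hyper_params(k, n, K, N)
  lower <- phyper(p$k, p$K, p$N - p$K, p$n)
  upper <- phyper(p$k - 1, p$K, p$N - p$K, p$n, lower.tail = FALSE)
  if (method == "doubling") {
    return(min(1, 2 * min(lower, upper)))
  }
  support <- max(0L, p$n + p$K - p$N):min(p$n, p$K)
  pmf <- dhyper(support, p$K, p$N - p$K, p$n)
  obs <- dhyper(p$k, p$K, p$N - p$K, p$n)
  min(1, sum(pmf[pmf <= obs * (1 + 1e-7)]))
}

#' Holm (Bonferroni step-down) adjustment
#'
#' Sequentially rejective multiple-testing correction: on ascending p-values,
#' `adjusted(i) = max over j <= i of min(1, (m - j + 1) * p(j))`, mapped back
#' to the input order. Computed with [stats::p.adjust()] after domain
#' validation; adjusted values are elementwise no smaller than the raw ones
#' and preserve their ranking.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    fm_domain_error("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "holm")
}

#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the binary membership indicators of two
#' term gene sets over a finite universe: `kappa = (Po - Pe) / (1 - Pe)`
#' where `Po` is the observed agreement fraction of the 2x2 membership table
#' and `Pe` the agreement expected from its marginals. When `Pe = 1` (both
#' marginals degenerate), kappa is 1 for identical sets and 0 otherwise.
#'
#' @param members_a,members_b character vectors of members, subsets of
#'   `universe`.
#' @param universe the finite background; must contain every member.
#' @return kappa in `[-1, 1]`; symmetric in its set arguments, 1 for
#'   identical sets.
#' @export
term_kappa <- function(members_a, members_b, universe) {
  if (length(universe) == 0) fm_domain_error("universe must be non-empty")
  members_a <- unique(members_a); members_b <- unique(members_b)
  outside <- setdiff(c(members_a, members_b), universe)
  if (length(outside) > 0) {
    fm_domain_error(sprintf("members outside the universe: %s",
                            paste(head(outside, 5), collapse = ", ")))
  }
  N <- length(unique(universe))
  both <- length(intersect(members_a, members_b))
  only_a <- length(members_a) - both
  only_b <- length(members_b) - both
  neither <- N - both - only_a - only_b
  po <- (both + neither) / N
  p_a <- length(members_a) / N
  p_b <- length(members_b) / N
  pe <- p_a * p_b + (1 - p_a) * (1 - p_b)
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Majority-direction label for a term
#'
#' A term is labelled `up` when more of its hit genes are up-regulated than
#' down-regulated, `down` in the opposite case, and `mixed` when the two
#' counts tie.
#'
#' @param hit_genes character vector of the term's hit genes (non-empty).
#' @param directions named character vector mapping each gene to `"up"` or
#'   `"down"`.
#' @return one of `"up"`, `"down"`, `"mixed"`.
#' @export
term_direction <- function(hit_genes, directions) {
  if (length(hit_genes) == 0) {
    fm_domain_error("cannot label a term with no hit genes")
  }
  d <- directions[hit_genes]
  if (any(is.na(d))) {
    fm_domain_error(sprintf("missing direction for hit gene(s): %s",
                            paste(hit_genes[is.na(d)], collapse = ", ")))
  }
  n_up <- sum(d == "up"); n_down <- sum(d == "down")
  if (n_up > n_down) "up" else if (n_down > n_up) "down" else "mixed"
}

#' Gene-set over-representation analysis
#'
#' Tests every gene set against the query with the two-sided hypergeometric
#' test and applies the Holm correction across terms. The background universe
#' is, by default, the union of all genes in the collection; query genes
#' absent from the universe are dropped with a logged count before testing.
#' When per-gene directions are supplied each term also gets up/down hit
#' counts and a majority-direction label.
#'
#' @param query character vector of query genes (e.g. consensus cluster ids).
#' @param gene_sets named list of member vectors (see [read_gmt()]).
#' @param directions optional named character vector (`"up"`/`"down"`) per
#'   query gene.
#' @param config an [enrichment_config()].
#' @param universe explicit background (required when `universe_policy` is
#'   `"explicit_list"`).
#' @return tibble with one row per term: term_id, N, K, n, k, p_two_sided,
#'   p_adjusted, hit_genes (list column), n_up, n_down, regulation_label;
#'   sorted by adjusted then raw p, then term_id.
#' @export
enrich_terms <- function(query, gene_sets, directions = NULL,
                         config = enrichment_config(), universe = NULL) {
  stopifnot(inherits(config, "fm_enrichment_config"))
  if (length(gene_sets) == 0) {
    fm_domain_error("empty gene-set collection")
  }
  if (config$universe_policy == "explicit_list") {
    if (is.null(universe)) {
      fm_config_error("universe_policy 'explicit_list' requires a universe")
    }
    universe <- unique(universe)
  } else {
    universe <- unique(unlist(gene_sets, use.names = FALSE))
  }
  query <- unique(query)
  query_in <- intersect(query, universe)
  n_dropped <- length(query) - length(query_in)
  if (n_dropped > 0) {
    fm_log("enrich", sprintf(
      "%d of %d query gene(s) absent from the universe were dropped",
      n_dropped, length(query)))
  }
  N <- length(universe)
  n <- length(query_in)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), universe)
    hits <- sort(intersect(members, query_in))
    k <- length(hits)
    tibble::tibble(
      term_id = term, N = N, K = length(members), n = n, k = k,
      p_two_sided = hypergeom_two_sided(k, n, length(members), N,
                                        method = config$two_sided),
      hit_genes = list(hits))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- holm_adjust(out$p_two_sided)
  if (!is.null(directions)) {
    dirs <- lapply(out$hit_genes, function(h) directions[h])
    out$n_up <- vapply(dirs, function(d) sum(d == "up", na.rm = TRUE), integer(1))
    out$n_down <- vapply(dirs, function(d) sum(d == "down", na.rm = TRUE), integer(1))
    out$regulation_label <- ifelse(
      out$k == 0, NA_character_,
      ifelse(out$n_up > out$n_down, "up",
             ifelse(out$n_down > out$n_up, "down", "mixed")))
  } else {
    out$n_up <- NA_integer_; out$n_down <- NA_integer_
    out$regulation_label <- NA_character_
  }
  out <- out[order(out$p_adjusted, out$p_two_sided, out$term_id), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Group significant terms by kappa similarity
#'
#' Builds a term graph over the significant results (Holm-adjusted p below
#' `alpha`) with an edge wherever the membership kappa reaches
#' `kappa_threshold`; kappa is computed over the universe restricted to the
#' query hit genes, so two terms are similar when they are hit by similar
#' query genes. Groups are the connected components of this graph; each is
#' represented by its member with the smallest adjusted p (ties broken
#' lexicographically).
#'
#' @param results an [enrich_terms()] tibble.
#' @param config an [enrichment_config()].
#' @return tibble with columns `representative`, `members` (list column),
#'   `n_members`, `mean_kappa` (mean pairwise kappa, 1 for singletons),
#'   `p_representative`; ordered by representative p then name.
#' @export
group_terms <- function(results, config = enrichment_config()) {
  stopifnot(inherits(config, "fm_enrichment_config"))
  sig <- results[results$p_adjusted < config$alpha & results$k > 0, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(representative = character(), members = list(),
                          n_members = integer(), mean_kappa = double(),
                          p_representative = double()))
  }
  hit_universe <- sort(unique(unlist(sig$hit_genes, use.names = FALSE)))
  m <- nrow(sig)
  kap <- matrix(1, m, m, dimnames = list(sig$term_id, sig$term_id))
  if (m > 1) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        kap[i, j] <- kap[j, i] <-
          term_kappa(sig$hit_genes[[i]], sig$hit_genes[[j]], hit_universe)
      }
    }
  }
  adj <- kap >= config$kappa_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(sig$term_id, comp)
  rows <- lapply(groups, function(members) {
    members <- sort(members)
    p_mem <- sig$p_adjusted[match(members, sig$term_id)]
    rep_id <- members[order(p_mem, members)][1]
    mk <- if (length(members) == 1) 1 else {
      sub <- kap[members, members]
      mean(sub[upper.tri(sub)])
    }
    tibble::tibble(representative = rep_id, members = list(members),
                   n_members = length(members), mean_kappa = mk,
                   p_representative = min(p_mem))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$p_representative, out$representative), , drop = FALSE]
  tibble::as_tibble(out)
}

#' MAPPFinder-style pathway Z-score
#'
#' Standardised over-representation score of a pathway of measured size `n`
#' containing `r` query hits, against `R` total query hits in a measured
#' universe of size `N`:
#' `z = (r - n R / N) / sqrt(n (R/N) (1 - R/N) (1 - (n-1)/(N-1)))`,
#' the observed hit count standardised by the mean and variance of the
#' hypergeometric draw of `n` from `N`. A degenerate variance (`R = 0`,
#' `R = N` or `n = N`) yields `z = 0` with a warning.
#'
#' @param r query hits on the pathway.
#' @param n pathway size (measured genes).
#' @param R total query hits in the measured universe.
#' @param N measured universe size (>= 2).
#' @param z_cutoff critical value for the significance flag (default 1.6449).
#' @param alternative `"greater"` (default) flags `z >= z_cutoff`;
#'   `"two_sided"` flags `|z| >= z_cutoff`.
#' @return one-row tibble: r, n, R, N, z, significant.
#' @export
pathway_zscore <- function(r, n, R, N, z_cutoff = 1.6449,
                           alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  r <- fm_check_count(r, "r"); n <- fm_check_count(n, "n")
  R <- fm_check_count(R, "R"); N <- fm_check_count(N, "N")
  if (N < 2 || n < 1) fm_domain_error("require N >= 2 and n >= 1")
  if (r > n || n > N || r > R || R > N) {
    fm_domain_error("require 0 <= r <= n <= N and r <= R <= N")
  }
  p <- R / N
  v <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  if (v <= 0) {
    warn("pathway Z-score variance is zero; returning z = 0",
         class = "fabrymeta_degenerate_zscore")
    z <- 0
  } else {
    z <- (r - n * p) / sqrt(v)
  }
  significant <- if (alternative == "greater") z >= z_cutoff else abs(z) >= z_cutoff
  tibble::tibble(r = r, n = n, R = R, N = N, z = z, significant = significant)
}

#' Pathway Z-scores over a collection
#'
#' Applies [pathway_zscore()] to every pathway in a gene-set collection,
#' using the collection union (or an explicit list) as the measured universe.
#'
#' @inheritParams enrich_terms
#' @return tibble with one row per pathway: pathway_id, r, n, R, N, z,
#'   significant; sorted by descending z then pathway_id. Pathways with no
#'   measured member are skipped.
#' @export
pathway_zscores <- function(query, gene_sets, config = enrichment_config(),
                            universe = NULL) {
  stopifnot(inherits(config, "fm_enrichment_config"))
  if (config$universe_policy == "explicit_list") {
    if (is.null(universe)) {
      fm_config_error("universe_policy 'explicit_list' requires a universe")
    }
    universe <- unique(universe)
  } else {
    universe <- unique(unlist(gene_sets, use.names = FALSE))
  }
  query_in <- intersect(unique(query), universe)
  N <- length(universe); R <- length(query_in)
  rows <- lapply(names(gene_sets), function(pw) {
    members <- intersect(unique(gene_sets[[pw]]), universe)
    if (length(members) == 0) return(NULL)
    res <- withCallingHandlers(
      pathway_zscore(length(intersect(members, query_in)), length(members),
                     R, N, z_cutoff = config$z_cutoff,
                     alternative = config$z_alternative),
      fabrymeta_degenerate_zscore = function(w) invokeRestart("muffleWarning"))
    dplyr::bind_cols(tibble::tibble(pathway_id = pw), res)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out <- out[order(-out$z, out$pathway_id), , drop = FALSE]
  tibble::as_tibble(out)
}
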
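## Shared fixtures and independent brute-force oracles.
options(fabrymeta.verbose = FALSE)

## small in-code study table
make_studies <- function(ids, platform = "proteomics", fluid = "urine",
                         group = "naive") {
  tibble::tibble(study_id = ids,
                 platform = rep_len(platform, length(ids)),
                 fluid = rep_len(fluid, length(ids)),
                 group = rep_len(group, length(ids)),
                 n_case = NA_real_, n_control = NA_real_,
                 ratio_convention = "ratio")
}

make_features <- function(cluster_id, study_id, ratio, p_value = 0.01,
                          tag = "UK") {
  tibble::tibble(cluster_id = cluster_id, study_id = study_id,
                 ratio = ratio, p_value = rep_len(p_value, length(ratio)),
                 direction = ifelse(ratio > 1, "up", "down"),
                 tag = rep_len(tag, length(ratio)))
}

write_tsv_fixture <- function(df, name = "fixture.tsv") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  path
}

## Oracle: Cohen's kappa from the explicit 2x2 membership table
bf_kappa <- function(a, b, universe) {
  in_a <- universe %in% a
  in_b <- universe %in% b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

## Oracle: consensus/contradiction partition by enumerating every cluster's
## direction multiset
bf_consistency <- function(features) {
  split_by <- split(features, features$cluster_id)
  res <- lapply(split_by, function(df) {
    dirs <- unique(ifelse(df$ratio > 1, "up", "down"))
    if (length(dirs) > 1) {
      list(kind = "removed", cluster = df$cluster_id[1])
    } else {
      list(kind = "consensus", cluster = df$cluster_id[1],
           mean_ratio = mean(df$ratio), n_studies = length(unique(df$study_id)))
    }
  })
  list(
    consensus = do.call(rbind, lapply(Filter(function(x) x$kind == "consensus", res),
      function(x) data.frame(cluster_id = x$cluster, mean_ratio = x$mean_ratio,
                             n_studies = x$n_studies))),
    removed = sort(unname(vapply(Filter(function(x) x$kind == "removed", res),
                                 function(x) x$cluster, character(1))),
                   method = "radix")
  )
}

## Oracle: O(n^3) agglomerative clustering (average linkage, complete data)
## returning merge heights and the partition after each merge
bf_agglomerate <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        ## average linkage: mean pairwise distance between the two clusters
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

## canonical form of a partition (set of sorted member sets) for comparison
canonical_partition <- function(groups) {
  sorted <- lapply(groups, sort)
  keys <- vapply(sorted, function(g) paste(g, collapse = ","), character(1))
  sort(keys, method = "radix")
}

## leaves under merge step `step` of an hclust tree
hclust_members <- function(hc, step) {
  unlist(lapply(hc$merge[step, ], function(x) {
    if (x < 0) -x else hclust_members(hc, x)
  }))
}

## partition of hclust leaves after the first k merges
hclust_partition_at <- function(hc, k) {
  n <- length(hc$order)
  consumed <- hc$merge[seq_len(k), , drop = FALSE]
  consumed <- consumed[consumed > 0]
  active <- setdiff(seq_len(k), consumed)
  groups <- lapply(active, function(s) hclust_members(hc, s))
  singletons <- setdiff(seq_len(n), unlist(groups))
  c(groups, as.list(singletons))
}
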
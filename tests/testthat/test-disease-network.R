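naive_diseases <- read_disease_table(
  system.file("extdata", "disease_associations_naive.tsv", package = "fabrymeta"))
ert_diseases <- read_disease_table(
  system.file("extdata", "disease_associations_ert.tsv", package = "fabrymeta"))

test_that("shared-gene ranking reproduces the printed disease counts", {
  query_naive <- unique(unlist(naive_diseases$gene_set))
  ranked <- rank_shared_genes(query_naive, naive_diseases)
  breast <- ranked[ranked$disease_name == "Malignant neoplasm of breast", ]
  expect_equal(breast$shared_count, 16)
  expect_equal(ranked$disease_name[1], "Malignant neoplasm of breast")

  query_ert <- unique(unlist(ert_diseases$gene_set))
  asthma <- rank_shared_genes(query_ert, ert_diseases)
  expect_equal(asthma$shared_count[asthma$disease_name == "Asthma"], 8)
  expect_equal(asthma$disease_name[1], "Asthma")
})

test_that("ranking drops disjoint diseases and breaks ties alphabetically", {
  diseases <- tibble::tibble(
    disease_name = c("zeta trait", "alpha trait", "unrelated"),
    gene_set = list(c("A", "B"), c("A", "C"), c("X", "Y")))
  out <- rank_shared_genes(c("A", "B", "C"), diseases)
  expect_equal(out$disease_name, c("alpha trait", "zeta trait"))
  expect_equal(out$shared_count, c(2, 2))
  expect_equal(out$shared_genes[[1]], c("A", "C"))
  expect_error(rank_shared_genes(character(), diseases),
               class = "fabrymeta_domain_error")
})

test_that("shared counts equal brute-force intersection sizes", {
  set.seed(19)
  pool <- paste0("G", 1:40)
  for (i in 1:200) {
    query <- sample(pool, sample(1:20, 1))
    genes <- sample(pool, sample(1:20, 1))
    out <- rank_shared_genes(query, tibble::tibble(disease_name = "d",
                                                   gene_set = list(genes)))
    expected <- length(intersect(unique(genes), unique(query)))
    if (expected == 0) {
      expect_equal(nrow(out), 0)
    } else {
      expect_equal(out$shared_count, expected)
      expect_equal(out$shared_genes[[1]], sort(intersect(genes, query)))
    }
  }
})

edges_fixture <- tibble::tibble(
  regulator = c("miR-29b", "miR-29c", "miR-144", "MAX"),
  target = c("COL3A1", "COL3A1", "FGA", "IL4I1"),
  network_id = c("rin_mirna1", "rin_mirna2", "rin_mirna1", "rin_tf1"),
  kind = c("miRNA", "miRNA", "miRNA", "TF"))

test_that("regulatory overlay keeps exactly the edges targeting the query", {
  out <- regulatory_overlay(c("COL3A1"), edges_fixture)
  expect_equal(out$status, "ok")
  expect_setequal(out$edges$regulator, c("miR-29b", "miR-29c"))
  expect_equal(out$regulators$n_targets, c(1, 1))
  ## overlay edge set = set filter of input edges
  expect_equal(out$edges,
               dplyr::arrange(edges_fixture[edges_fixture$target %in% "COL3A1", ],
                              regulator))
})

test_that("fewer loaded networks than required yields an empty overlay status", {
  one_net <- edges_fixture[edges_fixture$network_id == "rin_mirna1", ]
  out <- regulatory_overlay("COL3A1", one_net, min_networks = 2)
  expect_equal(out$status, "insufficient_networks")
  expect_equal(nrow(out$edges), 0)
  expect_equal(out$n_networks, 1)
})

test_that("a query with no targeted genes yields an empty overlay", {
  out <- regulatory_overlay("GLA", edges_fixture)
  expect_equal(out$status, "no_targets")
  expect_equal(nrow(out$edges), 0)
})
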
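small_cfg <- synthetic_config(n_signal = 20, n_null = 20,
                              contradiction_fraction = 0.1)

test_that("generation is deterministic for a fixed config and seed", {
  a <- generate_studies(small_cfg, seed = 42)
  b <- generate_studies(small_cfg, seed = 42)
  expect_identical(a, b)
  c <- generate_studies(small_cfg, seed = 43)
  expect_false(identical(a$measurements, c$measurements))
  gs_a <- generate_gene_sets(a$truth, small_cfg, seed = 42)
  gs_b <- generate_gene_sets(b$truth, small_cfg, seed = 42)
  expect_identical(gs_a, gs_b)
})

test_that("the default design mirrors the eleven-study dataspace", {
  syn <- generate_studies(synthetic_config(n_signal = 5, n_null = 5), seed = 1)
  expect_equal(nrow(syn$studies), 11)
  expect_equal(sum(syn$studies$group == "naive"), 7)
  expect_equal(sum(syn$studies$group == "ERT"), 4)
  expect_equal(sum(syn$studies$fluid == "urine"), 5)
  expect_equal(sum(syn$studies$fluid == "blood"), 6)
  expect_setequal(unique(syn$studies$platform),
                  c("proteomics", "peptidomics", "metabolomics",
                    "transcriptomics"))
})

test_that("planted structure satisfies its support and direction contracts", {
  syn <- generate_studies(small_cfg, seed = 7)
  joined <- dplyr::inner_join(syn$measurements, syn$alias_map, by = "raw_id")
  per_study <- dplyr::distinct(joined, cluster_id, study_id, .keep_all = TRUE)
  ## every planted consensus feature: >= 2 studies, uniform direction
  for (i in seq_len(nrow(syn$truth$consensus_features))) {
    cid <- syn$truth$consensus_features$cluster_id[i]
    rows <- joined[joined$cluster_id == cid, ]
    expect_gte(dplyr::n_distinct(rows$study_id), 2)
    expect_equal(dplyr::n_distinct(rows$ratio > 1), 1)
    expect_equal(unique(ifelse(rows$ratio > 1, "up", "down")),
                 syn$truth$consensus_features$direction[i])
  }
  ## every planted contradiction: >= 2 studies, both directions present
  for (cid in syn$truth$contradictory_clusters$cluster_id) {
    rows <- per_study[per_study$cluster_id == cid, ]
    expect_gte(nrow(rows), 2)
    expect_setequal(unique(ifelse(rows$ratio > 1, "up", "down")),
                    c("up", "down"))
  }
  ## truth sets are disjoint
  expect_length(intersect(syn$truth$consensus_features$cluster_id,
                          syn$truth$contradictory_clusters$cluster_id), 0)
})

test_that("a null-only configuration yields almost no consensus features", {
  cfg <- synthetic_config(n_signal = 0, n_null = 60,
                          contradiction_fraction = 0)
  syn <- generate_studies(cfg, seed = 3)
  expect_equal(nrow(syn$truth$consensus_features), 0)
  rep <- run_pipeline(run_config(syn$measurements, syn$studies,
                                 syn$alias_map, seed = 3))
  ## false positives need p < 0.05 and magnitude >= 1.4 jointly: rare
  expect_lte(sum(rep$direction_totals$n_consensus), 3)
})

test_that("invalid generator settings are configuration errors", {
  expect_error(synthetic_config(contradiction_fraction = 1.5),
               class = "fabrymeta_config_error")
  expect_error(synthetic_config(contradiction_fraction = -0.1),
               class = "fabrymeta_config_error")
  expect_error(synthetic_config(min_support = 1),
               class = "fabrymeta_config_error")
  big_terms <- synthetic_config(n_signal = 2, n_null = 2, background_size = 0,
                                term_size = c(50, 60))
  syn <- generate_studies(big_terms, seed = 1)
  expect_error(generate_gene_sets(syn$truth, big_terms, seed = 1),
               class = "fabrymeta_config_error")
})

test_that("a fully planted term is drawn entirely from signal clusters", {
  cfg <- synthetic_config(n_signal = 20, n_null = 20,
                          planted_fraction = 1, term_size = c(10, 10),
                          n_terms = 10, n_planted_terms = 3)
  syn <- generate_studies(cfg, seed = 5)
  gs <- generate_gene_sets(syn$truth, cfg, seed = 5)
  signal <- syn$truth$consensus_features$cluster_id
  for (term in gs$planted_terms) {
    expect_equal(length(intersect(gs$gene_sets[[term]], signal)), 10)
  }
})

test_that("unplanted terms overlap the signal list at the uniform rate", {
  ## Monte-Carlo check of the uniform-sampling expectation n*K/N
  cfg <- synthetic_config(n_signal = 20, n_null = 20,
                          planted_fraction = 0, term_size = c(10, 10),
                          n_terms = 10000, n_planted_terms = 0,
                          background_size = 100)
  syn <- generate_studies(cfg, seed = 9)
  gs <- generate_gene_sets(syn$truth, cfg, seed = 9)
  signal <- syn$truth$consensus_features$cluster_id
  N <- length(syn$truth$universe) + 100
  overlaps <- vapply(gs$gene_sets, function(m)
    length(intersect(m, signal)), numeric(1))
  expected <- 10 * length(signal) / N
  expect_equal(mean(overlaps), expected, tolerance = 0.05)
})

test_that("the truth file round-trips through plain-text tables", {
  syn <- generate_studies(small_cfg, seed = 2)
  dir <- withr::local_tempdir()
  write_truth(syn$truth, dir)
  back <- readr::read_tsv(file.path(dir, "truth_consensus.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(syn$truth$consensus_features))
  expect_equal(back$cluster_id, syn$truth$consensus_features$cluster_id)
})
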
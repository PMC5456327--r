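alias_fixture <- tibble::tibble(
  raw_id = c("GLA", "P06280", "GLA_HUMAN", paste0("g", 1:7)),
  cluster_id = c(rep("C_GLA", 3), paste0("C", 1:7)),
  tag = "ENZ")

test_that("aliases of one molecule map to a shared cluster", {
  meas <- tibble::tibble(study_id = "s1",
                         raw_id = c("GLA", "P06280", "GLA_HUMAN"),
                         ratio = 2, p_value = 0.01)
  out <- map_identifiers(meas, alias_fixture)
  expect_equal(unique(out$mapped$cluster_id), "C_GLA")
  expect_equal(nrow(out$unmapped), 0)
})

test_that("mapping counts distinct clusters and conserves rows", {
  ## 10 measurements: 3 aliases of C_GLA plus 7 singleton clusters -> 8 clusters
  meas <- tibble::tibble(
    study_id = "s1",
    raw_id = c("GLA", "P06280", "GLA_HUMAN", paste0("g", 1:7)),
    ratio = 2, p_value = 0.01)
  out <- map_identifiers(meas, alias_fixture)
  expect_equal(dplyr::n_distinct(out$mapped$cluster_id), 8)

  meas2 <- dplyr::bind_rows(meas, tibble::tibble(
    study_id = "s1", raw_id = "unknown_probe", ratio = 2, p_value = 0.01))
  out2 <- map_identifiers(meas2, alias_fixture)
  expect_equal(nrow(out2$mapped), nrow(meas))
  expect_equal(out2$unmapped$raw_id, "unknown_probe")
  expect_equal(nrow(out2$mapped) + nrow(out2$unmapped), nrow(meas2))
})

test_that("within-study collapsing averages ratios and keeps the best p", {
  mapped <- tibble::tibble(study_id = "s1", cluster_id = "C1",
                           raw_id = c("a", "b"), ratio = c(1.6, 2.0),
                           p_value = c(0.04, 0.01), tag = "MET")
  out <- collapse_within_study(mapped)
  expect_equal(out$features$ratio, 1.8)
  expect_equal(out$features$p_value, 0.01)
  expect_equal(out$features$direction, "up")

  fisher <- collapse_within_study(mapped, p_combine = "fisher")
  expect_equal(fisher$features$p_value,
               stats::pchisq(-2 * (log(0.04) + log(0.01)), df = 4,
                             lower.tail = FALSE))
})

test_that("collapsing passes singletons through and is idempotent", {
  mapped <- tibble::tibble(study_id = c("s1", "s1", "s2"),
                           cluster_id = c("C1", "C1", "C2"),
                           ratio = c(1.6, 2.0, 0.5),
                           p_value = c(0.04, 0.01, 0.02), tag = "UK")
  once <- collapse_within_study(mapped)$features
  expect_equal(once$ratio[once$cluster_id == "C2"], 0.5)
  twice <- collapse_within_study(once)$features
  expect_equal(twice, once)
})

test_that("within-study direction conflicts are dropped, not averaged", {
  mapped <- tibble::tibble(study_id = "s1", cluster_id = "C1",
                           ratio = c(1.6, 0.5), p_value = 0.01, tag = "UK")
  out <- collapse_within_study(mapped)
  expect_equal(nrow(out$features), 0)
  expect_equal(out$dropped$cluster_id, "C1")
})

test_that("thresholds combine platform and global cutoffs", {
  studies <- make_studies(c("tx", "pr"), platform = c("transcriptomics",
                                                      "proteomics"))
  feats <- make_features(c("C1", "C2", "C3", "C4"),
                         c("tx", "pr", "pr", "tx"),
                         ratio = c(1.8, 1.35, 0.5, 2.2), p_value = 0.01)
  out <- apply_thresholds(feats, studies, threshold_config())
  ## transcriptomics 1.8 fails platform 2.0; proteomics 1.35 passes 1.3 but
  ## fails global 1.4; proteomics 0.5 has magnitude 2.0 and passes
  expect_setequal(out$cluster_id, c("C3", "C4"))
  expect_equal(out$direction[out$cluster_id == "C3"], "down")

  high_p <- make_features("C5", "pr", 2.0, p_value = 0.2)
  expect_equal(nrow(apply_thresholds(high_p, studies)), 0)
  expect_error(apply_thresholds(make_features("C6", "nope", 2.0), studies),
               "unknown study", class = "fabrymeta_reference_error")
})

test_that("threshold filtering is monotone and direction-symmetric", {
  set.seed(11)
  studies <- make_studies(paste0("s", 1:4),
                          platform = sample(c("transcriptomics", "proteomics",
                                              "peptidomics", "metabolomics"),
                                            4, replace = TRUE))
  for (rep in 1:20) {
    feats <- make_features(paste0("C", 1:30),
                           sample(studies$study_id, 30, replace = TRUE),
                           ratio = exp(rnorm(30, 0, 0.8)),
                           p_value = runif(30))
    base <- apply_thresholds(feats, studies, threshold_config())
    stricter <- list(
      threshold_config(fc_transcriptomics = 2.5),
      threshold_config(fc_prot_metab = 1.6),
      threshold_config(fc_global = 1.8),
      threshold_config(p_max = 0.01))
    for (cfg in stricter) {
      expect_true(all(apply_thresholds(feats, studies, cfg)$cluster_id %in%
                        base$cluster_id))
    }
    ## reciprocal ratios are included or excluded together
    flipped <- feats
    flipped$ratio <- 1 / flipped$ratio
    expect_equal(apply_thresholds(flipped, studies)$cluster_id,
                 base$cluster_id)
  }
})
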
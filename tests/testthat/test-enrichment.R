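test_that("two-sided hypergeometric p matches exhaustive enumeration", {
  ## N=20, K=5, n=5, k=5: upper tail = choose(5,5)*choose(15,0)/choose(20,5)
  upper <- 1 / choose(20, 5)
  expect_equal(upper, 1 / 15504)
  expect_equal(hypergeom_two_sided(5, 5, 5, 20), 2 * upper)
  ## degenerate term: K = 0 forces k = 0 and p = 1
  expect_equal(hypergeom_two_sided(0, 5, 0, 20), 1)
  expect_error(hypergeom_two_sided(6, 5, 5, 20),
               class = "fabrymeta_domain_error")
  expect_error(hypergeom_two_sided(2, 5, 5, -1),
               class = "fabrymeta_domain_error")
})

test_that("two-sided p is bounded by twice the smaller tail and by 1", {
  set.seed(31)
  ok <- vapply(1:200, function(i) {
    N <- sample(2:80, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    supp <- max(0, n + K - N):min(n, K)
    k <- supp[sample.int(length(supp), 1)]
    p <- hypergeom_two_sided(k, n, K, N)
    lower <- phyper(k, K, N - K, n)
    upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ## the min-likelihood variant must also be a valid p in (0, 1]
    pm <- hypergeom_two_sided(k, n, K, N, method = "minlik")
    p > 0 && p <= 1 && p <= 2 * min(lower, upper) + 1e-12 &&
      pm > 0 && pm <= 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("the hypergeometric pmf is normalised over its support", {
  worst <- 0
  for (N in 1:200) {
    for (frac in c(0, 0.25, 0.5, 1)) {
      K <- round(frac * N); n <- round((1 - frac / 2) * N)
      support <- max(0, n + K - N):min(n, K)
      worst <- max(worst, abs(sum(dhyper(support, K, N - K, n)) - 1))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Holm adjustment reproduces hand-computed step-down values", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.05, 0.05)), c(0.10, 0.10))
  expect_error(holm_adjust(c(0.1, 1.2)), class = "fabrymeta_domain_error")
})

test_that("Holm adjustment matches an independent step-down oracle and is monotone", {
  step_down_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    running <- 0
    for (j in seq_len(m)) {
      running <- max(running, min(1, (m - j + 1) * p[ord[j]]))
      adj[ord[j]] <- running
    }
    adj
  }
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, step_down_oracle(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # ranking preserved
    ## monotone: raising one raw p never lowers any adjusted p
    p2 <- p
    idx <- sample(length(p), 1)
    p2[idx] <- min(1, p2[idx] + runif(1, 0, 1 - p2[idx]))
    expect_true(all(holm_adjust(p2) >= adj - 1e-12))
  }
})

test_that("kappa reproduces hand-built 2x2 tables", {
  universe <- paste0("g", 1:10)
  A <- paste0("g", 1:5)
  expect_equal(term_kappa(A, A, universe), 1)
  expect_equal(term_kappa(A, paste0("g", 6:10), universe), -1)
  expect_equal(term_kappa(A, c(paste0("g", 1:4), "g6"), universe), 0.6)
  expect_error(term_kappa(A, "g99", universe),
               class = "fabrymeta_domain_error")
})

test_that("kappa agrees with the brute-force table oracle on random pairs", {
  set.seed(41)
  universe <- paste0("g", 1:30)
  pairs <- lapply(1:1000, function(i)
    list(a = sample(universe, sample(0:30, 1)),
         b = sample(universe, sample(0:30, 1))))
  ours <- vapply(pairs, function(p) term_kappa(p$a, p$b, universe), numeric(1))
  oracle <- vapply(pairs, function(p) bf_kappa(p$a, p$b, universe), numeric(1))
  swapped <- vapply(pairs, function(p) term_kappa(p$b, p$a, universe),
                    numeric(1))
  expect_equal(ours, oracle)
  expect_equal(ours, swapped)  # symmetric in arguments
  expect_true(all(ours >= -1 & ours <= 1))
})

test_that("term grouping finds connected components above the kappa cutoff", {
  hit_universe <- paste0("g", 1:10)
  results <- tibble::tibble(
    term_id = c("T1", "T2", "T3"),
    p_adjusted = c(0.001, 0.01, 0.02), k = c(5, 5, 5),
    hit_genes = list(paste0("g", 1:5), c(paste0("g", 1:4), "g6"),
                     paste0("g", 6:10)))
  groups <- group_terms(results, enrichment_config())
  expect_equal(nrow(groups), 2)
  expect_equal(groups$representative[1], "T1")
  expect_setequal(groups$members[[1]], c("T1", "T2"))
  expect_equal(groups$members[[2]], "T3")
  expect_equal(groups$mean_kappa[[2]], 1)

  single <- group_terms(results[1, ], enrichment_config())
  expect_equal(single$n_members, 1)
  ## groups partition the significant terms
  expect_setequal(unlist(groups$members), results$term_id)
})

test_that("term direction labels follow the hit majority", {
  acute <- c("DEFB1", "IL1RN", "ITIH4", "ORM1", "ORM2", "SERPINA3",
             "VCAM1", "VTN")
  dirs <- setNames(rep("up", 8), acute)
  expect_equal(term_direction(acute, dirs), "up")
  dirs2 <- setNames(c("up", "up", "down", "down"), paste0("g", 1:4))
  expect_equal(term_direction(paste0("g", 1:4), dirs2), "mixed")
  expect_error(term_direction(character(), dirs),
               class = "fabrymeta_domain_error")
})

test_that("pathway Z-score matches its closed form and flags significance", {
  expect_equal(pathway_zscore(2, 10, 20, 100)$z, 0)  # r = nR/N exactly
  z <- pathway_zscore(3, 10, 10, 100)
  expect_equal(z$z, (3 - 1) / sqrt(10 * 0.1 * 0.9 * (1 - 9 / 99)),
               tolerance = 1e-12)
  expect_equal(round(z$z, 3), 2.211)
  expect_true(z$significant)
  expect_false(pathway_zscore(2, 10, 10, 100)$significant)
  expect_warning(out <- pathway_zscore(0, 10, 0, 100),
                 class = "fabrymeta_degenerate_zscore")
  expect_equal(out$z, 0)
  expect_error(pathway_zscore(5, 4, 10, 100), class = "fabrymeta_domain_error")
})

test_that("Z-score standardisation matches Monte-Carlo hypergeometric draws", {
  set.seed(61)
  for (i in 1:5) {
    N <- sample(40:120, 1)
    R <- sample(5:(N - 5), 1)
    n <- sample(2:(N %/% 2), 1)
    draws <- rhyper(100000, R, N - R, n)
    z_by_r <- vapply(0:min(n, R), function(r)
      pathway_zscore(r, n, R, N)$z, numeric(1))
    z_draws <- z_by_r[draws + 1]
    ## standardised draws should have mean ~0 and variance ~1
    expect_lt(abs(mean(z_draws)), 0.02)
    expect_lt(abs(var(z_draws) - 1), 0.05)
  }
})

test_that("enrichment over a collection assembles counts, p and labels", {
  gene_sets <- list(
    hitset = structure(paste0("g", 1:10), description = "mostly query"),
    coldset = structure(paste0("g", 41:60), description = "background"))
  universe <- paste0("g", 1:60)
  query <- paste0("g", c(1:8, 21:25))
  dirs <- setNames(rep(c("up", "down"), c(8, 5)), query)
  res <- enrich_terms(query, gene_sets, directions = dirs,
                      config = enrichment_config(universe_policy = "explicit_list"),
                      universe = universe)
  hit <- res[res$term_id == "hitset", ]
  expect_equal(hit$k, 8)
  expect_equal(hit$n, 13)
  expect_equal(hit$K, 10)
  expect_equal(hit$N, 60)
  expect_equal(hit$regulation_label, "up")
  expect_equal(hit$p_two_sided,
               hypergeom_two_sided(8, 13, 10, 60))
  expect_true(all(res$p_adjusted >= res$p_two_sided))
  expect_equal(res$n_up + res$n_down, res$k)

  ## query genes outside the universe are dropped before testing
  res2 <- enrich_terms(c(query, "mystery"), gene_sets,
                       config = enrichment_config(universe_policy = "explicit_list"),
                       universe = universe)
  expect_equal(res2$n[1], 13)
})
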
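# Case/control prioritized-gene enrichment and the random-gene-set null.

test_that("the simplified cascade waives the 1KJPN and HGVD steps but not the frequency filters", {
  v <- dplyr::bind_rows(
    make_variants(n = 1, pos = 10L, gene = "A1", sift = 0.01, gerp = 4) %>%
      dplyr::mutate(maf_1kjpn = 0.05),
    make_variants(n = 1, pos = 20L, gene = "A2", sift = 0.01, gerp = 4) %>%
      dplyr::mutate(maf_exac = 0.05),
    make_variants(n = 1, pos = 30L, gene = "A3", sift = 0.01, gerp = 4) %>%
      dplyr::mutate(maf_hgvd = 0.05)
  )
  g <- make_genotypes(
    list(v$variant_id[1], "p1", "het"),
    list(v$variant_id[2], "p1", "het"),
    list(v$variant_id[3], "p1", "het")
  )
  full <- prioritize_patient("p1", v, g, filter_config(),
                             case_alleles = count_case_alleles(g, "p1"))
  simp <- prioritize_patient("p1", v, g, filter_config(simplified = TRUE),
                             case_alleles = count_case_alleles(g, "p1"))
  status_of <- function(res, gene) res$trace$status[res$trace$gene == gene]
  expect_equal(status_of(full, "A1"), "removed")          # 1KJPN
  expect_equal(status_of(simp, "A1"), "prioritized_main") # waived
  expect_equal(status_of(full, "A3"), "removed")          # HGVD
  expect_equal(status_of(simp, "A3"), "prioritized_main") # waived
  expect_equal(status_of(full, "A2"), "removed")          # ExAC: never waived
  expect_equal(status_of(simp, "A2"), "removed")
})

test_that("percentage of individuals harbouring prioritized genes is plain arithmetic over the group", {
  hits <- tibble::tibble(sample_id = c("c1", "c1", "c2"),
                         gene = c("G1", "G2", "G1"))
  inds <- sprintf("c%d", 1:10)
  expect_equal(percent_with_prioritized(hits, inds, "G1"), 20)
  expect_equal(percent_with_prioritized(hits, inds, "G9"), 0)
  expect_error(percent_with_prioritized(hits, character(), "G1"),
               "empty cohort")
})

test_that("the random-set null is seeded, reproducible, and zero on empty hits", {
  pool <- sprintf("P%04d", 1:1200)
  hits <- tibble::tibble(sample_id = character(), gene = character())
  ecfg <- enrich_config(random_set_size = 908L, n_draws = 50L, seed = 5L)
  null <- random_geneset_null(hits, sprintf("i%d", 1:10), pool, ecfg)
  expect_equal(null$null_mean, 0)
  expect_equal(null$null_sd, 0)
  hits2 <- tibble::tibble(sample_id = c("i1", "i2"), gene = c("P0001", "P0500"))
  n1 <- random_geneset_null(hits2, sprintf("i%d", 1:10), pool, ecfg)
  n2 <- random_geneset_null(hits2, sprintf("i%d", 1:10), pool, ecfg)
  expect_identical(n1$draws, n2$draws)
  expect_error(
    random_geneset_null(hits2, "i1", sprintf("P%d", 1:100), ecfg),
    "smaller than the random set size"
  )
})

test_that("the 1000-draw null mean matches the closed-form expectation on a uniform-background fixture", {
  n_ind <- 60L
  pool <- sprintf("P%04d", 1:2000)
  q <- 5e-4
  k <- 908L
  hits <- withr::with_seed(17, {
    purrr::map(seq_len(n_ind), function(i) {
      g <- pool[stats::runif(length(pool)) < q]
      if (length(g) == 0) NULL else tibble::tibble(
        sample_id = sprintf("i%03d", i), gene = g)
    }) %>% dplyr::bind_rows()
  })
  inds <- sprintf("i%03d", seq_len(n_ind))
  ecfg <- enrich_config(random_set_size = k, n_draws = 1000L, seed = 23L)
  null <- random_geneset_null(hits, inds, pool, ecfg)

  # Conditional expectation given the realised gene sets, in closed form
  # (hypergeometric miss probability per individual).
  m <- table(factor(hits$sample_id, levels = inds))
  p_i <- 1 - exp(lchoose(2000 - as.integer(m), k) - lchoose(2000, k))
  mu_cond <- 100 * mean(p_i)
  se_mc <- stats::sd(null$draws) / sqrt(length(null$draws))
  expect_lt(abs(null$null_mean - mu_cond), 3 * se_mc + 1e-9)

  # And the realised sets themselves sit at the analytic expectation
  # 100 * (1 - (1 - q)^k) within sampling error over individuals.
  mu_analytic <- 100 * (1 - (1 - q)^k)
  se_ind <- 100 * stats::sd(p_i) / sqrt(n_ind)
  expect_lt(abs(mu_cond - mu_analytic), 3 * se_ind)
})

test_that("known and mitochondria-related gene sets are enriched in cases on the planted cohort; random sets are not", {
  co <- default_cohort()
  en <- .fixture_env$enrichment
  if (is.null(en)) {
    en <- run_enrichment(
      co, ecfg = enrich_config(require_configuration = FALSE, seed = 2L))
    .fixture_env$enrichment <- en
  }
  by <- tidy(en)
  known <- by[by$set == "known", ]
  mito <- by[by$set == "mito_related", ]
  rand <- by[by$set == "random", ]
  expect_gt(known$pct_cases, known$pct_controls)
  expect_gt(mito$fold, 1)
  # the random-set fold sits inside the null band around 1
  null_fold_sd <- stats::sd(en$null_cases$draws / pmax(en$null$null_mean, 1e-9))
  expect_lt(abs(rand$fold - 1), 3 * max(null_fold_sd, 0.1))
  # the null percentage never exceeds the whole-pool percentage
  pool <- setdiff(co$gene_sets$all,
                  union(co$gene_sets$known, co$gene_sets$mito))
  pool_pct <- percent_with_prioritized(en$gene_hits, co$controls, pool)
  expect_lte(en$null$null_mean, pool_pct)
  # with cases and controls the same group, the fold is exactly 1
  hits <- en$gene_hits
  p_same <- percent_with_prioritized(hits, co$cases, co$gene_sets$mito)
  expect_equal(enrichment_fold(p_same, p_same), 1)
})

test_that("fold enrichment is a plain ratio and undefined on a zero control percentage", {
  expect_equal(enrichment_fold(16.4, 10), 1.64)
  expect_equal(enrichment_fold(10, 10), 1)
  expect_true(is.na(enrichment_fold(5, 0)))
})
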
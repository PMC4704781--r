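# The exome filter cascade: per-filter behaviour, traces, recovery pass,
# and the order-invariance / monotonicity properties.

cfg <- filter_config()

test_that("functional class filter keeps protein-modifying classes and errors on unknown labels", {
  v <- make_variants(n = 3, pos = 1:3 * 10L,
                     class = c("missense", "other", "frameshift_indel"))
  res <- filter_functional_class(v, cfg)
  expect_equal(res$keep, c(TRUE, FALSE, TRUE))
  expect_match(res$reason[2], "not protein-modifying")
  v_bad <- make_variants(n = 1, class = "missense")
  v_bad$class <- "nonsense_mediated"
  expect_error(filter_functional_class(v_bad, cfg), "unknown functional class")
})

test_that("population frequency filter removes strictly above per-panel thresholds, names the panel, keeps boundary and novel variants", {
  v <- make_variants(n = 3, pos = 1:3 * 10L)
  v$maf_exac <- c(0.002, NA, NA)     # 0.2% > 0.1% -> remove
  v$maf_hgvd <- c(NA, NA, 0.004)     # exactly 0.4% -> keep (strict >)
  res <- filter_population_frequency(v, cfg)
  expect_equal(res$keep, c(FALSE, TRUE, TRUE))
  expect_match(res$reason[1], "exac")
  # frequencies outside [0,1] are an error
  v$maf_exac[1] <- 1.5
  expect_error(filter_population_frequency(v, cfg), "outside")
})

test_that("dbSNP frequency filtering is waived for entries with known medical impact", {
  v <- make_variants(n = 2, pos = c(10L, 20L))
  v$maf_dbsnp137 <- c(0.05, 0.05)
  v$dbsnp_medical_impact <- c(FALSE, TRUE)
  res <- filter_population_frequency(v, cfg)
  expect_equal(res$keep, c(FALSE, TRUE))
})

test_that("case recurrence counts alleles het=1 hom=2 hemi=1 and excludes at ten or more", {
  g <- do.call(make_genotypes, c(
    purrr::map(sprintf("c%02d", 1:5), ~ list("v1", .x, "hom_alt")),
    purrr::map(sprintf("c%02d", 1:9), ~ list("v2", .x, "het")),
    purrr::map(sprintf("c%02d", 1:4), ~ list("v3", .x, "hom_alt")),
    list(list("v3", "c05", "het"))
  ))
  cases <- sprintf("c%02d", 1:12)
  ca <- count_case_alleles(g, cases)
  expect_equal(ca$case_alleles[ca$variant_id == "v1"], 10)  # 5 hom
  expect_equal(ca$case_alleles[ca$variant_id == "v2"], 9)   # 9 het
  expect_equal(ca$case_alleles[ca$variant_id == "v3"], 9)   # 4 hom + 1 het
  v <- make_variants(n = 3, pos = 1:3 * 10L)
  v$variant_id <- c("v1", "v2", "v3")
  res <- filter_case_recurrence(v, ca, cfg)
  expect_equal(res$keep[match(c("v1", "v2", "v3"), res$variant_id)],
               c(FALSE, TRUE, TRUE))
})

test_that("segdup filter removes contained variants with half-open BED boundaries honoured", {
  d <- withr::local_tempdir()
  writeLines("chr1\t999\t2000", file.path(d, "sd.bed"))
  sd <- read_bed_regions(file.path(d, "sd.bed"))
  v <- make_variants(n = 3, pos = c(1500L, 2000L, 2001L))
  v <- flag_segdup(v, sd)
  res <- filter_segdup(v, cfg)
  expect_equal(res$keep, c(FALSE, FALSE, TRUE))  # 2000 is the last inside base
  # empty region set keeps everything
  v0 <- flag_segdup(v, sd[0, ])
  expect_true(all(filter_segdup(v0, cfg)$keep))
})

test_that("deleteriousness filter removes tolerated or unconserved variants; missing scores never remove", {
  v <- make_variants(n = 3, pos = 1:3 * 10L,
                     class = c("missense", "missense", "nonsense"),
                     sift = c(0.40, 0.01, NA), gerp = c(NA, 4.1, 3.0))
  res <- filter_deleteriousness(v, cfg)
  expect_equal(res$keep, c(FALSE, TRUE, TRUE))
  expect_match(res$reason[1], "tolerated")
})

test_that("recovery pass restores mito-gene variants failing only waivable filters", {
  v <- make_variants(n = 3, pos = 1:3 * 10L,
                     gene = c("MITO1", "OTHER1", "MITO2"),
                     gerp = c(1.0, 1.0, NA))
  v$maf_exac <- c(NA, NA, 0.01)  # MITO2 fails a non-waivable filter
  v$case_alleles <- 0L
  passes <- mitodx:::evaluate_filters(v, cfg)
  passes$gene <- v$gene
  out <- recovery_pass(passes, mito_genes = c("MITO1", "MITO2"), cfg)
  expect_equal(out$status[out$gene == "MITO1"], "prioritized_recovery")
  expect_equal(out$status[out$gene == "OTHER1"], "removed")
  expect_equal(out$status[out$gene == "MITO2"], "removed")
})

test_that("prioritize_patient returns survivors with complete traces; empty input gives empty output", {
  v <- dplyr::bind_rows(
    make_variants(n = 1, pos = 10L, gene = "GOOD", sift = 0.01, gerp = 4),
    make_variants(n = 1, pos = 20L, gene = "BAD", sift = 0.01, gerp = 4) %>%
      dplyr::mutate(maf_dbsnp137 = 0.2, maf_exac = 0.3)
  )
  g <- make_genotypes(
    list(v$variant_id[1], "p1", "het"),
    list(v$variant_id[2], "p1", "het")
  )
  res <- prioritize_patient("p1", v, g, cfg,
                            case_alleles = count_case_alleles(g, "p1"))
  expect_equal(res$prioritized$gene, "GOOD")
  expect_equal(nrow(res$trace), 2)                 # trace covers all carried
  expect_equal(sum(res$trace$status == "removed") +
                 nrow(res$prioritized), nrow(res$trace))
  expect_match(res$trace$failed[res$trace$gene == "BAD"], "population")

  res0 <- prioritize_patient("p2", v, g, cfg)
  expect_equal(nrow(res0$prioritized), 0)
  expect_equal(nrow(res0$trace), 0)
})

test_that("removed variants record exactly one failing filter under short-circuit trace order", {
  v <- random_variant_table(300, seed = 7)
  g <- do.call(make_genotypes, purrr::map(v$variant_id, ~ list(.x, "p1", "het")))
  res <- prioritize_patient("p1", v, g, cfg,
                            mito_genes = sprintf("G%04d", 1:50))
  removed <- res$trace[res$trace$status == "removed", ]
  first_fail <- purrr::map_chr(strsplit(removed$failed, ","), 1)
  # reason of the first failing filter is populated; earlier filters passed
  for (i in seq_len(nrow(removed))) {
    expect_false(is.na(removed[[paste0("reason_", first_fail[i])]][i]))
    earlier <- cfg$filter_order[seq_len(match(first_fail[i], cfg$filter_order) - 1)]
    for (f in earlier) expect_true(removed[[paste0("pass_", f)]][i])
  }
})

test_that("the cascade is order-invariant and monotone, and recovery only ever adds variants", {
  v <- random_variant_table(1000, seed = 42)
  g <- do.call(make_genotypes, purrr::map(v$variant_id, ~ list(.x, "p1", "het")))
  mito <- sprintf("G%04d", 1:60)
  base <- prioritize_patient("p1", v, g, cfg, mito_genes = mito)
  withr::with_seed(11, {
    for (k in 1:5) {
      ord <- sample(cfg$filter_order)
      cfg_perm <- filter_config(filter_order = ord)
      perm <- prioritize_patient("p1", v, g, cfg_perm, mito_genes = mito)
      expect_equal(
        perm$trace$status[order(perm$trace$variant_id)],
        base$trace$status[order(base$trace$variant_id)]
      )
    }
  })
  # monotonicity: dropping a filter never shrinks the main-pass survivor set
  for (drop in cfg$filter_order) {
    cfg_sub <- filter_config(filter_order = setdiff(cfg$filter_order, drop))
    sub <- prioritize_patient("p1", v, g, cfg_sub, mito_genes = mito)
    main_full <- base$trace$variant_id[base$trace$status == "prioritized_main"]
    main_sub <- sub$trace$variant_id[sub$trace$status == "prioritized_main"]
    expect_true(all(main_full %in% main_sub))
  }
  # recovery restorations all failed only waivable filters and sit in mito genes
  rec <- base$trace[base$trace$status == "prioritized_recovery", ]
  expect_true(all(rec$gene %in% mito))
  expect_true(all(purrr::map_lgl(
    strsplit(rec$failed, ","),
    ~ all(.x %in% c("segdup", "deleteriousness"))
  )))
})

test_that("planted causal nuclear variants all survive the cascade on the default cohort", {
  co <- default_cohort()
  dx <- default_diagnosis()
  planted <- co$truth[co$truth$variant_ids != "" &
                        !is.na(co$truth$expected_category), ]
  for (i in seq_len(nrow(planted))) {
    vids <- strsplit(planted$variant_ids[i], ",")[[1]]
    mine <- dx$prioritized[dx$prioritized$sample_id == planted$sample_id[i], ]
    expect_true(all(vids %in% mine$variant_id),
                info = paste(planted$sample_id[i], planted$mechanism[i]))
  }
})
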
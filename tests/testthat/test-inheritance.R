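# Recessive-model consistency, phasing, de novo detection and segregation.

test_that("recessive consistency classifies homozygous, compound-het, hemizygous and rejects lone inherited hets", {
  hom <- tibble::tibble(variant_id = "v1", chrom = "chr1", gt = "hom_alt")
  expect_equal(check_recessive_consistency(hom, "female"), "hom_recessive")

  lone <- tibble::tibble(variant_id = "v1", chrom = "chr1", gt = "het")
  expect_equal(check_recessive_consistency(lone, "female"), "reject")
  expect_equal(check_recessive_consistency(lone, "female",
                                           de_novo = TRUE),
               "de_novo_dominant")

  xv <- tibble::tibble(variant_id = "v1", chrom = "chrX", gt = "hemi_alt")
  expect_equal(check_recessive_consistency(xv, "male"), "x_hemizygous")
  # het male X calls are coerced to hemizygous with a warning
  xh <- tibble::tibble(variant_id = "v1", chrom = "chrX", gt = "het")
  expect_warning(m <- check_recessive_consistency(xh, "male"), "coerced")
  expect_equal(m, "x_hemizygous")

  pair <- tibble::tibble(variant_id = c("v1", "v2"), chrom = "chr1",
                         gt = c("het", "het"))
  expect_equal(check_recessive_consistency(pair, "female"), "compound_het")
})

test_that("trio phasing: one variant from each parent is trans, both from one parent is cis, ambiguity is unknown", {
  trans <- phase_compound_het(father_gt = c("het", "hom_ref"),
                              mother_gt = c("hom_ref", "het"))
  expect_equal(trans$phase, "in_trans")
  cis <- phase_compound_het(father_gt = c("het", "het"),
                            mother_gt = c("hom_ref", "hom_ref"))
  expect_equal(cis$phase, "in_cis")
  unk <- phase_compound_het(father_gt = NULL, mother_gt = NULL)
  expect_equal(unk$phase, "unknown")
  # molecular phase groups override genotype reasoning
  pg_cis <- phase_compound_het(father_gt = c("het", "hom_ref"),
                               mother_gt = c("hom_ref", "het"),
                               phase_groups = c("hapA", "hapA"))
  expect_equal(pg_cis$phase, "in_cis")
  # a child allele absent from both parents is flagged, not phased
  viol <- phase_compound_het(father_gt = c("hom_ref", "het"),
                             mother_gt = c("hom_ref", "hom_ref"))
  expect_false(viol$mendelian_ok)
})

test_that("trio phasing agrees with brute-force haplotype enumeration over all 81 parental genotype combinations", {
  gts <- c("hom_ref", "het", "hom_alt")
  n_checked <- 0L
  for (f1 in gts) for (f2 in gts) for (m1 in gts) for (m2 in gts) {
    oracle <- phase_oracle(c(f1, f2), c(m1, m2))
    got <- phase_compound_het(father_gt = c(f1, f2), mother_gt = c(m1, m2))
    info <- sprintf("father=(%s,%s) mother=(%s,%s)", f1, f2, m1, m2)
    if (oracle$consistent) {
      expect_true(got$mendelian_ok, info = info)
      expect_equal(got$phase, oracle$phase, info = info)
    } else {
      expect_false(got$mendelian_ok, info = info)
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 81L)
})

test_that("de novo detection requires the allele absent from both genotyped parents", {
  expect_true(detect_de_novo("het", "hom_ref", "hom_ref")$de_novo)
  expect_false(detect_de_novo("het", "hom_ref", "het")$de_novo)
  miss <- detect_de_novo("het", NULL, "hom_ref")
  expect_false(miss$de_novo)
  expect_match(miss$reason, "missing")
  # hemizygous male X alt with a clear mother is de novo
  expect_true(detect_de_novo("hemi_alt", "hom_ref", "hom_ref",
                             chrom = "chrX", sex = "male")$de_novo)
})

test_that("segregation is consistent when affected relatives share the configuration and unaffected ones do not", {
  relatives <- tibble::tibble(
    sample_id = c("sib1", "dad", "mum"),
    affected = c(TRUE, FALSE, FALSE),
    sex = c("male", "male", "female"),
    gts = list("hom_alt", "het", "het"),
    chrom = list("chr1", "chr1", "chr1")
  )
  seg <- check_segregation("hom_recessive", relatives)
  expect_equal(seg$segregation, "consistent")
  expect_true(seg$informative)

  bad <- relatives
  bad$affected <- c(FALSE, FALSE, FALSE)  # unaffected sib homozygous
  seg2 <- check_segregation("hom_recessive", bad)
  expect_equal(seg2$segregation, "inconsistent")

  expect_equal(check_segregation("hom_recessive", NULL)$segregation,
               "untested")
})

test_that("call_inheritance integrates trio phasing and drops cis-only pairs, with no de novo calls on fully inherited trios", {
  v <- dplyr::bind_rows(
    make_variants(n = 2, pos = c(10L, 20L), gene = "GENE1"),
    make_variants(n = 2, pos = c(30L, 40L), gene = "GENE2")
  )
  ped <- make_trio_ped()
  g <- make_genotypes(
    # GENE1: trans pair (one from each parent)
    list(v$variant_id[1], "kid", "het"), list(v$variant_id[1], "dad", "het"),
    list(v$variant_id[2], "kid", "het"), list(v$variant_id[2], "mum", "het"),
    # GENE2: cis pair (both paternal)
    list(v$variant_id[3], "kid", "het"), list(v$variant_id[3], "dad", "het"),
    list(v$variant_id[4], "kid", "het"), list(v$variant_id[4], "dad", "het")
  )
  pri <- v %>% dplyr::inner_join(
    g %>% dplyr::filter(.data$sample_id == "kid") %>%
      dplyr::select("variant_id", "gt"),
    by = "variant_id"
  )
  calls <- call_inheritance(pri, "kid", g, ped)
  expect_equal(calls$gene, "GENE1")
  expect_equal(calls$model, "compound_het")
  expect_equal(calls$phase, "in_trans")
  expect_false(any(calls$de_novo))
})

test_that("no de novo events fire on the default synthetic cohort beyond the planted ones", {
  co <- default_cohort()
  dx <- default_diagnosis()
  dn_findings <- dx$findings %>%
    dplyr::filter(purrr::map_lgl(.data$tags, ~ "de_novo" %in% .x))
  planted_dn <- co$truth$sample_id[
    co$truth$mechanism %in% c("de_novo_dominant", "x_hemizygous")]
  expect_true(all(dn_findings$sample_id %in% planted_dn))
})
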
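# Readers/writers for VCF, PED, BED, annotation and gene lists.

write_tiny_cohort <- function(dir, drop_annotation_for = NULL) {
  v <- make_variants(
    n = 3, chrom = c("chr1", "chr2", "chrX"),
    pos = c(100L, 200L, 300L), ref = c("A", "C", "G"),
    alt = c("G", "T", "A"), gene = c("G0001", "G0002", "G0003"),
    sift = c(0.01, NA, 0.5), gerp = c(3, 4, NA)
  )
  g <- make_genotypes(
    list(v$variant_id[1], "s1", "het"),
    list(v$variant_id[1], "s2", "hom_alt"),
    list(v$variant_id[2], "s2", "het"),
    list(v$variant_id[3], "s1", "hemi_alt")
  )
  vcf <- file.path(dir, "t.vcf")
  ann <- file.path(dir, "t.tsv")
  write_cohort_vcf(v, g, vcf)
  a <- dplyr::select(v, -"variant_id")
  if (!is.null(drop_annotation_for)) {
    a <- a[a$pos != drop_annotation_for, ]
  }
  readr::write_tsv(a, ann)
  list(vcf = vcf, ann = ann, variants = v, genotypes = g)
}

test_that("a VCF with matching annotation yields one variant per allele and genotypes for all samples", {
  d <- withr::local_tempdir()
  fx <- write_tiny_cohort(d)
  cv <- read_cohort_vcf(fx$vcf, fx$ann)
  expect_setequal(cv$variants$variant_id, fx$variants$variant_id)
  expect_equal(nrow(cv$genotypes), 3 * 2)  # 3 alleles x 2 samples
  got <- cv$genotypes[cv$genotypes$gt != "hom_ref", ]
  expect_setequal(
    paste(got$variant_id, got$sample_id, got$gt),
    paste(fx$genotypes$variant_id, fx$genotypes$sample_id, fx$genotypes$gt)
  )
})

test_that("VCF alleles without an annotation row are excluded with a warning, not silently dropped", {
  d <- withr::local_tempdir()
  fx <- write_tiny_cohort(d, drop_annotation_for = 200L)
  expect_warning(cv <- read_cohort_vcf(fx$vcf, fx$ann), "no annotation row")
  expect_equal(nrow(cv$variants), 2)
  expect_false("chr2:200:C:T" %in% cv$genotypes$variant_id)
})

test_that("annotation key collisions and unknown class labels are errors", {
  d <- withr::local_tempdir()
  v <- make_variants(n = 2, pos = c(10L, 10L))
  readr::write_tsv(dplyr::select(v, -"variant_id"), file.path(d, "dup.tsv"))
  expect_error(read_annotation(file.path(d, "dup.tsv")), "collision")
  v2 <- make_variants(n = 1, class = "weird")
  readr::write_tsv(dplyr::select(v2, -"variant_id"), file.path(d, "cls.tsv"))
  expect_error(read_annotation(file.path(d, "cls.tsv")), "unknown functional class")
})

test_that("multi-allelic VCF records are split into one variant per alternate allele", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t500\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2"
  ), vcf)
  v <- make_variants(n = 2, pos = c(500L, 500L), ref = "A",
                     alt = c("G", "T"))
  readr::write_tsv(dplyr::select(v, -"variant_id"), file.path(d, "m.tsv"))
  cv <- read_cohort_vcf(vcf, file.path(d, "m.tsv"))
  expect_setequal(cv$variants$alt, c("G", "T"))
  g <- cv$genotypes
  expect_equal(g$gt[g$variant_id == "chr1:500:A:G" & g$sample_id == "s1"], "het")
  expect_equal(g$gt[g$variant_id == "chr1:500:A:G" & g$sample_id == "s2"], "hom_ref")
  expect_equal(g$gt[g$variant_id == "chr1:500:A:T" & g$sample_id == "s2"], "het")
})

test_that("write -> read round-trip preserves keys and carried genotypes exactly", {
  co <- default_cohort()
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  cv <- read_cohort_vcf(paths[["vcf"]], paths[["annotation"]])
  expect_setequal(cv$variants$variant_id, co$variants$variant_id)
  carried <- cv$genotypes[cv$genotypes$gt != "hom_ref", ]
  expect_setequal(
    paste(carried$variant_id, carried$sample_id, carried$gt),
    paste(co$genotypes$variant_id, co$genotypes$sample_id, co$genotypes$gt)
  )
  ped <- read_pedigree(paths[["ped"]])
  expect_equal(
    dplyr::arrange(ped, .data$sample_id),
    dplyr::arrange(co$pedigree, .data$sample_id)
  )
})

test_that("pedigree reading resolves trios and rejects broken parentage", {
  d <- withr::local_tempdir()
  ped_path <- file.path(d, "trio.ped")
  writeLines(c("F1\tdad\t0\t0\t1\t1",
               "F1\tmum\t0\t0\t2\t1",
               "F1\tkid\tdad\tmum\t2\t2"), ped_path)
  ped <- read_pedigree(ped_path)
  trios <- pedigree_trios(ped)
  expect_equal(nrow(trios), 1)
  expect_equal(trios$father_id, "dad")

  writeLines("F1\tsolo\t0\t0\t1\t2", file.path(d, "solo.ped"))
  expect_equal(nrow(pedigree_trios(read_pedigree(file.path(d, "solo.ped")))), 0)

  writeLines(c("F1\tkid\tdad\t0\t1\t2"), file.path(d, "orphan.ped"))
  expect_error(read_pedigree(file.path(d, "orphan.ped")), "unknown parent")

  writeLines(c("F1\ta\tb\t0\t1\t2", "F1\tb\ta\t0\t1\t1"),
             file.path(d, "cycle.ped"))
  expect_error(read_pedigree(file.path(d, "cycle.ped")), "cyclic")
})

test_that("BED regions convert to 1-based inclusive coordinates at the boundary", {
  d <- withr::local_tempdir()
  bed <- file.path(d, "r.bed")
  writeLines("chr1\t999\t2000\tsegdup1", bed)
  r <- read_bed_regions(bed)
  expect_equal(r$start, 1000L)
  expect_equal(r$end, 2000L)
  # Round trip through the writer restores the same 1-based coordinates.
  write_bed_regions <- mitodx:::write_bed_regions
  out <- file.path(d, "rt.bed")
  write_bed_regions(r, out)
  expect_equal(read_bed_regions(out)$start, 1000L)
  expect_equal(read_bed_regions(out)$end, 2000L)
})

test_that("gene lists and the mtDNA catalog read cleanly", {
  d <- withr::local_tempdir()
  writeLines(c("G0001", "", "G0002 "), file.path(d, "g.txt"))
  expect_equal(read_gene_list(file.path(d, "g.txt")), c("G0001", "G0002"))
  cat_path <- system.file("extdata", "synthetic_mt_catalog.tsv",
                          package = "mitodx")
  ctl <- read_mt_catalog(cat_path)
  expect_true(all(ctl$status %in% c("confirmed", "reported")))
  expect_true(all(ctl$pos >= 1 & ctl$pos <= MT_GENOME_LENGTH))
})
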
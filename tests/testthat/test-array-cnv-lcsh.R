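# Array arm: segmentation, CNV prioritization, LCSH, the exact HWE founder
# screen and composite CNV+SNV logic.

make_probes <- function(n = 200, chrom = "chr1", spacing = 25000L,
                        log2 = 0, genotype = "AB") {
  tibble::tibble(
    chrom = chrom, pos = spacing * seq_len(n),
    genotype = rep_len(genotype, n), log2_ratio = rep_len(log2, n)
  )
}

test_that("segmentation finds maximal qualifying runs with exact boundaries and respects the probe-count gate", {
  p <- make_probes(200)
  p$log2_ratio[61:120] <- -1.0  # 60 consecutive probes, 1.48 Mb span
  segs <- segment_copy_number(p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$state, "deletion")
  expect_equal(segs$start, p$pos[61])
  expect_equal(segs$end, p$pos[120])
  expect_equal(segs$n_probes, 60L)
  expect_equal(segs$size_kb, (p$pos[120] - p$pos[61] + 1) / 1000)

  expect_equal(nrow(segment_copy_number(make_probes(200))), 0)

  p2 <- make_probes(200)
  p2$log2_ratio[50:51] <- -1.0  # only 2 qualifying probes
  expect_equal(nrow(segment_copy_number(p2)), 0)

  # duplications segment on the positive threshold
  p3 <- make_probes(200)
  p3$log2_ratio[10:30] <- 0.5
  expect_equal(segment_copy_number(p3)$state, "duplication")

  p_unsorted <- make_probes(10)[c(2, 1, 3:10), ]
  expect_error(segment_copy_number(p_unsorted), "not sorted")
})

test_that("gaps up to max_gap are absorbed into a segment; longer gaps split it", {
  p <- make_probes(100)
  p$log2_ratio[21:60] <- -1.0
  p$log2_ratio[40:41] <- 0     # 2-probe gap: absorbed by default
  segs <- segment_copy_number(p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_probes, 38L)
  p$log2_ratio[40:43] <- 0     # 4-probe gap: splits
  expect_equal(nrow(segment_copy_number(p)), 2)
})

test_that("CNV prioritization applies the strict >100 kb gate, control-overlap filter and disorder annotation", {
  segs <- tibble::tibble(
    chrom = c("chr6", "chr6", "chr2"),
    start = c(10000001L, 30000001L, 20000001L),
    end = c(11675000L, 30099000L, 20300000L),
    state = "deletion",
    size_kb = c(1675, 99, 300),
    n_probes = c(67L, 5L, 12L)
  )
  controls <- tibble::tibble(chrom = "chr2", start = 20000001L,
                             end = 20300000L)
  disorders <- tibble::tibble(chrom = "chr6", start = 9800001L,
                              end = 11875000L,
                              name = "congenital heart defects")
  out <- prioritize_cnv(segs, controls, disorders)
  expect_equal(nrow(out), 1)            # 99 kb fails size, chr2 is in controls
  expect_equal(out$chrom, "chr6")
  expect_equal(out$disorder, "congenital heart defects")
  expect_equal(out$control_overlap, 0)

  # reciprocal overlap: a 90%-overlapping control segment removes the CNV
  controls2 <- tibble::tibble(chrom = "chr6", start = 10000001L,
                              end = as.integer(10000000 + 0.9 * 1675000))
  out2 <- prioritize_cnv(segs[1, ], controls2, disorders)
  expect_equal(nrow(out2), 0)
  # brute-force check of the reciprocal fraction used
  ov <- length(intersect(seq(10000001, 11675000),
                         seq(controls2$start, controls2$end)))
  expect_gte(min(ov / 1675000, ov / (controls2$end - controls2$start + 1)),
             0.5)
})

test_that("LCSH detection reports maximal homozygous runs above the span threshold", {
  p <- make_probes(400, genotype = "AB")
  hom_idx <- 101:212  # 112 probes = 2.8 Mb span at 25 kb spacing
  p$genotype[hom_idx] <- rep_len(c("AA", "BB"), length(hom_idx))
  runs <- detect_lcsh(p, min_mb = 1.0)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start, p$pos[101])
  expect_equal(runs$end, p$pos[212])
  expect_equal(runs$length_mb, (p$pos[212] - p$pos[101] + 1) / 1e6)

  # alternating genotypes yield no runs
  alt <- make_probes(100, genotype = c("AA", "AB"))
  expect_equal(nrow(detect_lcsh(alt, min_mb = 0.01)), 0)

  # short stretches are threshold-dependent: hidden at 1.0 Mb, visible at 0.1
  p2 <- make_probes(100, genotype = "AB")
  p2$genotype[40:52] <- "AA"  # 0.3 Mb
  expect_equal(nrow(detect_lcsh(p2, min_mb = 1.0)), 0)
  expect_equal(nrow(detect_lcsh(p2, min_mb = 0.1)), 1)

  # runs are maximal: extending either end would add a het probe
  ext <- runs
  expect_equal(p$genotype[100], "AB")
  expect_equal(p$genotype[213], "AB")
})

test_that("isolated het interrupts are tolerated only when allowed", {
  p <- make_probes(100, genotype = "AB")
  p$genotype[20:60] <- "AA"
  p$genotype[40] <- "AB"
  expect_equal(nrow(detect_lcsh(p, min_mb = 1.0, max_het_interrupt = 0L)), 0)
  runs <- detect_lcsh(p, min_mb = 1.0, max_het_interrupt = 1L)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_probes, 40L)
})

test_that("the exact HWE test matches closed-form enumeration for every genotype triple up to n = 30", {
  for (n in 1:30) {
    for (n_bb in 0:n) {
      for (n_ab in 0:(n - n_bb)) {
        n_aa <- n - n_bb - n_ab
        expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                     hwe_oracle(n_aa, n_ab, n_bb),
                     tolerance = 1e-10,
                     info = sprintf("(%d,%d,%d)", n_aa, n_ab, n_bb))
      }
    }
  }
})

test_that("HWE edge cases: exact proportions and monomorphic sites give p = 1; founder-like homozygote excess is flagged", {
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_error(hwe_exact_test(-1, 0, 0), "non-negative")
  # three homozygotes and one carrier among 142: strong HW violation
  p <- hwe_exact_test(138, 1, 3)
  expect_equal(p, hwe_oracle(138, 1, 3), tolerance = 1e-10)
  expect_lt(p, 1e-4)
  scr <- hwe_screen(tibble::tibble(variant_id = c("founder", "normal"),
                                   n_aa = c(138, 120), n_ab = c(1, 20),
                                   n_bb = c(3, 2)))
  expect_true(scr$violated[scr$variant_id == "founder"])
  expect_false(scr$violated[scr$variant_id == "normal"])
})

test_that("composite CNV+SNV promotion pairs het deletions with het variants and notes impossible homozygotes", {
  genes <- tibble::tibble(gene = c("COXL", "FARL"), chrom = c("chr5", "chr5"),
                          start = c(1000000L, 9000000L),
                          end = c(1020000L, 9020000L))
  segs <- tibble::tibble(chrom = "chr5", start = 900000L, end = 2300000L,
                         state = "deletion", size_kb = 1400, n_probes = 50L)
  pri <- make_variants(n = 2, chrom = "chr5", pos = c(1005000L, 9005000L),
                       gene = c("COXL", "FARL")) %>%
    dplyr::mutate(gt = c("het", "het"))
  comp <- detect_composite_cnv_snv(segs, pri, genes)
  expect_equal(comp$gene, "COXL")  # FARL is outside the deletion
  expect_true(is.na(comp$note))

  pri2 <- pri %>% dplyr::mutate(gt = c("hom_alt", "het"))
  comp2 <- detect_composite_cnv_snv(segs, pri2, genes)
  expect_match(comp2$note, "hemizygous")

  # a deletion with no co-occurring variant yields no composite
  expect_equal(nrow(detect_composite_cnv_snv(segs, pri[0, ], genes)), 0)
})
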
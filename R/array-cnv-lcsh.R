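# SNP-array arm: deterministic copy-number segmentation, CNV prioritization
# against control panels and known-disorder regions, detection of long
# contiguous stretches of homozygosity (LCSH), the cohort Hardy-Weinberg
# founder screen, and composite CNV+SNV compound-heterozygote detection.

#' Segment copy number from probe log2 ratios
#'
#' A deterministic threshold/run-length segmenter: maximal runs of at least
#' `min_probes` probes whose log2 ratio is beyond the deletion or
#' duplication threshold, tolerating up to `max_gap` consecutive
#' non-qualifying probes inside a run, become segments. Segment boundaries
#' are the first and last qualifying probe positions. Replaces the vendor
#' hidden-Markov callers used upstream of the published screen with fully
#' specified, exactly reproducible behaviour; the prioritization logic, not
#' the caller, is the contribution here.
#'
#' @param probes Tibble for one sample with `chrom`, `pos`, `log2_ratio`
#'   sorted by position within chromosome.
#' @param del_thresh Log2 ratio at or below which a probe supports a
#'   deletion (default -0.3).
#' @param dup_thresh Log2 ratio at or above which a probe supports a
#'   duplication (default +0.26).
#' @param min_probes Minimum qualifying probes per segment (default 10).
#' @param max_gap Maximum run of interleaved non-qualifying probes absorbed
#'   into a segment (default 2).
#' @return Tibble of segments: `chrom`, `start`, `end` (1-based inclusive),
#'   `state` (deletion/duplication), `size_kb`, `n_probes`.
#' @export
segment_copy_number <- function(probes, del_thresh = -0.3, dup_thresh = 0.26,
                                min_probes = 10L, max_gap = 2L) {
  assert_columns(probes, c("chrom", "pos", "log2_ratio"), "probe table")
  segs <- list()
  for (chr in unique(probes$chrom)) {
    p <- probes[probes$chrom == chr, ]
    if (is.unsorted(p$pos)) {
      abort(sprintf("probes on %s are not sorted by position", chr))
    }
    for (state in c("deletion", "duplication")) {
      qual <- if (state == "deletion") {
        p$log2_ratio <= del_thresh
      } else {
        p$log2_ratio >= dup_thresh
      }
      segs[[length(segs) + 1]] <-
        qualifying_runs(qual, min_probes, max_gap) %>%
        mutate(chrom = chr, state = state,
               start = p$pos[.data$first], end = p$pos[.data$last])
    }
  }
  out <- bind_rows(segs)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  state = character(), size_kb = numeric(),
                  n_probes = integer()))
  }
  out %>%
    mutate(size_kb = (.data$end - .data$start + 1) / 1000) %>%
    select("chrom", "start", "end", "state", "size_kb", "n_probes") %>%
    arrange(.data$chrom, .data$start)
}

# Maximal runs of TRUE in `qual`, allowing interior FALSE gaps of up to
# max_gap, with at least min_probes TRUE members. Returns first/last TRUE
# indices and the TRUE count per run.
qualifying_runs <- function(qual, min_probes, max_gap) {
  idx <- which(qual)
  if (length(idx) == 0) {
    return(tibble(first = integer(), last = integer(), n_probes = integer()))
  }
  breaks <- which(diff(idx) > max_gap + 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  tibble(
    first = idx[starts],
    last = idx[ends],
    n_probes = ends - starts + 1L
  ) %>% filter(.data$n_probes >= min_probes)
}

# Largest reciprocal-overlap fraction between a segment and a set of
# regions on the same chromosome (0 when none overlap).
max_reciprocal_overlap <- function(chrom, start, end, regions) {
  r <- regions[regions$chrom == chrom, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  ov <- interval_overlap(start, end, r$start, r$end)
  frac <- pmin(ov / (end - start + 1), ov / (r$end - r$start + 1))
  max(frac)
}

#' Prioritize copy-number segments
#'
#' Keeps rather large segments (strictly more than `min_kb` kilobases) not
#' explained by the control panel (reciprocal overlap with any control CNV
#' below `control_overlap_max`), and annotates survivors with any
#' overlapping known genomic-disorder region. Manual database curation is
#' represented by the disorder-region annotation plus the free-text `curation`
#' column on the output.
#'
#' @param segments Segment tibble from [segment_copy_number()].
#' @param control_cnvs Control-cohort CNV regions (1-based tibble).
#' @param disorder_regions Known genomic-disorder regions with a `name`
#'   column.
#' @param min_kb Minimum size in kb, strict (default 100: ">100 kb").
#' @param control_overlap_max Reciprocal-overlap fraction at or above which
#'   a segment counts as present in controls (default 0.5).
#' @return Prioritized segments with `control_overlap`, `disorder` (region
#'   name or NA) and an empty `curation` column.
#' @export
prioritize_cnv <- function(segments, control_cnvs = NULL,
                           disorder_regions = NULL, min_kb = 100,
                           control_overlap_max = 0.5) {
  if (nrow(segments) == 0) {
    return(mutate(segments, control_overlap = numeric(),
                  disorder = character(), curation = character()))
  }
  segs <- segments %>% filter(.data$size_kb > min_kb)
  if (nrow(segs) == 0) {
    return(mutate(segs, control_overlap = numeric(),
                  disorder = character(), curation = character()))
  }
  segs$control_overlap <- purrr::pmap_dbl(
    segs %>% select("chrom", "start", "end"),
    function(chrom, start, end) {
      if (is.null(control_cnvs)) 0 else {
        max_reciprocal_overlap(chrom, start, end, control_cnvs)
      }
    }
  )
  segs <- segs %>% filter(.data$control_overlap < control_overlap_max)
  segs$disorder <- purrr::pmap_chr(
    segs %>% select("chrom", "start", "end"),
    function(chrom, start, end) {
      if (is.null(disorder_regions)) return(NA_character_)
      r <- disorder_regions[disorder_regions$chrom == chrom, , drop = FALSE]
      if (nrow(r) == 0) return(NA_character_)
      ov <- interval_overlap(start, end, r$start, r$end)
      if (all(ov == 0)) NA_character_ else r$name[which.max(ov)]
    }
  )
  segs$curation <- NA_character_
  segs
}

#' Detect long contiguous stretches of homozygosity (LCSH)
#'
#' Maximal runs of homozygous genotype calls (AA or BB), allowing up to
#' `max_het_interrupt` isolated heterozygous calls inside a run, spanning at
#' least `min_mb` megabases. No-calls do not interrupt a run and do not
#' count as homozygous members.
#'
#' @param probes Tibble for one sample with `chrom`, `pos`, `genotype`
#'   (AA/AB/BB/no-call), sorted by position within chromosome.
#' @param min_mb Minimum reported span in megabases (default 1.0; founder
#'   stretches down to ~0.1 Mb can be surfaced by lowering this).
#' @param max_het_interrupt Isolated het calls tolerated per run (default 0).
#' @return Tibble of runs: `chrom`, `start`, `end`, `length_mb`, `n_probes`.
#' @export
detect_lcsh <- function(probes, min_mb = 1.0, max_het_interrupt = 0L) {
  assert_columns(probes, c("chrom", "pos", "genotype"), "probe table")
  runs <- list()
  for (chr in unique(probes$chrom)) {
    p <- probes[probes$chrom == chr & probes$genotype != "no-call", ]
    if (nrow(p) == 0) next
    if (is.unsorted(p$pos)) {
      abort(sprintf("probes on %s are not sorted by position", chr))
    }
    hom <- p$genotype %in% c("AA", "BB")
    idx <- which(hom)
    if (length(idx) == 0) next
    # Break where more than max_het_interrupt het probes intervene.
    breaks <- which((diff(idx) - 1L) > max_het_interrupt)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, length(idx))
    runs[[length(runs) + 1]] <- tibble(
      chrom = chr,
      start = p$pos[idx[starts]],
      end = p$pos[idx[ends]],
      n_probes = ends - starts + 1L
    )
  }
  out <- bind_rows(runs)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length_mb = numeric(), n_probes = integer()))
  }
  out %>%
    mutate(length_mb = (.data$end - .data$start + 1) / 1e6) %>%
    filter(.data$length_mb >= min_mb) %>%
    select("chrom", "start", "end", "length_mb", "n_probes") %>%
    arrange(.data$chrom, .data$start)
}

#' Exact Hardy-Weinberg equilibrium test for one biallelic variant
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count. The
#' conditional distribution is computed by the standard stable recurrence
#' over heterozygote counts.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major hom, het, minor hom).
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) abort("genotype counts must be non-negative")
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_minor <- 2 * min(n_aa, n_bb) + n_ab
  # Feasible het counts share the parity of the minor allele count.
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  if (length(hets) == 1) return(1)
  # Unnormalised probabilities via the recurrence
  #   P(h+2)/P(h) = 4 * n_AA(h) * n_BB(h) / ((h+2) * (h+1))
  # walked from the mid-range mode for numerical stability.
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_minor * (2 * n - n_minor) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      h <- hets[i]
      hom_minor <- (n_minor - h) / 2
      hom_major <- n - h - hom_minor
      probs[i + 1] <- probs[i] * 4 * hom_minor * hom_major /
        ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- hets[i]
      hom_minor <- (n_minor - h) / 2
      hom_major <- n - h - hom_minor
      probs[i - 1] <- probs[i] * h * (h - 1) /
        (4 * (hom_minor + 1) * (hom_major + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n_ab]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Cohort Hardy-Weinberg founder screen
#'
#' Applies the exact test to each variant's genotype counts and flags
#' violations after multiple-testing adjustment; in an outbred case series a
#' rare variant violating Hardy-Weinberg through homozygote excess is the
#' signature of a shared founder allele.
#'
#' @param genotype_counts Tibble with `variant_id`, `n_aa`, `n_ab`, `n_bb`.
#' @param alpha Significance level after adjustment (default 0.05).
#' @param method Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default Bonferroni).
#' @return Input with `p_value`, `p_adjusted` and `violated` columns.
#' @export
hwe_screen <- function(genotype_counts, alpha = 0.05, method = "bonferroni") {
  assert_columns(genotype_counts, c("variant_id", "n_aa", "n_ab", "n_bb"),
                 "genotype counts")
  out <- genotype_counts %>%
    mutate(p_value = purrr::pmap_dbl(
      list(.data$n_aa, .data$n_ab, .data$n_bb), hwe_exact_test
    ))
  out %>%
    mutate(p_adjusted = p.adjust(.data$p_value, method = method),
           violated = .data$p_adjusted < alpha)
}

#' Genotype counts per variant for a set of samples
#'
#' @param genotypes Long genotype tibble.
#' @param sample_ids Samples to count over (e.g. the case cohort).
#' @return Tibble `variant_id`, `n_aa`, `n_ab`, `n_bb` (missing and
#'   hemizygous calls are excluded; the screen is autosomal).
#' @export
genotype_counts <- function(genotypes, sample_ids) {
  # Samples with no genotype row at all for a variant are homozygous
  # reference (sparse representation); explicit missing or hemizygous calls
  # are excluded from the counts.
  genotypes %>%
    filter(.data$sample_id %in% sample_ids) %>%
    group_by(.data$variant_id) %>%
    summarise(
      n_aa = sum(.data$gt == "hom_ref") + (length(sample_ids) - dplyr::n()),
      n_ab = sum(.data$gt == "het"),
      n_bb = sum(.data$gt == "hom_alt"),
      .groups = "drop"
    )
}

#' Composite CNV + SNV biallelic candidates
#'
#' For each gene overlapped by a heterozygous deletion segment, any
#' prioritized heterozygous variant in that gene is promoted to a biallelic
#' (composite) candidate: the point variant sits on the remaining allele. A
#' homozygous-looking call inside a heterozygous deletion is reported as a
#' composite with a hemizygosity note (one allele deleted, the apparent
#' homozygote is in fact hemizygous).
#'
#' @param segments Prioritized deletion segments for one patient.
#' @param prioritized Patient's prioritized nuclear variants (`variant_id`,
#'   `gene`, `chrom`, `pos`, `gt`).
#' @param genes Gene catalog tibble (`gene`, `chrom`, `start`, `end`).
#' @return Tibble of composite findings: `gene`, `variant_id`, `gt`,
#'   `segment_chrom`, `segment_start`, `segment_end`, `note`.
#' @export
detect_composite_cnv_snv <- function(segments, prioritized, genes) {
  dels <- segments %>% filter(.data$state == "deletion")
  if (nrow(dels) == 0 || nrow(prioritized) == 0) {
    return(tibble(gene = character(), variant_id = character(),
                  gt = character(), segment_chrom = character(),
                  segment_start = integer(), segment_end = integer(),
                  note = character()))
  }
  hit_genes <- genes %>%
    inner_join(dels, by = "chrom", suffix = c("", "_seg"),
               relationship = "many-to-many") %>%
    filter(interval_overlap(.data$start, .data$end,
                            .data$start_seg, .data$end_seg) > 0)
  if (nrow(hit_genes) == 0) {
    return(tibble(gene = character(), variant_id = character(),
                  gt = character(), segment_chrom = character(),
                  segment_start = integer(), segment_end = integer(),
                  note = character()))
  }
  prioritized %>%
    inner_join(hit_genes %>%
                 select("gene", segment_chrom = "chrom",
                        segment_start = "start_seg",
                        segment_end = "end_seg"),
               by = "gene") %>%
    filter(.data$gt %in% c("het", "hom_alt")) %>%
    mutate(note = if_else(
      .data$gt == "hom_alt",
      "apparent homozygote inside het deletion: hemizygous in fact",
      NA_character_
    )) %>%
    select("gene", "variant_id", "gt", "segment_chrom", "segment_start",
           "segment_end", "note")
}
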
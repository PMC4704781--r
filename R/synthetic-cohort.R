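# Fully synthetic diagnostic cohort with planted causal mechanisms and an
# exported truth table. The generator emulates the statistical structure of
# a childhood-onset respiratory-chain-deficiency case series: rare-variant
# MAF spectra across population panels, trio transmission, founder
# haplotypes inside homozygosity stretches, heteroplasmic mtDNA events,
# circular-genome deletions and >100 kb CNVs. Everything is produced from a
# single seed and is byte-reproducible.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 48 cases with
#' parents (trios) and 48 healthy controls on a scaled-down genome (six
#' autosomes plus X, ~300 Mb, full-length 16,569 bp circular MT), a 5,000
#' gene catalog with 60 known OXPHOS disease genes (8 on X) inside a 1,000
#' gene mitochondria-related set, and one planted patient group per causal
#' mechanism. Founder homozygosity stretches span 2.8 Mb; heteroplasmy of
#' planted mtDNA point mutations is uniform on \[0.3, 1\]; depletion
#' patients' qPCR ratios centre on 0.2 of control with 4 replicates; the
#' planted chromosomal deletion is 1,675 kb.
#'
#' @param n_cases,n_controls Cohort sizes (planted mechanisms take the
#'   first cases; the remainder carry background variation only).
#' @param genome Named chromosome lengths; must include `MT`.
#' @param n_genes,n_known,n_mito Catalog size and subset sizes (known
#'   disease genes are a subset of the mitochondria-related set).
#' @param gene_length Length of each synthetic gene, bp.
#' @param background_rate Expected cascade-surviving background variants
#'   per individual (Poisson).
#' @param filtered_rate Expected background variants per individual removed
#'   by some cascade filter (Poisson, split across failure flavours).
#' @param maf_frac_novel Fraction of rare background variants absent from
#'   every panel.
#' @param mechanisms List of plant specifications from [plant_spec()].
#' @param probe_spacing Array probe spacing, bp.
#' @param lcsh_founder_mb Founder homozygosity stretch length, Mb.
#' @param heteroplasmy_range Uniform range for planted heteroplasmy.
#' @param mt_depth Mean mtDNA coverage depth.
#' @param mt_del_breakpoints First/last deleted base of the planted mtDNA
#'   deletion.
#' @param mt_del_heteroplasmy Fraction of deleted mtDNA molecules.
#' @param depletion_ratio_mean,depletion_ratio_sd qPCR ratio distribution
#'   for depletion patients (fraction of control).
#' @param qpcr_replicates Replicates per sample.
#' @param cnv_del_kb,cnv_snv_del_kb Planted deletion sizes, kb.
#' @param log2_sd Array log2-ratio noise SD.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return A `mitodx_sim_config` list.
#' @export
sim_config <- function(n_cases = 48L, n_controls = 48L,
                       genome = c(chr1 = 6e7, chr2 = 5e7, chr3 = 4.5e7,
                                  chr4 = 4e7, chr5 = 3.5e7, chr6 = 3e7,
                                  chrX = 4e7, MT = 16569),
                       n_genes = 5000L, n_known = 60L, n_mito = 1000L,
                       gene_length = 20000L,
                       background_rate = 1.5, filtered_rate = 6,
                       maf_frac_novel = 0.5,
                       mechanisms = default_mechanisms(),
                       probe_spacing = 25000L,
                       lcsh_founder_mb = 2.8,
                       heteroplasmy_range = c(0.3, 1.0),
                       mt_depth = 150,
                       mt_del_breakpoints = c(11359L, 15068L),
                       mt_del_heteroplasmy = 0.7,
                       depletion_ratio_mean = 0.2,
                       depletion_ratio_sd = 0.02,
                       qpcr_replicates = 4L,
                       cnv_del_kb = 1675, cnv_snv_del_kb = 1387,
                       log2_sd = 0.12,
                       seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0, n_genes > 0, "MT" %in% names(genome),
            background_rate >= 0, filtered_rate >= 0)
  n_planted <- sum(purrr::map_int(mechanisms, "n_patients"))
  if (n_planted > n_cases) {
    abort("more planted patients than cases")
  }
  structure(as.list(environment()), class = "mitodx_sim_config")
}

#' Specification of one planted causal mechanism
#'
#' @param mechanism One of `recessive_hom_founder_lcsh`, `compound_het`,
#'   `de_novo_dominant`, `x_hemizygous`, `mtdna_point`, `mtdna_deletion`,
#'   `mtdna_depletion`, `cnv_deletion`, `cnv_plus_snv`, `none`.
#' @param n_patients Number of patients planted with this mechanism.
#' @return A `mitodx_plant_spec` list.
#' @export
plant_spec <- function(mechanism, n_patients = 1L) {
  mechs <- c("recessive_hom_founder_lcsh", "compound_het",
             "de_novo_dominant", "x_hemizygous", "mtdna_point",
             "mtdna_deletion", "mtdna_depletion", "cnv_deletion",
             "cnv_plus_snv", "none")
  if (!mechanism %in% mechs) {
    abort(sprintf("unknown mechanism: %s", mechanism))
  }
  structure(list(mechanism = mechanism, n_patients = as.integer(n_patients)),
            class = "mitodx_plant_spec")
}

#' Default planted mechanisms: one group per diagnostic class
#' @export
default_mechanisms <- function() {
  list(
    plant_spec("recessive_hom_founder_lcsh", 3L),
    plant_spec("compound_het", 5L),
    plant_spec("de_novo_dominant", 2L),
    plant_spec("x_hemizygous", 2L),
    plant_spec("mtdna_point", 4L),
    plant_spec("mtdna_deletion", 1L),
    plant_spec("mtdna_depletion", 2L),
    plant_spec("cnv_deletion", 2L),
    plant_spec("cnv_plus_snv", 1L)
  )
}

#' Built-in synthetic mtDNA pathogenicity catalog
#'
#' A small fully synthetic stand-in for a confirmed/reported mtDNA
#' pathogenicity catalog, used by the simulator and tests; positions echo
#' well-known pathogenic rCRS sites but the table carries no real
#' population content.
#' @return Tibble `pos`, `ref`, `alt`, `status`.
#' @export
synthetic_mt_catalog <- function() {
  tibble(
    pos = c(3243L, 8993L, 9176L, 10191L, 13513L, 4216L, 15928L),
    ref = c("A", "T", "T", "T", "G", "T", "G"),
    alt = c("G", "G", "C", "C", "A", "C", "A"),
    status = c(rep("confirmed", 5), rep("reported", 2))
  )
}

bases <- c("A", "C", "G", "T")

rand_alleles <- function(n) {
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tibble(ref = ref, alt = unname(alt))
}

# Build the deterministic gene catalog for a genome.
build_gene_catalog <- function(cfg) {
  nuclear <- cfg$genome[names(cfg$genome) != "MT"]
  n_per <- round(cfg$n_genes * nuclear / sum(nuclear))
  n_per[length(n_per)] <- cfg$n_genes - sum(n_per[-length(n_per)])
  rows <- purrr::imap(n_per, function(k, chr) {
    spacing <- floor(nuclear[[chr]] / (k + 1))
    start <- spacing * seq_len(k)
    tibble(chrom = chr, start = start,
           end = start + cfg$gene_length - 1L)
  })
  genes <- bind_rows(rows) %>%
    mutate(gene = sprintf("G%04d", row_number())) %>%
    select("gene", "chrom", "start", "end")

  # Known-gene quotas per chromosome guarantee targets for every planted
  # mechanism; quota genes sit away from chromosome ends so homozygosity
  # windows and deletions around them stay inside the chromosome.
  len_of <- setNames(as.numeric(nuclear), names(nuclear))
  interior <- genes$start > 3e6 & genes$end < len_of[genes$chrom] - 3e6
  pick <- function(chr, k) {
    pool <- genes$gene[genes$chrom == chr & interior]
    sample(pool, k)
  }
  quota <- c(pick("chrX", 8), pick("chr1", 4), pick("chr2", 8),
             pick("chr3", 4), pick("chr5", 3))
  known <- c(quota, sample(setdiff(genes$gene[interior], quota),
                           cfg$n_known - length(quota)))
  mito_extra <- sample(setdiff(genes$gene, known), cfg$n_mito - cfg$n_known)
  genes %>%
    mutate(is_known = .data$gene %in% known,
           is_mito = .data$gene %in% c(known, mito_extra))
}

# Annotation row template for a planted, cascade-surviving variant.
planted_variant_row <- function(genes, gene, offset, ref, alt, class,
                                sift, gerp, maf = list()) {
  g <- genes[genes$gene == gene, ]
  pos <- g$start + offset
  row <- tibble(
    chrom = g$chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, class = class,
    maf_dbsnp137 = maf$dbsnp137 %||% NA_real_,
    maf_esp6500 = maf$esp6500 %||% NA_real_,
    maf_1kg = maf$`1kg` %||% NA_real_,
    maf_exac = maf$exac %||% NA_real_,
    maf_hgvd = maf$hgvd %||% NA_real_,
    maf_1kjpn = maf$`1kjpn` %||% NA_real_,
    sift = sift, gerp = gerp,
    segdup = FALSE, dbsnp_medical_impact = FALSE, artifact_flag = FALSE,
    kjpn_hom = FALSE
  )
  row$variant_id <- variant_id(row$chrom, row$pos, row$ref, row$alt)
  row
}

# One background variant annotation row of a given failure flavour
# ("surviving" passes every filter).
background_variant_row <- function(genes, cfg, flavour) {
  g <- genes[sample(nrow(genes), 1), ]
  pos <- g$start + sample.int(cfg$gene_length, 1) - 1L
  al <- rand_alleles(1)
  class <- sample(c("missense", "nonsense", "splice_site",
                    "frameshift_indel", "inframe_indel"), 1,
                  prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
  sift <- if (class == "missense") runif(1, 0, 0.15) else NA_real_
  gerp <- runif(1, 2.5, 6)
  rare_maf <- function(max) if (runif(1) < 0.5) NA_real_ else runif(1, 0, max)
  maf <- if (runif(1) < cfg$maf_frac_novel) list() else list(
    dbsnp137 = rare_maf(0.010), esp6500 = rare_maf(0.001),
    `1kg` = rare_maf(0.010), exac = rare_maf(0.001),
    hgvd = rare_maf(0.004), `1kjpn` = rare_maf(0.004)
  )
  row <- planted_variant_row(genes, g$gene, pos - g$start, al$ref, al$alt,
                             class, sift, gerp, maf)
  if (flavour == "common") {
    row$maf_exac <- runif(1, 0.002, 0.05)
    row$maf_dbsnp137 <- runif(1, 0.02, 0.3)
  } else if (flavour == "tolerated") {
    row$class <- "missense"
    row$sift <- runif(1, 0.2, 0.9)
  } else if (flavour == "low_gerp") {
    row$gerp <- runif(1, -3, 2.4)
  } else if (flavour == "segdup") {
    row$segdup <- TRUE
  } else if (flavour == "synonymous") {
    row$class <- "other"
    row$sift <- NA_real_
  } else if (flavour == "artifact") {
    row$artifact_flag <- TRUE
  }
  row
}

#' Plant an mtDNA deletion into a circular coverage profile
#'
#' Per-base depth is Poisson around `depth_in` outside the deleted arc and
#' around `depth_out` inside it; the arc runs circularly from `start` to
#' `end` inclusive and may wrap the origin.
#'
#' @param start,end First and last deleted positions (1-based on the
#'   circle).
#' @param depth_in,depth_out Mean depths outside/inside the arc (> 0).
#' @param genome_len Circle length (default rCRS).
#' @return Tibble `pos`, `depth` with attributes `first_deleted`,
#'   `last_deleted` recording the planted truth.
#' @export
plant_mtdna_deletion <- function(start, end, depth_in = 150, depth_out = 45,
                                 genome_len = MT_GENOME_LENGTH) {
  if (depth_in <= 0 || depth_out <= 0) abort("depths must be positive")
  if (start < 1 || start > genome_len || end < 1 || end > genome_len) {
    abort("breakpoints must lie in 1..genome_len")
  }
  arc <- if (end >= start) seq.int(start, end) else {
    c(seq.int(start, genome_len), seq.int(1, end))
  }
  depth <- rpois(genome_len, depth_in)
  depth[arc] <- rpois(length(arc), depth_out)
  structure(tibble(pos = seq_len(genome_len), depth = depth),
            first_deleted = as.integer(start), last_deleted = as.integer(end))
}

#' Simulate a complete synthetic diagnostic cohort
#'
#' Generates, from one seed, every input the diagnostic pipeline consumes:
#' annotated nuclear variants and multi-sample genotypes (cases, parents,
#' controls), a pedigree with trios for every case, SNP-array probe tables,
#' mtDNA variant/coverage tables against a synthetic pathogenicity catalog,
#' a qPCR copy-ratio table, enzyme activities, wet-lab evidence tags, the
#' control-CNV and disorder-region panels, and a truth table stating each
#' planted patient's mechanism and expected diagnostic category.
#'
#' @param config A [sim_config()].
#' @return A `mitodx_cohort` list of tibbles (see Details in the package
#'   vignette); `$truth` is the planted truth table.
#' @export
simulate_cohort <- function(config = sim_config()) {
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  genes <- build_gene_catalog(cfg)
  case_ids <- sprintf("case%03d", seq_len(cfg$n_cases))
  control_ids <- sprintf("ctrl%03d", seq_len(cfg$n_controls))

  # -- pedigree: one trio per case, singleton controls --------------------
  forced_male <- character()
  mech_of <- rep("none", cfg$n_cases)
  i <- 1L
  for (m in cfg$mechanisms) {
    mech_of[seq.int(i, i + m$n_patients - 1L)] <- m$mechanism
    i <- i + m$n_patients
  }
  forced_male <- case_ids[mech_of == "x_hemizygous"]

  sexes <- sample(c("male", "female"), cfg$n_cases, replace = TRUE)
  sexes[case_ids %in% forced_male] <- "male"
  ped_cases <- tibble(
    family_id = sprintf("F%03d", seq_len(cfg$n_cases)),
    sample_id = case_ids,
    father_id = paste0(case_ids, "_fa"),
    mother_id = paste0(case_ids, "_mo"),
    sex = sexes, affected = TRUE
  )
  ped_parents <- bind_rows(
    tibble(family_id = ped_cases$family_id, sample_id = ped_cases$father_id,
           father_id = NA_character_, mother_id = NA_character_,
           sex = "male", affected = FALSE),
    tibble(family_id = ped_cases$family_id, sample_id = ped_cases$mother_id,
           father_id = NA_character_, mother_id = NA_character_,
           sex = "female", affected = FALSE)
  )
  ped_controls <- tibble(
    family_id = paste0("FC", seq_len(cfg$n_controls)),
    sample_id = control_ids,
    father_id = NA_character_, mother_id = NA_character_,
    sex = sample(c("male", "female"), cfg$n_controls, replace = TRUE),
    affected = FALSE
  )

  variants <- list()
  gts <- list()
  evidence <- list()
  truth <- list()
  extra_ped <- list()
  add_gt <- function(vid, sid, g) {
    gts[[length(gts) + 1]] <<- tibble(variant_id = vid, sample_id = sid,
                                      gt = g)
  }
  add_variant <- function(row) {
    variants[[length(variants) + 1]] <<- row
    row$variant_id
  }
  add_truth <- function(sid, mechanism, gene, region, vids, category) {
    truth[[length(truth) + 1]] <<- tibble(
      sample_id = sid, mechanism = mechanism,
      gene = gene %||% NA_character_, region = region %||% NA_character_,
      variant_ids = paste(vids, collapse = ","),
      expected_category = category
    )
  }
  add_evidence <- function(sid, gene, tag) {
    evidence[[length(evidence) + 1]] <<- tibble(sample_id = sid,
                                                gene = gene, tag = tag)
  }

  # -- mechanism target loci ----------------------------------------------
  pick_known <- function(chr, n) {
    g <- genes %>% filter(.data$is_known, .data$chrom == chr)
    g$gene[seq_len(n)]
  }
  founder_gene <- pick_known("chr1", 1)
  comphet_genes <- pick_known("chr2", 5)
  depletion_genes <- pick_known("chr3", 2)
  x_genes <- pick_known("chrX", 2)
  dnd_genes <- genes %>%
    filter(!.data$is_mito, .data$chrom == "chr4") %>%
    slice(1:2) %>% pull("gene")

  # cnv_plus_snv target: a known chr5 gene; the deletion is placed over it.
  cnv_snv_gene <- pick_known("chr5", 1)
  g5 <- genes[genes$gene == cnv_snv_gene, ]
  cnv_snv_region <- tibble(
    chrom = "chr5",
    start = as.integer(g5$start - 5e5),
    end = as.integer(g5$start - 5e5 + cfg$cnv_snv_del_kb * 1000 - 1)
  )
  cnv_del_region <- tibble(
    chrom = "chr6", start = 10000001L,
    end = as.integer(10000000 + cfg$cnv_del_kb * 1000)
  )
  disorder_regions <- tibble(
    chrom = "chr6", start = cnv_del_region$start - 200000L,
    end = cnv_del_region$end + 200000L,
    name = "congenital heart defects, nonsyndromic"
  )
  common_dup_region <- tibble(chrom = "chr2", start = 20000001L,
                              end = 20300000L)
  control_cnvs <- common_dup_region %>% mutate(name = "common_dup")

  # -- planted mechanisms --------------------------------------------------
  founder_vid <- NULL
  mt_plants <- list()
  depletion_ids <- character()
  mtdel_ids <- character()
  cnv_del_ids <- character()
  cnv_snv_ids <- character()
  lcsh_windows <- list()
  comphet_idx <- 0L
  xhemi_idx <- 0L
  dnd_idx <- 0L
  depl_idx <- 0L
  catalog <- synthetic_mt_catalog()
  confirmed <- catalog %>% filter(.data$status == "confirmed")

  for (ci in seq_len(cfg$n_cases)) {
    sid <- case_ids[ci]
    fa <- paste0(sid, "_fa")
    mo <- paste0(sid, "_mo")
    mech <- mech_of[ci]

    if (mech == "recessive_hom_founder_lcsh") {
      if (is.null(founder_vid)) {
        founder_vid <- add_variant(planted_variant_row(
          genes, founder_gene, 1000L, "A", "G", "missense",
          sift = 0.02, gerp = 4.5,
          maf = list(hgvd = 0.003, `1kjpn` = 0.003)
        ))
      }
      add_gt(founder_vid, sid, "hom_alt")
      add_gt(founder_vid, fa, "het")
      add_gt(founder_vid, mo, "het")
      g <- genes[genes$gene == founder_gene, ]
      half <- cfg$lcsh_founder_mb * 1e6 / 2
      lcsh_windows[[length(lcsh_windows) + 1]] <- tibble(
        sample_id = sid, chrom = g$chrom,
        start = as.integer(max(1, (g$start + g$end) / 2 - half)),
        end = as.integer((g$start + g$end) / 2 + half)
      )
      add_truth(sid, mech, founder_gene, NULL, founder_vid,
                "known_nuclear_gene")
    } else if (mech == "compound_het") {
      comphet_idx <- comphet_idx + 1L
      gene <- comphet_genes[comphet_idx]
      v1 <- add_variant(planted_variant_row(
        genes, gene, 500L, "C", "T", "missense", sift = 0.03, gerp = 4.0))
      v2 <- add_variant(planted_variant_row(
        genes, gene, 5000L, "G", "A", "frameshift_indel",
        sift = NA_real_, gerp = 5.0))
      add_gt(v1, sid, "het"); add_gt(v2, sid, "het")
      add_gt(v1, fa, "het"); add_gt(v2, mo, "het")
      if (comphet_idx == 1L) {
        # An affected sibling sharing the configuration makes segregation
        # informative for this family.
        sib <- paste0(sid, "_sib")
        extra_ped[[length(extra_ped) + 1]] <- tibble(
          family_id = ped_cases$family_id[ci], sample_id = sib,
          father_id = fa, mother_id = mo, sex = "female", affected = TRUE)
        add_gt(v1, sib, "het"); add_gt(v2, sib, "het")
      } else {
        add_evidence(sid, gene, "rescue")
      }
      add_truth(sid, mech, gene, NULL, c(v1, v2), "known_nuclear_gene")
    } else if (mech == "de_novo_dominant") {
      dnd_idx <- dnd_idx + 1L
      gene <- dnd_genes[dnd_idx]
      v <- add_variant(planted_variant_row(
        genes, gene, 700L, "G", "A", "missense", sift = 0.01, gerp = 5.2))
      add_gt(v, sid, "het")  # absent from both parents: de novo
      add_truth(sid, mech, gene, NULL, v, "other_monogenic_gene")
    } else if (mech == "x_hemizygous") {
      xhemi_idx <- xhemi_idx + 1L
      gene <- x_genes[xhemi_idx]
      v <- add_variant(planted_variant_row(
        genes, gene, 900L, "G", "A",
        if (xhemi_idx == 1L) "missense" else "nonsense",
        sift = if (xhemi_idx == 1L) 0.01 else NA_real_, gerp = 4.8))
      add_gt(v, sid, "hemi_alt")
      if (xhemi_idx == 2L) {
        add_gt(v, mo, "het")  # carrier mother; NDP evidence supports it
        add_evidence(sid, gene, "no_detectable_protein")
      }
      add_truth(sid, mech, gene, NULL, v, "known_nuclear_gene")
    } else if (mech == "mtdna_point") {
      k <- sample(nrow(confirmed), 1)
      h <- runif(1, cfg$heteroplasmy_range[1], cfg$heteroplasmy_range[2])
      depth <- 1000L
      alt_n <- rbinom(1, depth, h)
      mt_plants[[length(mt_plants) + 1]] <- tibble(
        sample_id = sid, pos = confirmed$pos[k], ref = confirmed$ref[k],
        alt = confirmed$alt[k], ref_count = depth - alt_n, alt_count = alt_n)
      add_truth(sid, mech, NULL,
                sprintf("m.%d%s>%s", confirmed$pos[k], confirmed$ref[k],
                        confirmed$alt[k]),
                character(), "mtdna_mutation")
    } else if (mech == "mtdna_deletion") {
      mtdel_ids <- c(mtdel_ids, sid)
      add_truth(sid, mech, NULL,
                sprintf("m.%d_%ddel", cfg$mt_del_breakpoints[1],
                        cfg$mt_del_breakpoints[2]),
                character(), "mtdna_mutation")
    } else if (mech == "mtdna_depletion") {
      depl_idx <- depl_idx + 1L
      depletion_ids <- c(depletion_ids, sid)
      gene <- depletion_genes[depl_idx]
      v <- add_variant(planted_variant_row(
        genes, gene, 1200L, "C", "T", "splice_site",
        sift = NA_real_, gerp = 5.5))
      add_gt(v, sid, "hom_alt")
      add_gt(v, fa, "het"); add_gt(v, mo, "het")
      add_truth(sid, mech, gene, NULL, v, "known_nuclear_gene")
    } else if (mech == "cnv_deletion") {
      cnv_del_ids <- c(cnv_del_ids, sid)
      add_truth(sid, mech, NULL,
                sprintf("%s:%d-%d del", cnv_del_region$chrom,
                        cnv_del_region$start, cnv_del_region$end),
                character(), "chromosomal_aberration")
    } else if (mech == "cnv_plus_snv") {
      cnv_snv_ids <- c(cnv_snv_ids, sid)
      v <- add_variant(planted_variant_row(
        genes, cnv_snv_gene, 1500L, "G", "A", "missense",
        sift = 0.05, gerp = 3.8))
      add_gt(v, sid, "het")
      add_gt(v, mo, "het")
      add_evidence(sid, cnv_snv_gene, "rescue")
      add_truth(sid, mech, cnv_snv_gene,
                sprintf("%s:%d-%d del", cnv_snv_region$chrom,
                        cnv_snv_region$start, cnv_snv_region$end),
                v, "known_nuclear_gene")
    } else {
      add_truth(sid, "none", NULL, NULL, character(), NA_character_)
    }
  }

  # A het carrier of the founder allele among the background cases mirrors
  # the observed founder pattern (carriers plus homozygotes).
  none_cases <- case_ids[mech_of == "none"]
  if (length(none_cases) > 0 && !is.null(founder_vid)) {
    carrier <- none_cases[1]
    add_gt(founder_vid, carrier, "het")
    add_gt(founder_vid, paste0(carrier, "_mo"), "het")
  }

  # A cohort-recurrent artifact-like variant: rare in panels yet carried by
  # 12 cases, removed by the case-recurrence filter.
  recur_gene <- genes$gene[genes$chrom == "chr3"][50]
  recur_vid <- add_variant(planted_variant_row(
    genes, recur_gene, 800L, "T", "C", "missense", sift = 0.05, gerp = 3.5))
  for (sid in case_ids[seq_len(min(12L, cfg$n_cases))]) {
    add_gt(recur_vid, sid, "het")
    add_gt(recur_vid, paste0(sid, "_fa"), "het")
  }

  # -- background variants -------------------------------------------------
  flavours <- c("common", "tolerated", "low_gerp", "segdup", "synonymous",
                "artifact")
  flavour_probs <- c(0.45, 0.15, 0.15, 0.10, 0.10, 0.05)
  for (sid in c(case_ids, control_ids)) {
    is_case <- sid %in% case_ids
    n_surv <- rpois(1, cfg$background_rate)
    n_filt <- rpois(1, cfg$filtered_rate)
    fl <- c(rep("surviving", n_surv),
            sample(flavours, n_filt, replace = TRUE, prob = flavour_probs))
    sex_i <- if (is_case) {
      ped_cases$sex[match(sid, ped_cases$sample_id)]
    } else {
      ped_controls$sex[match(sid, ped_controls$sample_id)]
    }
    for (f in fl) {
      row <- background_variant_row(genes, cfg, f)
      vid <- add_variant(row)
      on_male_x <- row$chrom == "chrX" && sex_i == "male"
      add_gt(vid, sid, if (on_male_x) "hemi_alt" else "het")
      if (is_case) {
        # Background variation is inherited, never spuriously de novo: a
        # random parent carries the allele (the mother for male X).
        parent <- if (on_male_x) paste0(sid, "_mo") else {
          paste0(sid, sample(c("_fa", "_mo"), 1))
        }
        add_gt(vid, parent, "het")
      }
    }
  }

  variants <- bind_rows(variants) %>%
    distinct(.data$variant_id, .keep_all = TRUE)
  genotypes <- bind_rows(gts) %>%
    distinct(.data$variant_id, .data$sample_id, .keep_all = TRUE)

  pedigree <- bind_rows(ped_cases, bind_rows(extra_ped), ped_parents,
                        ped_controls)

  # -- array probes (cases only) ------------------------------------------
  nuclear <- cfg$genome[names(cfg$genome) != "MT"]
  grid <- purrr::imap(nuclear, function(len, chr) {
    tibble(chrom = chr, pos = seq.int(cfg$probe_spacing, len,
                                      by = cfg$probe_spacing))
  }) %>% bind_rows()
  n_grid <- nrow(grid)

  # Founder patients share one haplotype pattern across the LCSH window.
  founder_window <- if (length(lcsh_windows) > 0) lcsh_windows[[1]] else NULL
  founder_hap <- NULL
  if (!is.null(founder_window)) {
    in_win <- grid$chrom == founder_window$chrom &
      grid$pos >= founder_window$start & grid$pos <= founder_window$end
    founder_hap <- sample(c("AA", "BB"), sum(in_win), replace = TRUE)
  }

  probes <- purrr::map(case_ids, function(sid) {
    genotype <- sample(c("AA", "AB", "BB", "no-call"), n_grid,
                       replace = TRUE, prob = c(0.345, 0.30, 0.345, 0.01))
    log2_ratio <- rnorm(n_grid, 0, cfg$log2_sd)
    mech <- mech_of[match(sid, case_ids)]
    if (mech == "recessive_hom_founder_lcsh") {
      in_win <- grid$chrom == founder_window$chrom &
        grid$pos >= founder_window$start & grid$pos <= founder_window$end
      genotype[in_win] <- founder_hap
    }
    apply_deletion <- function(region, log2_mean) {
      idx <- grid$chrom == region$chrom &
        grid$pos >= region$start & grid$pos <= region$end
      log2_ratio[idx] <<- rnorm(sum(idx), log2_mean, cfg$log2_sd)
      genotype[idx] <<- sample(c("AA", "BB"), sum(idx), replace = TRUE)
    }
    if (sid %in% cnv_del_ids) apply_deletion(cnv_del_region, -1.0)
    if (sid %in% cnv_snv_ids) apply_deletion(cnv_snv_region, -1.0)
    if (match(sid, case_ids) <= 6L) {
      idx <- grid$chrom == common_dup_region$chrom &
        grid$pos >= common_dup_region$start &
        grid$pos <= common_dup_region$end
      log2_ratio[idx] <- rnorm(sum(idx), 0.45, cfg$log2_sd)
    }
    tibble(sample_id = sid, chrom = grid$chrom, pos = grid$pos,
           genotype = genotype, log2_ratio = log2_ratio)
  }) %>% bind_rows()

  # -- mtDNA tables --------------------------------------------------------
  mt_background <- purrr::map(case_ids, function(sid) {
    n <- rpois(1, 2)
    if (n == 0) return(NULL)
    pos <- sample(setdiff(seq_len(MT_GENOME_LENGTH), catalog$pos), n)
    al <- rand_alleles(n)
    depth <- 1000L
    h <- runif(n, 0.9, 1)
    alt_n <- rbinom(n, depth, h)
    tibble(sample_id = sid, pos = as.integer(pos), ref = al$ref, alt = al$alt,
           ref_count = depth - alt_n, alt_count = alt_n)
  })
  mt_variants <- bind_rows(c(mt_plants, mt_background)) %>%
    arrange(.data$sample_id, .data$pos)

  mt_coverage <- purrr::map(case_ids, function(sid) {
    if (sid %in% mtdel_ids) {
      prof <- plant_mtdna_deletion(
        cfg$mt_del_breakpoints[1], cfg$mt_del_breakpoints[2],
        depth_in = cfg$mt_depth,
        depth_out = cfg$mt_depth * (1 - cfg$mt_del_heteroplasmy))
    } else {
      prof <- tibble(pos = seq_len(MT_GENOME_LENGTH),
                     depth = rpois(MT_GENOME_LENGTH, cfg$mt_depth))
    }
    mutate(prof, sample_id = sid)
  }) %>% bind_rows() %>% select("sample_id", "pos", "depth")

  qpcr <- purrr::map(case_ids, function(sid) {
    m <- if (sid %in% depletion_ids) cfg$depletion_ratio_mean else 1.0
    s <- if (sid %in% depletion_ids) cfg$depletion_ratio_sd else 0.08
    tibble(sample_id = sid, tissue = "tissue",
           replicate = seq_len(cfg$qpcr_replicates),
           ratio = pmax(0.01, rnorm(cfg$qpcr_replicates, m, s)),
           control_mean = 1.0)
  }) %>% bind_rows()

  enzymes <- purrr::map(case_ids, function(sid) {
    tibble(sample_id = sid,
           tissue = c("tissue", "fibroblast"),
           complex = c("I", "I"),
           percent_control = c(runif(1, 5, 60), runif(1, 10, 60)))
  }) %>% bind_rows()

  segdup_regions <- variants %>%
    filter(.data$segdup) %>%
    mutate(start = .data$pos - 100L, end = .data$pos + 100L,
           name = "segdup") %>%
    select("chrom", "start", "end", "name")

  structure(list(
    config = cfg,
    genome = cfg$genome,
    genes = genes,
    gene_sets = list(
      known = genes$gene[genes$is_known],
      mito = genes$gene[genes$is_mito],
      all = genes$gene
    ),
    variants = variants,
    genotypes = genotypes,
    pedigree = pedigree,
    cases = case_ids,
    controls = control_ids,
    probes = probes,
    mt_catalog = catalog,
    mt_variants = mt_variants,
    mt_coverage = mt_coverage,
    qpcr = qpcr,
    enzymes = enzymes,
    evidence = bind_rows(evidence),
    control_cnvs = control_cnvs,
    disorder_regions = disorder_regions,
    segdup_regions = segdup_regions,
    truth = bind_rows(truth)
  ), class = "mitodx_cohort")
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits the multi-sample VCF, tab-delimited annotation table, PED
#' pedigree, probe/mtDNA/qPCR tables, BED region files, gene lists, and the
#' truth table (TSV and JSON) into a directory, using exactly the formats
#' the package readers consume.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  paths <- c(
    vcf = p("cohort.vcf"), annotation = p("annotation.tsv"),
    ped = p("pedigree.ped"), probes = p("probes.tsv"),
    mt_variants = p("mt_variants.tsv"), mt_coverage = p("mt_coverage.tsv"),
    mt_catalog = p("mt_catalog.tsv"), qpcr = p("qpcr.tsv"),
    enzymes = p("enzymes.tsv"), evidence = p("evidence.tsv"),
    control_cnvs = p("control_cnvs.bed"),
    disorder_regions = p("disorder_regions.bed"),
    segdup = p("segdup.bed"), genes_known = p("genes_known.txt"),
    genes_mito = p("genes_mito.txt"), gene_catalog = p("gene_catalog.tsv"),
    truth = p("truth.tsv"), truth_json = p("truth.json")
  )
  write_cohort_vcf(cohort$variants, cohort$genotypes, paths["vcf"],
                   contigs = cohort$genome)
  ann <- cohort$variants %>% select(-"variant_id")
  readr::write_tsv(ann, paths["annotation"], progress = FALSE)
  write_pedigree(cohort$pedigree, paths["ped"])
  readr::write_tsv(cohort$probes, paths["probes"], progress = FALSE)
  readr::write_tsv(cohort$mt_variants, paths["mt_variants"], progress = FALSE)
  readr::write_tsv(cohort$mt_coverage, paths["mt_coverage"], progress = FALSE)
  readr::write_tsv(cohort$mt_catalog, paths["mt_catalog"], progress = FALSE)
  readr::write_tsv(cohort$qpcr, paths["qpcr"], progress = FALSE)
  readr::write_tsv(cohort$enzymes, paths["enzymes"], progress = FALSE)
  readr::write_tsv(cohort$evidence, paths["evidence"], progress = FALSE)
  write_bed_regions(cohort$control_cnvs, paths["control_cnvs"])
  write_bed_regions(cohort$disorder_regions, paths["disorder_regions"])
  write_bed_regions(cohort$segdup_regions, paths["segdup"])
  writeLines(cohort$gene_sets$known, paths["genes_known"])
  writeLines(cohort$gene_sets$mito, paths["genes_mito"])
  readr::write_tsv(cohort$genes, paths["gene_catalog"], progress = FALSE)
  readr::write_tsv(cohort$truth, paths["truth"], progress = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth_json"], dataframe = "rows")
  invisible(paths)
}
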
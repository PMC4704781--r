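# Genotype-configuration reasoning: recessive-model consistency,
# compound-heterozygote phasing from trio genotypes, de novo detection and
# family segregation.

x_chroms <- c("X", "chrX")
is_x_chrom <- function(chrom) chrom %in% x_chroms

# Heterozygous calls on the male X are coerced to hemizygous (array/VCF
# dialect tolerance); a warning is emitted once per call site.
coerce_male_x <- function(gt, chrom, sex) {
  needs <- gt == "het" & is_x_chrom(chrom) & sex == "male"
  if (any(needs)) {
    warn(sprintf("%d heterozygous male X call(s) coerced to hemizygous",
                 sum(needs)))
    gt[needs] <- "hemi_alt"
  }
  gt
}

#' Recessive-model consistency for one gene's prioritized variants
#'
#' Classifies the genotype configuration of a patient's prioritized variants
#' in a single gene: one homozygous variant supports a homozygous recessive
#' model; two or more heterozygous variants form a compound-heterozygote
#' candidate (phase still to be established); a single variant on the male X
#' is hemizygous; a single inherited autosomal heterozygote is inconsistent
#' with recessive inheritance and rejected (a confirmed de novo event
#' bypasses this rejection, see [detect_de_novo()]).
#'
#' @param gene_variants Tibble of the patient's prioritized variants in one
#'   gene with columns `variant_id`, `chrom`, `gt`.
#' @param sex `"male"` or `"female"`.
#' @param de_novo Optional logical vector (per variant) of confirmed de novo
#'   status; a single de novo heterozygote is returned as
#'   `de_novo_dominant` instead of rejected.
#' @return One of `"hom_recessive"`, `"compound_het"`, `"x_hemizygous"`,
#'   `"de_novo_dominant"`, `"reject"`.
#' @export
check_recessive_consistency <- function(gene_variants, sex,
                                        de_novo = NULL) {
  gt <- coerce_male_x(gene_variants$gt, gene_variants$chrom, sex)
  if (any(gt == "hom_alt")) return("hom_recessive")
  on_x <- is_x_chrom(gene_variants$chrom)
  if (sex == "male" && any(gt == "hemi_alt" & on_x)) return("x_hemizygous")
  het <- gt == "het"
  if (sum(het) >= 2) return("compound_het")
  if (!is.null(de_novo) && any(de_novo & carries_alt(gt))) {
    return("de_novo_dominant")
  }
  "reject"
}

#' Phase a candidate compound-heterozygote pair from trio genotypes
#'
#' For two heterozygous variants in one gene: the pair is in trans when each
#' parent carries exactly one of the two (so the child must have received
#' them on different haplotypes), in cis when one parent carries both and
#' the other neither (the child received both on one transmitted
#' haplotype), and unknown otherwise. Molecular phase groups (from cloned
#' gDNA/cDNA sequencing) override genotype reasoning when supplied: same
#' group is cis, different groups trans. Pairs in cis are excluded from
#' compound-heterozygote calls downstream. Homozygous parents pin their
#' transmitted allele, so configurations like a father homozygous for
#' variant 1 with only the mother carrying variant 2 also phase in trans;
#' the call is exactly the consensus of all parental haplotype assignments
#' consistent with the trio genotypes.
#'
#' Mendelian violations (a child allele absent from both parents without a
#' de novo flag) are flagged in the result, never silently phased.
#'
#' @param father_gt,mother_gt Length-2 genotype vectors (variant 1, variant
#'   2) in the hom_ref/het/hom_alt vocabulary; `NULL` when the parent is not
#'   genotyped.
#' @param phase_groups Optional length-2 vector of haplotype labels for the
#'   child's two variants.
#' @param de_novo Optional length-2 logical of confirmed de novo status.
#' @return List with `phase` (`"in_trans"`, `"in_cis"` or `"unknown"`) and
#'   `mendelian_ok` (logical).
#' @export
phase_compound_het <- function(father_gt = NULL, mother_gt = NULL,
                               phase_groups = NULL, de_novo = c(FALSE, FALSE)) {
  if (!is.null(phase_groups) && length(phase_groups) == 2 &&
      !any(is.na(phase_groups))) {
    phase <- if (phase_groups[1] == phase_groups[2]) "in_cis" else "in_trans"
    return(list(phase = phase, mendelian_ok = TRUE))
  }
  if (is.null(father_gt) || is.null(mother_gt)) {
    return(list(phase = "unknown", mendelian_ok = TRUE))
  }
  if (any(de_novo)) {
    # A de novo site has no parental origin; genotypes cannot phase it.
    return(list(phase = "unknown", mendelian_ok = TRUE))
  }
  # Per site, the alleles each parent can transmit; with the child het at
  # both sites, the paternal haplotype allele a is feasible iff the mother
  # can supply the complementary 1 - a. A parent homozygous at a site
  # forces its transmission, which is what pins the phase.
  transmittable <- function(gt) {
    switch(gt, hom_ref = 0L, het = c(0L, 1L), hom_alt = 1L, hemi_alt = 1L,
           missing = c(0L, 1L), c(0L, 1L))
  }
  feasible <- purrr::map(1:2, function(s) {
    af <- transmittable(father_gt[s])
    am <- transmittable(mother_gt[s])
    af[(1L - af) %in% am]
  })
  if (any(lengths(feasible) == 0)) {
    # Child allele configuration impossible from these parents and not
    # flagged de novo: report, never silently phase.
    return(list(phase = "unknown", mendelian_ok = FALSE))
  }
  outcomes <- unique(unlist(purrr::map(feasible[[1]], function(a1) {
    purrr::map_chr(feasible[[2]], function(a2) {
      if (a1 == a2) "in_cis" else "in_trans"
    })
  })))
  phase <- if (length(outcomes) == 1) outcomes else "unknown"
  list(phase = phase, mendelian_ok = TRUE)
}

#' Confirmed de novo status of a child variant from trio genotypes
#'
#' True only when the child carries the alternate allele and both parents
#' are genotyped homozygous reference (a hemizygous male X variant needs
#' only the mother to be homozygous reference for the transmitted X, but
#' both parents must still lack the allele). A missing parent genotype makes
#' the variant untestable, returning `FALSE` with the reason.
#'
#' @param child_gt,father_gt,mother_gt Genotype calls for one variant.
#' @param chrom Chromosome of the variant.
#' @param sex Child sex.
#' @return List with `de_novo` (logical) and `reason`.
#' @export
detect_de_novo <- function(child_gt, father_gt, mother_gt,
                           chrom = "chr1", sex = "female") {
  if (is.null(father_gt) || is.null(mother_gt) ||
      is.na(father_gt) || is.na(mother_gt) ||
      father_gt == "missing" || mother_gt == "missing") {
    return(list(de_novo = FALSE, reason = "parent genotype missing"))
  }
  if (!carries_alt(child_gt)) {
    return(list(de_novo = FALSE, reason = "child does not carry the allele"))
  }
  parents_clear <- if (sex == "male" && is_x_chrom(chrom)) {
    # The X came from the mother; the father's X is untransmitted but a
    # paternal carrier would still argue against a true de novo event.
    mother_gt == "hom_ref" && !carries_alt(father_gt)
  } else {
    father_gt == "hom_ref" && mother_gt == "hom_ref"
  }
  if (parents_clear) {
    list(de_novo = TRUE, reason = "absent from both parents")
  } else {
    list(de_novo = FALSE, reason = "allele present in a parent")
  }
}

# Does a sample's genotype set realise a qualifying configuration for a
# gene-level call? Used by segregation checks.
has_configuration <- function(model, gts, chrom, sex) {
  gts <- coerce_male_x(gts, chrom, sex)
  switch(model,
    hom_recessive = any(gts == "hom_alt"),
    x_hemizygous = any(gts %in% c("hemi_alt", "hom_alt")),
    compound_het = sum(carries_alt(gts)) >= 2,
    de_novo_dominant = any(carries_alt(gts)),
    FALSE
  )
}

#' Family segregation of a gene-level inheritance call
#'
#' Consistent when every genotyped affected relative carries the same
#' qualifying configuration and no genotyped unaffected relative does;
#' inconsistent when either condition fails; untested when no non-proband
#' relative is genotyped.
#'
#' For a recessive model an unaffected het carrier parent does not carry
#' the configuration, so trio parents alone are vacuously consistent; the
#' diagnostic pipeline therefore only converts segregation into supporting
#' evidence when at least one affected non-proband relative is informative.
#'
#' @param model Inheritance model of the call (e.g. `"hom_recessive"`).
#' @param relatives Tibble of non-proband relatives with columns
#'   `sample_id`, `affected`, `sex`, and per-variant genotypes in a list
#'   column `gts` (character vectors over the call's variants) plus `chrom`
#'   list column aligned with `gts`.
#' @return List with `segregation` (`"consistent"`, `"inconsistent"` or
#'   `"untested"`) and `informative` (did any affected relative share the
#'   configuration?).
#' @export
check_segregation <- function(model, relatives) {
  if (is.null(relatives) || nrow(relatives) == 0) {
    return(list(segregation = "untested", informative = FALSE))
  }
  has <- purrr::pmap_lgl(relatives, function(sample_id, affected, sex, gts,
                                             chrom, ...) {
    has_configuration(model, gts, chrom, sex)
  })
  consistent <- all(has[relatives$affected]) && !any(has[!relatives$affected])
  list(
    segregation = if (consistent) "consistent" else "inconsistent",
    informative = any(has & relatives$affected)
  )
}

#' Gene-level inheritance calls for one patient
#'
#' Runs the recessive-consistency, de novo and phasing logic over a
#' patient's prioritized variants, gene by gene, using trio genotypes from
#' the pedigree when available.
#'
#' @param prioritized Tibble of the patient's prioritized variants
#'   (`variant_id`, `gene`, `chrom`, `gt`).
#' @param sample_id Patient id.
#' @param genotypes Cohort-wide long genotype tibble (for parents and
#'   relatives).
#' @param pedigree Pedigree tibble ([read_pedigree()] layout).
#' @param phase_groups Optional tibble (`sample_id`, `variant_id`,
#'   `phase_group`) of molecular phase labels.
#' @return Tibble with one row per gene: `gene`, `model`, `phase`,
#'   `segregation`, `seg_informative`, `de_novo`, `mendelian_flag` and a
#'   `variant_ids` list column. Rejected configurations are dropped.
#' @export
call_inheritance <- function(prioritized, sample_id, genotypes, pedigree,
                             phase_groups = NULL) {
  if (nrow(prioritized) == 0) {
    return(tibble(gene = character(), model = character(),
                  phase = character(), segregation = character(),
                  seg_informative = logical(), de_novo = logical(),
                  mendelian_flag = logical(),
                  variant_ids = list()))
  }
  me <- pedigree[pedigree$sample_id == sample_id, ]
  sex <- if (nrow(me) == 1) me$sex else "female"
  father <- if (nrow(me) == 1) me$father_id else NA_character_
  mother <- if (nrow(me) == 1) me$mother_id else NA_character_

  parent_gt <- function(parent, vid) {
    if (is.na(parent)) return(NULL)
    g <- genotypes$gt[genotypes$sample_id == parent &
                        genotypes$variant_id == vid]
    if (length(g) == 0) "hom_ref" else g[1]
  }

  siblings <- pedigree %>%
    filter(.data$sample_id != !!sample_id,
           !is.na(.data$father_id), !is.na(.data$mother_id),
           .data$father_id == father, .data$mother_id == mother)

  genes <- unique(prioritized$gene)
  rows <- purrr::map(genes, function(g) {
    gv <- prioritized %>% filter(.data$gene == g)
    dn <- purrr::map(gv$variant_id, function(vid) {
      detect_de_novo(gv$gt[gv$variant_id == vid][1],
                     parent_gt(father, vid), parent_gt(mother, vid),
                     chrom = gv$chrom[gv$variant_id == vid][1], sex = sex)
    })
    dn_flags <- purrr::map_lgl(dn, "de_novo")
    model <- check_recessive_consistency(gv, sex, de_novo = dn_flags)
    if (model == "reject") return(NULL)

    phase <- "unknown"
    mendelian_flag <- FALSE
    variant_ids <- gv$variant_id
    if (model == "compound_het") {
      hets <- gv %>% filter(.data$gt == "het")
      pairs <- utils::combn(hets$variant_id, 2, simplify = FALSE)
      results <- purrr::map(pairs, function(pr) {
        pg <- NULL
        if (!is.null(phase_groups)) {
          pg <- purrr::map_chr(pr, function(vid) {
            lbl <- phase_groups$phase_group[
              phase_groups$sample_id == sample_id &
                phase_groups$variant_id == vid]
            if (length(lbl) == 0) NA_character_ else lbl[1]
          })
        }
        fgt <- purrr::map_chr(pr, function(vid) {
          g <- parent_gt(father, vid)
          if (is.null(g)) NA_character_ else g
        })
        mgt <- purrr::map_chr(pr, function(vid) {
          g <- parent_gt(mother, vid)
          if (is.null(g)) NA_character_ else g
        })
        dn2 <- dn_flags[match(pr, gv$variant_id)]
        phase_compound_het(
          father_gt = if (any(is.na(fgt))) NULL else fgt,
          mother_gt = if (any(is.na(mgt))) NULL else mgt,
          phase_groups = pg, de_novo = dn2
        )
      })
      phases <- purrr::map_chr(results, "phase")
      mendelian_flag <- any(!purrr::map_lgl(results, "mendelian_ok"))
      if (any(phases == "in_trans")) {
        phase <- "in_trans"
        variant_ids <- unique(unlist(pairs[phases == "in_trans"]))
      } else if (all(phases == "in_cis")) {
        return(NULL)  # single-haplotype pair(s): excluded
      } else {
        phase <- "unknown"
        variant_ids <- unique(unlist(pairs[phases != "in_cis"]))
      }
    }

    relatives <- NULL
    if (nrow(siblings) > 0) {
      relatives <- purrr::pmap(siblings, function(sample_id, sex, affected, ...) {
        sid <- sample_id
        gts <- purrr::map_chr(variant_ids, function(vid) {
          g <- genotypes$gt[genotypes$sample_id == sid &
                              genotypes$variant_id == vid]
          if (length(g) == 0) "hom_ref" else g[1]
        })
        tibble(sample_id = sid, affected = affected, sex = sex,
               gts = list(gts),
               chrom = list(gv$chrom[match(variant_ids, gv$variant_id)]))
      }) %>% bind_rows()
    }
    seg <- check_segregation(model, relatives)

    tibble(
      gene = g, model = model,
      phase = if (model == "compound_het") phase else "unknown",
      segregation = seg$segregation,
      seg_informative = seg$informative,
      de_novo = any(dn_flags),
      mendelian_flag = mendelian_flag,
      variant_ids = list(variant_ids)
    )
  })
  bind_rows(purrr::compact(rows))
}
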
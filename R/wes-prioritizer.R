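# Whole-exome rare-variant filter cascade with per-variant audit trace and
# the mitochondria-gene recovery pass.
#
# Every filter is an independent predicate on an annotated variant (plus, for
# case recurrence, the cohort genotypes), so the final status of a variant is
# a pure conjunction and does not depend on evaluation order; only the audit
# trace reflects the configured order.

#' Filter cascade configuration
#'
#' Defaults follow the published cascade: remove variants with MAF > 1.0% in
#' dbSNP137 (unless the dbSNP entry has known medical impact), > 0.1% in
#' ESP6500, > 1.0% in 1KG, > 0.1% in ExAC, > 0.4% in HGVD; remove variants
#' with >= 10 alleles among cases; remove variants in segmental duplications;
#' remove variants with SIFT > 0.15 (tolerated) or GERP < 2.5 (unconserved),
#' with missing scores never removing (truncating variants have no SIFT
#' score); keep only protein-modifying classes. The 1KJPN step (Japanese
#' whole-genome reference panel) is a configurable MAF threshold, default
#' 0.4% mirroring HGVD, plus an optional homozygote-presence veto; the source
#' workflow filtered on 1KJPN "MAF and genotype information" without stating
#' a number.
#'
#' @param maf_max Named numeric vector of per-panel maximum MAFs; removal
#'   uses a strict `>` comparison, so a variant exactly at the threshold is
#'   kept.
#' @param case_allele_max Maximum tolerated alternate-allele count among
#'   affected cases; 9 means "exclude at >= 10 alleles". Het counts 1,
#'   hom 2, hemizygous 1.
#' @param sift_max Remove when SIFT strictly exceeds this (tolerated).
#' @param gerp_min Remove when GERP is strictly below this (unconserved).
#' @param functional_classes Classes kept by the protein-impact filter.
#' @param kjpn_hom_veto If `TRUE`, a variant observed homozygous in 1KJPN
#'   (annotation column `kjpn_hom`) is removed by the 1KJPN step.
#' @param filter_order Evaluation order used for the audit trace.
#' @param simplified If `TRUE`, run the simplified pipeline used for the
#'   enrichment evaluation: drop the manual-inspection (artifact), 1KJPN and
#'   HGVD steps.
#' @return A `mitodx_filter_config` list.
#' @export
filter_config <- function(maf_max = c(dbsnp137 = 0.010, esp6500 = 0.001,
                                      `1kg` = 0.010, exac = 0.001,
                                      hgvd = 0.004, `1kjpn` = 0.004),
                          case_allele_max = 9L,
                          sift_max = 0.15,
                          gerp_min = 2.5,
                          functional_classes = c("nonsense", "splice_site",
                                                 "frameshift_indel",
                                                 "inframe_indel", "missense"),
                          kjpn_hom_veto = TRUE,
                          filter_order = c("functional_class", "artifact",
                                           "population_frequency",
                                           "case_recurrence", "segdup",
                                           "deleteriousness", "kjpn"),
                          simplified = FALSE) {
  stopifnot(all(maf_max >= 0 & maf_max <= 1), case_allele_max >= 0,
            sift_max >= 0, sift_max <= 1)
  if (simplified) {
    filter_order <- setdiff(filter_order, c("artifact", "kjpn"))
    maf_max <- maf_max[setdiff(names(maf_max), c("hgvd", "1kjpn"))]
  }
  structure(
    list(maf_max = maf_max, case_allele_max = as.integer(case_allele_max),
         sift_max = sift_max, gerp_min = gerp_min,
         functional_classes = functional_classes,
         kjpn_hom_veto = kjpn_hom_veto, filter_order = filter_order,
         simplified = simplified),
    class = "mitodx_filter_config"
  )
}

#' Protein-impact class filter
#'
#' Keeps nonsense, splice-site, coding indel (frameshift or in-frame) and
#' missense variants; everything else (class `other`) is removed. An
#' unrecognised class label is an error, never silently kept.
#'
#' @param variants Annotated variant tibble with a `class` column.
#' @param cfg A [filter_config()].
#' @return Input tibble plus `keep` (logical) and `reason` columns.
#' @export
filter_functional_class <- function(variants, cfg = filter_config()) {
  bad <- setdiff(unique(variants$class), functional_classes)
  if (length(bad) > 0) {
    abort(sprintf("unknown functional class label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  mutate(variants,
    keep = .data$class %in% cfg$functional_classes,
    reason = if_else(.data$keep, NA_character_,
                     paste0("class ", .data$class, " not protein-modifying"))
  )
}

# Panel columns and their config keys.
panel_map <- c(maf_dbsnp137 = "dbsnp137", maf_esp6500 = "esp6500",
               maf_1kg = "1kg", maf_exac = "exac", maf_hgvd = "hgvd")

#' Population-frequency filter across public panels
#'
#' Removes a variant when any panel frequency strictly exceeds its
#' threshold; the reason names the first offending panel in the fixed panel
#' order. Missing panel frequencies count as 0 (novel variant). The dbSNP137
#' threshold is waived for entries flagged with known medical impact.
#'
#' @inheritParams filter_functional_class
#' @export
filter_population_frequency <- function(variants, cfg = filter_config()) {
  panels <- panel_map[panel_map %in% names(cfg$maf_max)]
  reason <- rep(NA_character_, nrow(variants))
  for (col in names(panels)) {
    panel <- panels[[col]]
    f <- variants[[col]]
    if (is.null(f)) next
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      abort(sprintf("%s contains frequencies outside [0, 1]", col))
    }
    f[is.na(f)] <- 0
    offender <- f > cfg$maf_max[[panel]]
    if (panel == "dbsnp137" && !is.null(variants$dbsnp_medical_impact)) {
      offender <- offender & !variants$dbsnp_medical_impact
    }
    idx <- which(is.na(reason) & offender)
    reason[idx] <- sprintf("MAF %.4g > %.4g in %s", f[idx],
                           cfg$maf_max[[panel]], panel)
  }
  mutate(variants, keep = is.na(reason), reason = reason)
}

#' Alternate-allele counts among affected cases
#'
#' @param genotypes Long genotype tibble.
#' @param case_ids Sample ids of the affected cases.
#' @return Tibble `variant_id`, `case_alleles`.
#' @export
count_case_alleles <- function(genotypes, case_ids) {
  genotypes %>%
    filter(.data$sample_id %in% case_ids) %>%
    group_by(.data$variant_id) %>%
    summarise(case_alleles = sum(allele_dose[.data$gt]), .groups = "drop")
}

#' Case-recurrence filter
#'
#' Variants too common among the cases themselves (>= 10 alternate alleles
#' by default, counting het 1 / hom 2 / hemizygous 1) are removed as likely
#' platform artifacts or unfiltered polymorphisms.
#'
#' @inheritParams filter_functional_class
#' @param case_alleles Either a `variant_id`/`case_alleles` tibble from
#'   [count_case_alleles()] or `NULL` if `variants` already carries a
#'   `case_alleles` column.
#' @export
filter_case_recurrence <- function(variants, case_alleles = NULL,
                                   cfg = filter_config()) {
  if (!is.null(case_alleles)) {
    variants <- variants %>%
      select(-dplyr::any_of("case_alleles")) %>%
      left_join(case_alleles, by = "variant_id")
  }
  ca <- variants$case_alleles
  ca[is.na(ca)] <- 0
  mutate(variants,
    keep = ca <= cfg$case_allele_max,
    reason = if_else(.data$keep, NA_character_,
                     sprintf("%d alleles among cases (>= %d)", as.integer(ca),
                             cfg$case_allele_max + 1L))
  )
}

#' Flag variants inside segmental-duplication regions
#'
#' @param variants Variant tibble with `chrom`, `pos`.
#' @param segdup_regions 1-based inclusive region tibble (see
#'   [read_bed_regions()]).
#' @return `variants` with the `segdup` column set from the regions.
#' @export
flag_segdup <- function(variants, segdup_regions) {
  mutate(variants,
         segdup = pos_in_regions(.data$chrom, .data$pos, segdup_regions))
}

#' Segmental-duplication filter
#'
#' @inheritParams filter_functional_class
#' @export
filter_segdup <- function(variants, cfg = filter_config()) {
  sd_flag <- variants$segdup %||% rep(FALSE, nrow(variants))
  sd_flag[is.na(sd_flag)] <- FALSE
  mutate(variants,
    keep = !sd_flag,
    reason = if_else(.data$keep, NA_character_, "inside segmental duplication")
  )
}

#' Deleteriousness filter (SIFT / GERP)
#'
#' Removes variants predicted tolerated (SIFT > 0.15) or at unconserved
#' positions (GERP < 2.5). A missing score never removes: truncating
#' variants (nonsense, frameshift) have no SIFT score yet are retained by
#' the cascade.
#'
#' @inheritParams filter_functional_class
#' @export
filter_deleteriousness <- function(variants, cfg = filter_config()) {
  sift <- variants$sift %||% rep(NA_real_, nrow(variants))
  gerp <- variants$gerp %||% rep(NA_real_, nrow(variants))
  sift_bad <- !is.na(sift) & sift > cfg$sift_max
  gerp_bad <- !is.na(gerp) & gerp < cfg$gerp_min
  mutate(variants,
    keep = !(sift_bad | gerp_bad),
    reason = case_when(
      sift_bad ~ sprintf("SIFT %.3g > %.3g (tolerated)", sift, cfg$sift_max),
      gerp_bad ~ sprintf("GERP %.3g < %.3g (unconserved)", gerp, cfg$gerp_min),
      TRUE ~ NA_character_
    )
  )
}

#' Manual-inspection artifact filter
#'
#' Read-level artifact review is human curation upstream of this package; it
#' is represented by the boolean annotation column `artifact_flag`.
#'
#' @inheritParams filter_functional_class
#' @export
filter_artifact <- function(variants, cfg = filter_config()) {
  flag <- variants$artifact_flag %||% rep(FALSE, nrow(variants))
  flag[is.na(flag)] <- FALSE
  mutate(variants,
    keep = !flag,
    reason = if_else(.data$keep, NA_character_, "flagged NGS artifact")
  )
}

#' 1KJPN reference-panel filter
#'
#' Removes variants exceeding the configured 1KJPN MAF threshold or, when
#' the homozygote veto is on, variants observed homozygous in the panel
#' (annotation column `kjpn_hom`).
#'
#' @inheritParams filter_functional_class
#' @export
filter_kjpn <- function(variants, cfg = filter_config()) {
  thr <- unname(cfg$maf_max["1kjpn"])
  f <- variants$maf_1kjpn %||% rep(NA_real_, nrow(variants))
  f[is.na(f)] <- 0
  maf_bad <- if (length(thr) == 1 && !is.na(thr)) f > thr else rep(FALSE, nrow(variants))
  hom <- variants$kjpn_hom %||% rep(FALSE, nrow(variants))
  hom[is.na(hom)] <- FALSE
  hom_bad <- cfg$kjpn_hom_veto & hom
  mutate(variants,
    keep = !(maf_bad | hom_bad),
    reason = case_when(
      maf_bad ~ sprintf("MAF %.4g > %.4g in 1kjpn", f, thr),
      hom_bad ~ "homozygote present in 1KJPN",
      TRUE ~ NA_character_
    )
  )
}

filter_fns <- list(
  functional_class = filter_functional_class,
  artifact = filter_artifact,
  population_frequency = filter_population_frequency,
  case_recurrence = function(variants, cfg) {
    filter_case_recurrence(variants, case_alleles = NULL, cfg = cfg)
  },
  segdup = filter_segdup,
  deleteriousness = filter_deleteriousness,
  kjpn = filter_kjpn
)

# Filters waived by the mitochondria-gene recovery pass.
recovery_waived <- c("segdup", "deleteriousness")

# Evaluate every configured filter independently; returns a tibble with one
# logical pass column and one reason column per filter.
evaluate_filters <- function(variants, cfg) {
  out <- tibble(variant_id = variants$variant_id)
  for (f in cfg$filter_order) {
    res <- filter_fns[[f]](variants, cfg)
    out[[paste0("pass_", f)]] <- res$keep
    out[[paste0("reason_", f)]] <- res$reason
  }
  out
}

# Final status from the per-filter pass matrix.
status_from_passes <- function(passes, mito_gene, cfg) {
  ord <- cfg$filter_order
  pass_cols <- paste0("pass_", ord)
  all_pass <- rowSums(!as.matrix(passes[pass_cols])) == 0
  waivable <- intersect(recovery_waived, ord)
  hard <- setdiff(ord, waivable)
  hard_pass <- rowSums(!as.matrix(passes[paste0("pass_", hard)])) == 0
  case_when(
    all_pass ~ "prioritized_main",
    hard_pass & mito_gene ~ "prioritized_recovery",
    TRUE ~ "removed"
  )
}

#' Mitochondria-gene recovery pass
#'
#' Re-examines removed variants with the segmental-duplication, SIFT and
#' GERP filters waived; variants in mitochondria-related genes that fail
#' only those filters are restored with status `prioritized_recovery`.
#' Frequency, class, artifact, recurrence and 1KJPN failures are never
#' waived.
#'
#' @param trace A filter trace tibble from [prioritize_patient()] (the
#'   `trace` element), or any tibble with `variant_id`, `gene` and the
#'   per-filter `pass_*` columns.
#' @param mito_genes Character vector of mitochondria-related gene symbols.
#' @param cfg The [filter_config()] used for the main pass.
#' @return The trace with `status` recomputed so qualifying variants become
#'   `prioritized_recovery`.
#' @export
recovery_pass <- function(trace, mito_genes, cfg = filter_config()) {
  mutate(trace,
    status = status_from_passes(trace, .data$gene %in% mito_genes, cfg))
}

#' Run the filter cascade for one patient
#'
#' Applies the cascade to the variants the patient carries, records a full
#' per-variant audit trace, and restores mitochondria-gene variants removed
#' only by the waivable filters (recovery pass). The prioritized set is the
#' union of main-pass survivors and recovery restorations and is identical
#' regardless of filter evaluation order.
#'
#' @param sample_id Patient sample id.
#' @param variants Annotated variant tibble (cohort-wide).
#' @param genotypes Long genotype tibble (cohort-wide).
#' @param cfg A [filter_config()].
#' @param mito_genes Mitochondria-related gene symbols (recovery pass
#'   universe); known disease genes should be included.
#' @param case_alleles Optional precomputed [count_case_alleles()] result;
#'   required for the case-recurrence filter unless `variants` already has a
#'   `case_alleles` column.
#' @return List with `prioritized` (annotated variants + `gt` + `status`)
#'   and `trace` (one row per carried variant: per-filter outcomes, failed
#'   filters, final status).
#' @export
prioritize_patient <- function(sample_id, variants, genotypes,
                               cfg = filter_config(),
                               mito_genes = character(),
                               case_alleles = NULL) {
  carried <- genotypes %>%
    filter(.data$sample_id == !!sample_id, carries_alt(.data$gt)) %>%
    select("variant_id", "gt")
  vars <- variants %>% semi_join(carried, by = "variant_id")
  if (nrow(vars) == 0) {
    empty <- tibble(variant_id = character(), gene = character(),
                    status = character(), failed = character())
    return(list(prioritized = vars %>% mutate(gt = character(),
                                              status = character()),
                trace = empty))
  }
  if (!is.null(case_alleles)) {
    vars <- vars %>%
      select(-dplyr::any_of("case_alleles")) %>%
      left_join(case_alleles, by = "variant_id")
  }
  passes <- evaluate_filters(vars, cfg)
  status <- status_from_passes(passes, vars$gene %in% mito_genes, cfg)

  pass_mat <- !as.matrix(passes[paste0("pass_", cfg$filter_order)])
  failed <- apply(pass_mat, 1, function(row) {
    paste(cfg$filter_order[row], collapse = ",")
  })
  trace <- passes %>%
    mutate(sample_id = !!sample_id, gene = vars$gene, status = status,
           failed = failed) %>%
    select("sample_id", "variant_id", "gene", dplyr::starts_with("pass_"),
           dplyr::starts_with("reason_"), "status", "failed")

  prioritized <- vars %>%
    mutate(status = status) %>%
    filter(.data$status != "removed") %>%
    left_join(carried, by = "variant_id")
  list(prioritized = prioritized, trace = trace)
}

#' Run the filter cascade for every case in a cohort
#'
#' @param variants,genotypes Cohort-wide annotated variants and genotypes.
#' @param case_ids Affected sample ids (used for both the case-recurrence
#'   allele count and the set of patients processed).
#' @inheritParams prioritize_patient
#' @return List with `prioritized` (rows per patient x prioritized variant)
#'   and `trace` (all patients' audit traces).
#' @export
prioritize_cohort <- function(variants, genotypes, case_ids,
                              cfg = filter_config(),
                              mito_genes = character()) {
  ca <- count_case_alleles(genotypes, case_ids)
  res <- purrr::map(case_ids, function(s) {
    prioritize_patient(s, variants, genotypes, cfg, mito_genes,
                       case_alleles = ca)
  })
  prioritized <- purrr::map(res, "prioritized") %>%
    purrr::map2(case_ids, ~ mutate(.x, sample_id = .y)) %>%
    bind_rows()
  list(prioritized = prioritized,
       trace = bind_rows(purrr::map(res, "trace")))
}
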
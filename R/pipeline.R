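# End-to-end orchestration: run the three diagnostic arms over a cohort,
# assemble per-patient findings with evidence tags, grade firmness, assign
# diagnostic categories and summarize the cohort.

finding_row <- function(sample_id, source, gene = NA_character_,
                        payload = NA_character_, model = NA_character_,
                        phase = NA_character_, tags = character()) {
  tibble(sample_id = sample_id, source = source, gene = gene,
         payload = payload, model = model, phase = phase,
         tags = list(sort(unique(tags))))
}

nuclear_source <- function(gene, gene_sets) {
  if (gene %in% gene_sets$known) {
    "nuclear_known_gene"
  } else if (gene %in% gene_sets$mito) {
    "nuclear_mito_related"
  } else {
    "nuclear_other_monogenic"
  }
}

#' Run the full diagnostic workflow over a cohort
#'
#' Per case: (i) the exome filter cascade with recovery pass and
#' inheritance-model reasoning; (ii) mtDNA catalog prioritization,
#' large-deletion detection from coverage, and the qPCR depletion rule;
#' (iii) array copy-number segmentation with control filtering and
#' disorder-region annotation, LCSH detection, and composite CNV+SNV
#' promotion. Findings are tagged with molecular evidence -- wet-lab tags
#' from the evidence table plus pipeline-derived tags (confirmed de novo,
#' catalog-confirmed mtDNA events, disorder-region CNVs, LCSH support for
#' homozygous candidates, Hardy-Weinberg founder sharing, informative
#' family segregation, and a positive depletion assay supporting a
#' biallelic nuclear candidate) -- then graded firm or pVUS and collapsed
#' to one diagnostic category per patient.
#'
#' @param cohort A `mitodx_cohort` from [simulate_cohort()] or an
#'   equivalent list of tibbles assembled from files by the readers.
#' @param cfg Filter cascade configuration ([filter_config()]).
#' @param lcsh_min_mb Minimum LCSH span for the homozygosity screen, Mb.
#' @param hwe_alpha Significance level for the founder screen.
#' @return A `mitodx_diagnosis` list: `findings` (one row per finding with
#'   firmness), `classifications` (per patient: category, severity),
#'   `summary` ([summarize_cohort()] result), `prioritized`, `trace`,
#'   `cnv`, `lcsh`, `mt`, `depletion`, `hwe`.
#' @export
diagnose_cohort <- function(cohort, cfg = filter_config(),
                            lcsh_min_mb = 1.0, hwe_alpha = 0.05) {
  gene_sets <- cohort$gene_sets
  cases <- cohort$cases

  wes <- prioritize_cohort(cohort$variants, cohort$genotypes, cases,
                           cfg = cfg, mito_genes = gene_sets$mito)
  prioritized <- wes$prioritized

  # Founder screen over variants prioritized in at least one case.
  hwe <- genotype_counts(
    cohort$genotypes %>%
      semi_join(distinct(prioritized, .data$variant_id), by = "variant_id"),
    cases
  ) %>% hwe_screen(alpha = hwe_alpha)
  founder_vids <- hwe$variant_id[hwe$violated]

  # Depletion calls per case with a complete replicate set.
  depletion <- cohort$qpcr %>%
    group_by(.data$sample_id) %>%
    summarise(
      call = call_depletion(.data$ratio, first(.data$control_mean)),
      .groups = "drop"
    )

  findings <- list()
  cnv_all <- list()
  lcsh_all <- list()
  mt_all <- list()

  for (sid in cases) {
    mine <- prioritized %>% filter(.data$sample_id == sid)
    evid <- cohort$evidence
    tags_for <- function(gene) {
      if (is.null(evid) || nrow(evid) == 0) return(character())
      evid$tag[evid$sample_id == sid & evid$gene == gene]
    }

    # -- array arm --------------------------------------------------------
    probes_i <- cohort$probes %>% filter(.data$sample_id == sid)
    segs <- prioritize_cnv(
      segment_copy_number(probes_i),
      control_cnvs = cohort$control_cnvs,
      disorder_regions = cohort$disorder_regions
    )
    if (nrow(segs) > 0) {
      cnv_all[[length(cnv_all) + 1]] <- mutate(segs, sample_id = sid)
    }
    lcsh <- detect_lcsh(probes_i, min_mb = lcsh_min_mb)
    if (nrow(lcsh) > 0) {
      lcsh_all[[length(lcsh_all) + 1]] <- mutate(lcsh, sample_id = sid)
    }

    composite <- detect_composite_cnv_snv(segs, mine, cohort$genes)
    composite_genes <- unique(composite$gene)

    # -- nuclear arm ------------------------------------------------------
    depleted <- nrow(depletion) > 0 &&
      sid %in% depletion$sample_id[depletion$call == "MTDPS"]
    calls <- call_inheritance(
      mine %>% filter(!(.data$gene %in% composite_genes)),
      sid, cohort$genotypes, cohort$pedigree
    )
    for (k in seq_len(nrow(calls))) {
      cl <- calls[k, ]
      gene <- cl$gene
      vids <- cl$variant_ids[[1]]
      tags <- tags_for(gene)
      if (cl$de_novo) tags <- c(tags, "de_novo")
      if (cl$segregation == "consistent" && cl$seg_informative) {
        tags <- c(tags, "segregation")
      }
      gene_row <- cohort$genes[cohort$genes$gene == gene, ]
      if (cl$model %in% c("hom_recessive", "x_hemizygous") &&
          nrow(lcsh) > 0 && nrow(gene_row) == 1 &&
          any(lcsh$chrom == gene_row$chrom &
                lcsh$start <= gene_row$end & lcsh$end >= gene_row$start)) {
        tags <- c(tags, "lcsh_support")
      }
      if (any(vids %in% founder_vids)) {
        tags <- c(tags, "shared_rare_variant")
      }
      if (depleted &&
          cl$model %in% c("hom_recessive", "compound_het", "x_hemizygous") &&
          gene %in% gene_sets$known) {
        # A positive depletion assay is the functional readout of a
        # biallelic defect in a known mtDNA-maintenance gene.
        tags <- c(tags, "functional_assay")
      }
      findings[[length(findings) + 1]] <- finding_row(
        sid, nuclear_source(gene, gene_sets), gene = gene,
        payload = paste(vids, collapse = ","),
        model = cl$model, phase = cl$phase, tags = tags
      )
    }

    # -- composite CNV + SNV findings ------------------------------------
    for (gene in composite_genes) {
      comp <- composite %>% filter(.data$gene == gene)
      findings[[length(findings) + 1]] <- finding_row(
        sid, nuclear_source(gene, gene_sets), gene = gene,
        payload = paste(
          c(comp$variant_id,
            sprintf("%s:%d-%d del", comp$segment_chrom[1],
                    comp$segment_start[1], comp$segment_end[1])),
          collapse = ","),
        model = "composite_cnv_snv", phase = "in_trans",
        tags = tags_for(gene)
      )
    }

    # -- CNV-only findings -------------------------------------------------
    seg_rest <- segs
    if (nrow(composite) > 0) {
      seg_rest <- segs %>%
        anti_join(composite %>%
                    distinct(chrom = .data$segment_chrom,
                             start = .data$segment_start,
                             end = .data$segment_end),
                  by = c("chrom", "start", "end"))
    }
    for (k in seq_len(nrow(seg_rest))) {
      sg <- seg_rest[k, ]
      findings[[length(findings) + 1]] <- finding_row(
        sid, "chromosomal",
        payload = sprintf("%s:%d-%d %s", sg$chrom, sg$start, sg$end,
                          sg$state),
        tags = if (!is.na(sg$disorder)) "known_pathogenic" else character()
      )
    }

    # -- mtDNA arm ---------------------------------------------------------
    mt_i <- cohort$mt_variants %>% filter(.data$sample_id == sid)
    if (nrow(mt_i) > 0) {
      mt_hits <- prioritize_mt_variants(mt_i, cohort$mt_catalog)
      if (nrow(mt_hits) > 0) {
        mt_all[[length(mt_all) + 1]] <- mt_hits
      }
      for (k in seq_len(nrow(mt_hits))) {
        h <- mt_hits[k, ]
        findings[[length(findings) + 1]] <- finding_row(
          sid, "mtdna",
          payload = sprintf("m.%d%s>%s (het %.2f)", h$pos, h$ref, h$alt,
                            h$heteroplasmy),
          tags = if (h$catalog_status == "confirmed") {
            "known_pathogenic"
          } else {
            character()
          }
        )
      }
    }
    cov_i <- cohort$mt_coverage %>% filter(.data$sample_id == sid)
    if (nrow(cov_i) == MT_GENOME_LENGTH) {
      del <- detect_large_deletion(cov_i)
      if (nrow(del) == 1) {
        findings[[length(findings) + 1]] <- finding_row(
          sid, "mtdna",
          payload = sprintf("m.%d_%ddel%d", del$first_deleted,
                            del$last_deleted, del$length),
          tags = "known_pathogenic"  # large single deletions: classic event
        )
      }
    }
  }

  findings <- if (length(findings) == 0) {
    finding_row(character(0), character(0))[0, ]
  } else {
    bind_rows(findings)
  }
  findings$firmness <- purrr::pmap_chr(
    findings %>% select("source", "model", "phase", "tags"),
    function(source, model, phase, tags) {
      assign_firmness(source, model, phase, tags)
    }
  )

  severities <- purrr::map_chr(cases, function(sid) {
    act <- cohort$enzymes %>% filter(.data$sample_id == sid)
    if (nrow(act) == 0) NA_character_ else classify_severity(act)
  })
  classifications <- tibble(
    sample_id = cases,
    category = purrr::map_chr(cases, function(sid) {
      classify_patient(findings %>% filter(.data$sample_id == sid))
    }),
    severity = severities
  )

  structure(list(
    findings = findings,
    classifications = classifications,
    summary = summarize_cohort(classifications),
    prioritized = prioritized,
    trace = wes$trace,
    cnv = bind_rows(cnv_all),
    lcsh = bind_rows(lcsh_all),
    mt = bind_rows(mt_all),
    depletion = depletion,
    hwe = hwe
  ), class = "mitodx_diagnosis")
}

#' @export
print.mitodx_diagnosis <- function(x, ...) {
  cat("<mitodx_diagnosis>\n")
  cat(sprintf("  %d patients, %d findings (%d firm)\n",
              nrow(x$classifications), nrow(x$findings),
              sum(x$findings$firmness == "firm")))
  print(as_tibble(x$summary))
  invisible(x)
}
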
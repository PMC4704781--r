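# Per-patient integration: Bernier severity grading, evidence-based
# firmness (firm vs pVUS), diagnostic category assignment, and cohort
# summary arithmetic.

#' Diagnostic categories, in priority order
#'
#' When a patient harbours multiple firm findings, the category of the
#' highest-priority one is assigned; the order follows the diagnostic
#' narrative (mtDNA first, chromosomal last) and is configurable in
#' [classify_patient()].
#' @export
diagnostic_categories <- c(
  "mtdna_mutation", "known_nuclear_gene", "novel_mito_related_gene",
  "other_monogenic_gene", "chromosomal_aberration", "pvus_only", "unresolved"
)

#' Evidence tags accepted as molecular proof of pathogenicity
#' @export
evidence_tags <- c(
  "rescue", "segregation", "de_novo", "known_pathogenic", "lcsh_support",
  "shared_rare_variant", "no_detectable_protein", "functional_assay",
  "splice_defect"
)

#' Bernier severity from respiratory-chain enzyme activities
#'
#' Major: any non-fibroblast tissue below 20% of control, a fibroblast line
#' below 30%, or below 30% in two or more tissues. Minor: any tissue below
#' 30%, a fibroblast line below 40%, or below 40% in two or more tissues.
#' Activities are percent of control relative to citrate synthase (or
#' complex II) activity, already normalized on input.
#'
#' @param activities Tibble with `tissue` (`"tissue"` or `"fibroblast"`),
#'   `complex`, `percent_control` (>= 0). One patient's measurements.
#' @return `"major"`, `"minor"` or `"none"`.
#' @export
classify_severity <- function(activities) {
  assert_columns(activities, c("tissue", "percent_control"), "activities")
  if (nrow(activities) == 0) abort("no enzyme activity measurements")
  if (any(activities$percent_control < 0)) {
    abort("percent of control must be non-negative")
  }
  pc <- activities$percent_control
  fib <- activities$tissue == "fibroblast"
  n_tissues_below <- function(threshold) {
    length(unique(activities$tissue[pc < threshold]))
  }
  major <- any(pc[!fib] < 20) || any(pc[fib] < 30) || n_tissues_below(30) >= 2
  minor <- any(pc[!fib] < 30) || any(pc[fib] < 40) || n_tissues_below(40) >= 2
  if (major) "major" else if (minor) "minor" else "none"
}

# Is the genotype configuration of a finding fully established?
configuration_established <- function(source, model, phase) {
  if (source %in% c("mtdna", "chromosomal")) return(TRUE)
  if (is.na(model)) return(FALSE)
  switch(model,
    hom_recessive = TRUE,
    x_hemizygous = TRUE,
    de_novo_dominant = TRUE,
    compound_het = identical(phase, "in_trans"),
    composite_cnv_snv = TRUE,
    FALSE
  )
}

#' Firmness of one finding: firm diagnosis or pVUS
#'
#' A finding is firm only when (i) the causal genotype configuration is
#' established -- biallelic with phase in trans for compound heterozygotes,
#' homozygous, hemizygous, confirmed de novo dominant, or an mtDNA /
#' chromosomal event -- and (ii) at least one molecular evidence tag
#' supports pathogenicity. Candidates lacking molecular evidence stay pVUS
#' even in well-known disease genes.
#'
#' @param source Finding source: `"mtdna"`, `"nuclear_known_gene"`,
#'   `"nuclear_mito_related"`, `"nuclear_other_monogenic"`,
#'   `"chromosomal"`.
#' @param model Inheritance model (`NA` for non-nuclear findings).
#' @param phase Compound-het phase (`"in_trans"`, `"unknown"`, or `NA`).
#' @param tags Character vector of evidence tags attached to the finding.
#' @return `"firm"` or `"pVUS"`.
#' @export
assign_firmness <- function(source, model = NA_character_,
                            phase = NA_character_, tags = character()) {
  tags <- intersect(tags, evidence_tags)
  established <- configuration_established(source, model, phase)
  if (established && length(tags) > 0) "firm" else "pVUS"
}

source_category <- c(
  mtdna = "mtdna_mutation",
  nuclear_known_gene = "known_nuclear_gene",
  nuclear_mito_related = "novel_mito_related_gene",
  nuclear_other_monogenic = "other_monogenic_gene",
  chromosomal = "chromosomal_aberration"
)

#' Diagnostic category for one patient from their findings
#'
#' The category of the highest-priority firm finding wins; patients with
#' findings but no firm one are `pvus_only`; patients with no findings are
#' `unresolved`. Stable under permutation of the findings.
#'
#' @param findings Tibble with at least `source` and `firmness` for one
#'   patient (zero rows allowed).
#' @param priority Category priority order (highest first).
#' @return A single category string.
#' @export
classify_patient <- function(findings,
                             priority = diagnostic_categories[1:5]) {
  if (is.null(findings) || nrow(findings) == 0) return("unresolved")
  firm <- findings %>% filter(.data$firmness == "firm")
  if (nrow(firm) == 0) return("pvus_only")
  cats <- unname(source_category[firm$source])
  cats[order(match(cats, priority))][1]
}

#' Cohort summary: per-category counts and percentages
#'
#' Accepts either a per-patient classification tibble (column `category`)
#' or a named count vector/list over the categories. Percentages are
#' rounded half-up to one decimal. Derived aggregates: `any_prioritized`
#' (every category except unresolved) and `firm_total` (the five firm
#' categories).
#'
#' @param x Classification tibble with a `category` column, or named counts.
#' @param total Cohort size; defaults to the sum of counts. An error is
#'   raised if the counts do not sum to it.
#' @return A `mitodx_cohort_summary`: tibble of `category`, `n`, `pct` with
#'   aggregate attributes (see [glance.mitodx_cohort_summary()]).
#' @export
summarize_cohort <- function(x, total = NULL) {
  if (is.data.frame(x)) {
    assert_columns(x, "category", "classification table")
    counts <- table(factor(x$category, levels = diagnostic_categories))
    counts <- setNames(as.integer(counts), names(counts))
  } else {
    bad <- setdiff(names(x), diagnostic_categories)
    if (length(bad) > 0) {
      abort(sprintf("unknown categories: %s", paste(bad, collapse = ", ")))
    }
    counts <- setNames(rep(0L, length(diagnostic_categories)),
                       diagnostic_categories)
    counts[names(x)] <- as.integer(unlist(x))
  }
  total <- total %||% sum(counts)
  if (sum(counts) != total) {
    abort(sprintf("category counts (%d) do not sum to the cohort size (%d)",
                  sum(counts), total))
  }
  firm_cats <- diagnostic_categories[1:5]
  out <- tibble(
    category = factor(diagnostic_categories, levels = diagnostic_categories),
    n = unname(counts[diagnostic_categories]),
    pct = percent_of(unname(counts[diagnostic_categories]), total)
  )
  structure(out,
    class = c("mitodx_cohort_summary", class(out)),
    total = total,
    any_prioritized_n = sum(counts[setdiff(diagnostic_categories, "unresolved")]),
    any_prioritized_pct = percent_of(
      sum(counts[setdiff(diagnostic_categories, "unresolved")]), total),
    firm_n = sum(counts[firm_cats]),
    firm_pct = percent_of(sum(counts[firm_cats]), total)
  )
}

#' One-row aggregates of a cohort summary
#'
#' @param x A [summarize_cohort()] result.
#' @param ... Unused.
#' @return Tibble with `total`, `any_prioritized_n/pct`, `firm_n/pct`,
#'   `pvus_only_pct`, `unresolved_pct`.
#' @export
glance.mitodx_cohort_summary <- function(x, ...) {
  tibble(
    total = attr(x, "total"),
    any_prioritized_n = attr(x, "any_prioritized_n"),
    any_prioritized_pct = attr(x, "any_prioritized_pct"),
    firm_n = attr(x, "firm_n"),
    firm_pct = attr(x, "firm_pct"),
    pvus_only_pct = x$pct[x$category == "pvus_only"],
    unresolved_pct = x$pct[x$category == "unresolved"]
  )
}

#' Per-category rows of a cohort summary as a plain tibble
#'
#' @inheritParams glance.mitodx_cohort_summary
#' @export
tidy.mitodx_cohort_summary <- function(x, ...) {
  as_tibble(x)
}

#' Summarize enzymatic (biochemical) diagnoses
#'
#' Counts per enzymatic diagnosis label with percentages of the cohort,
#' rounded half-up to one decimal.
#'
#' @param x Tibble with a `diagnosis` column (one row per patient) or a
#'   named count vector.
#' @param total Cohort size (defaults to the sum of counts).
#' @return Tibble `diagnosis`, `n`, `pct` sorted by decreasing count.
#' @export
summarize_enzymatic <- function(x, total = NULL) {
  counts <- if (is.data.frame(x)) {
    assert_columns(x, "diagnosis", "enzymatic diagnoses")
    table(x$diagnosis)
  } else {
    x
  }
  total <- total %||% sum(counts)
  tibble(
    diagnosis = names(counts),
    n = as.integer(counts),
    pct = percent_of(as.integer(counts), total)
  ) %>% arrange(dplyr::desc(.data$n))
}
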
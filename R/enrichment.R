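# Prioritized-gene enrichment evaluation: percentage of individuals
# harbouring prioritized genes in cases vs controls, for known disease
# genes, mitochondria-related genes, and a 908-gene / 1000-draw
# random-gene-set null.

#' Enrichment configuration
#'
#' @param random_set_size Genes per random draw (default 908).
#' @param n_draws Number of random sets (default 1000).
#' @param require_configuration If `TRUE`, an individual counts as
#'   harbouring a prioritized gene only when the gene's variants form a
#'   qualifying inheritance configuration (homozygous, two or more
#'   heterozygous, or hemizygous male X); if `FALSE`, any
#'   cascade-surviving variant counts.
#' @param seed Seed for the random draws.
#' @return A `mitodx_enrich_config` list.
#' @export
enrich_config <- function(random_set_size = 908L, n_draws = 1000L,
                          require_configuration = TRUE, seed = 1L) {
  stopifnot(random_set_size >= 1, n_draws >= 1)
  structure(list(random_set_size = as.integer(random_set_size),
                 n_draws = as.integer(n_draws),
                 require_configuration = require_configuration,
                 seed = seed),
            class = "mitodx_enrich_config")
}

#' Per-individual prioritized gene sets under the simplified cascade
#'
#' Runs the simplified exome pipeline (no manual-inspection, validation,
#' 1KJPN or HGVD steps; see [filter_config()] with `simplified = TRUE`) for
#' each individual and returns the genes harbouring prioritized variants,
#' optionally restricted to qualifying inheritance configurations.
#'
#' @param cohort A `mitodx_cohort` (or compatible list of tibbles).
#' @param sample_ids Individuals to process (cases and/or controls).
#' @param cfg A simplified [filter_config()].
#' @param ecfg An [enrich_config()].
#' @return Tibble `sample_id`, `gene` -- one row per individual-gene hit.
#' @export
prioritized_gene_sets <- function(cohort, sample_ids,
                                  cfg = filter_config(simplified = TRUE),
                                  ecfg = enrich_config()) {
  ca <- count_case_alleles(cohort$genotypes, cohort$cases)
  rows <- purrr::map(sample_ids, function(sid) {
    pri <- prioritize_patient(sid, cohort$variants, cohort$genotypes, cfg,
                              mito_genes = cohort$gene_sets$mito,
                              case_alleles = ca)$prioritized
    if (nrow(pri) == 0) return(NULL)
    if (ecfg$require_configuration) {
      calls <- call_inheritance(pri, sid, cohort$genotypes, cohort$pedigree)
      if (nrow(calls) == 0) return(NULL)
      tibble(sample_id = sid, gene = unique(calls$gene))
    } else {
      tibble(sample_id = sid, gene = unique(pri$gene))
    }
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(sample_id = character(), gene = character())
  else out
}

#' Percentage of individuals harbouring a prioritized gene from a set
#'
#' @param gene_hits Tibble `sample_id`, `gene` of prioritized genes per
#'   individual ([prioritized_gene_sets()]).
#' @param individuals All individual ids in the group (the denominator;
#'   individuals with no prioritized gene must still count).
#' @param gene_set Character vector of gene symbols.
#' @return Percentage in `[0, 100]` (not rounded).
#' @export
percent_with_prioritized <- function(gene_hits, individuals, gene_set) {
  if (length(individuals) == 0) abort("empty cohort")
  hit <- gene_hits %>%
    filter(.data$sample_id %in% individuals, .data$gene %in% gene_set) %>%
    distinct(.data$sample_id)
  100 * nrow(hit) / length(individuals)
}

#' Random-gene-set null for the enrichment percentage
#'
#' Draws `n_draws` random sets of `random_set_size` genes from the eligible
#' pool (all genes minus known disease genes minus mitochondria-related
#' genes) and computes the percentage of individuals harbouring a
#' prioritized gene from each set; returns the draws with their mean and
#' sample standard deviation (n-1 denominator).
#'
#' @param gene_hits,individuals As in [percent_with_prioritized()].
#' @param gene_pool Eligible gene pool to draw from.
#' @param ecfg An [enrich_config()]; `seed` makes the draws reproducible.
#' @return List with `null_mean`, `null_sd`, `draws` (numeric vector).
#' @export
random_geneset_null <- function(gene_hits, individuals, gene_pool,
                                ecfg = enrich_config()) {
  if (length(gene_pool) < ecfg$random_set_size) {
    abort(sprintf("gene pool (%d) smaller than the random set size (%d)",
                  length(gene_pool), ecfg$random_set_size))
  }
  hits <- gene_hits %>% filter(.data$sample_id %in% individuals,
                               .data$gene %in% gene_pool)
  draws <- withr::with_seed(ecfg$seed, {
    purrr::map_dbl(seq_len(ecfg$n_draws), function(i) {
      set <- sample(gene_pool, ecfg$random_set_size)
      percent_with_prioritized(hits, individuals, set)
    })
  })
  list(null_mean = mean(draws),
       null_sd = sd(draws),
       draws = draws)
}

#' Fold enrichment of cases over controls
#'
#' @param pct_cases,pct_controls Percentages of individuals harbouring
#'   prioritized genes.
#' @return `pct_cases / pct_controls`, or `NA` (undefined) when
#'   `pct_controls` is 0; both percentages always accompany the fold in
#'   [run_enrichment()] output.
#' @export
enrichment_fold <- function(pct_cases, pct_controls) {
  if_else(pct_controls > 0, pct_cases / pct_controls, NA_real_)
}

#' Run the full enrichment evaluation on a cohort
#'
#' Computes case and control percentages and folds for the known
#' disease-gene set and the mitochondria-related set, plus the random-set
#' null over the eligible pool.
#'
#' @param cohort A `mitodx_cohort`.
#' @param cfg Simplified cascade configuration.
#' @param ecfg An [enrich_config()].
#' @return A `mitodx_enrichment` list: `by_set` tibble (set, pct_cases,
#'   pct_controls, fold), `null` (mean, sd, draws), `gene_hits`.
#' @export
run_enrichment <- function(cohort, cfg = filter_config(simplified = TRUE),
                           ecfg = enrich_config()) {
  hits <- prioritized_gene_sets(
    cohort, c(cohort$cases, cohort$controls), cfg, ecfg)
  sets <- list(
    known = cohort$gene_sets$known,
    mito_related = cohort$gene_sets$mito
  )
  by_set <- purrr::imap(sets, function(gs, nm) {
    pc <- percent_with_prioritized(hits, cohort$cases, gs)
    pk <- percent_with_prioritized(hits, cohort$controls, gs)
    tibble(set = nm, pct_cases = pc, pct_controls = pk,
           fold = enrichment_fold(pc, pk))
  }) %>% bind_rows()
  pool <- setdiff(cohort$gene_sets$all,
                  union(cohort$gene_sets$known, cohort$gene_sets$mito))
  null <- random_geneset_null(hits, cohort$controls, pool, ecfg)
  null_cases <- random_geneset_null(hits, cohort$cases, pool, ecfg)
  by_set <- bind_rows(by_set, tibble(
    set = "random",
    pct_cases = null_cases$null_mean,
    pct_controls = null$null_mean,
    fold = enrichment_fold(null_cases$null_mean, null$null_mean)
  ))
  structure(list(by_set = by_set, null = null, null_cases = null_cases,
                 gene_hits = hits, config = ecfg),
            class = "mitodx_enrichment")
}

#' Per-set rows of an enrichment result
#' @param x A [run_enrichment()] result.
#' @param ... Unused.
#' @export
tidy.mitodx_enrichment <- function(x, ...) {
  x$by_set
}

#' One-row summary of an enrichment result
#' @inheritParams tidy.mitodx_enrichment
#' @export
glance.mitodx_enrichment <- function(x, ...) {
  tibble(
    known_fold = x$by_set$fold[x$by_set$set == "known"],
    mito_fold = x$by_set$fold[x$by_set$set == "mito_related"],
    null_mean = x$null$null_mean,
    null_sd = x$null$null_sd,
    n_draws = length(x$null$draws)
  )
}

#' @export
print.mitodx_enrichment <- function(x, ...) {
  cat("<mitodx_enrichment>\n")
  print(x$by_set)
  cat(sprintf("  random-set null: mean %.2f%%, sd %.2f%% over %d draws\n",
              x$null$null_mean, x$null$null_sd, length(x$null$draws)))
  invisible(x)
}
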
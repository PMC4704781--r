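# mtDNA arm: heteroplasmy estimation, catalog-based variant prioritization,
# circular-genome large-deletion detection and length arithmetic, and the
# qPCR-based mtDNA-depletion (MTDPS) rule.

#' Length of the circular human mtDNA reference (rCRS), in bases
#' @export
MT_GENOME_LENGTH <- 16569L

#' Heteroplasmy fraction from allele counts
#'
#' `alt / (ref + alt)` when total depth reaches `min_depth`; `NA` (no-call)
#' otherwise. Scale-invariant in the counts.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorised).
#' @param min_depth Minimum total depth for a call.
#' @return Numeric vector of fractions in `[0, 1]`, `NA` for no-calls.
#' @export
call_heteroplasmy <- function(ref_count, alt_count, min_depth = 20) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    abort("allele counts must be non-negative")
  }
  total <- ref_count + alt_count
  out <- alt_count / total
  out[total < min_depth] <- NA_real_
  out
}

#' Prioritize mtDNA variants against a pathogenicity catalog
#'
#' Variants matching a catalog entry with status `confirmed` or `reported`
#' are retained and annotated; everything else is dropped. Confirmed
#' entries are eligible for a firm diagnosis downstream; reported-only
#' entries can at most become prioritized variants of unknown significance.
#'
#' @param mt_variants Tibble with `pos`, `ref`, `alt` and either
#'   `heteroplasmy` or `ref_count`/`alt_count` columns (heteroplasmy is
#'   computed from counts when absent).
#' @param catalog Catalog tibble ([read_mt_catalog()]).
#' @param min_depth Depth gate for the heteroplasmy call.
#' @return The prioritized subset with `catalog_status` and `heteroplasmy`.
#' @export
prioritize_mt_variants <- function(mt_variants, catalog, min_depth = 20) {
  v <- as_tibble(mt_variants)
  if (!"heteroplasmy" %in% names(v)) {
    v$heteroplasmy <- call_heteroplasmy(v$ref_count, v$alt_count, min_depth)
  }
  stopifnot(all(v$pos >= 1 & v$pos <= MT_GENOME_LENGTH))
  v %>%
    inner_join(catalog %>% rename(catalog_status = "status"),
               by = c("pos", "ref", "alt")) %>%
    filter(.data$catalog_status %in% c("confirmed", "reported"))
}

#' Inclusive span of an mtDNA deletion on the circular genome
#'
#' The deletion m.11359_15068del spans `15068 - 11359 + 1 = 3710` bases;
#' a deletion wrapping the origin (first > last) spans
#' `genome_len - first + 1 + last` bases.
#'
#' @param first_deleted,last_deleted First and last deleted positions
#'   (1-based, traversed in the reference direction).
#' @param genome_len Circle length (default rCRS, 16,569 bp).
#' @return Deleted length in bases.
#' @export
deletion_length <- function(first_deleted, last_deleted,
                            genome_len = MT_GENOME_LENGTH) {
  if (any(first_deleted < 1 | first_deleted > genome_len) ||
      any(last_deleted < 1 | last_deleted > genome_len)) {
    abort("positions must lie in 1..genome_len")
  }
  if_else(last_deleted >= first_deleted,
          last_deleted - first_deleted + 1,
          genome_len - first_deleted + 1 + last_deleted)
}

#' Detect a large mtDNA deletion from a per-base coverage profile
#'
#' Finds the maximal circular arc of consecutive low-coverage bases (depth
#' below `drop_factor` times the flanking/reference depth), tolerating
#' isolated noisy bases inside the arc up to `max_gap` consecutive
#' non-low positions, and reports its first and last deleted bases plus the
#' residual fraction of intact molecules. Arcs may wrap the origin.
#'
#' @param profile Tibble with `pos` (1..genome length, complete) and
#'   `depth`, or a bare numeric depth vector covering the whole circle
#'   (rCRS length 16,569 in production; smaller circles are accepted for
#'   toy geometries).
#' @param drop_factor Depth fraction below which a base counts as deleted.
#' @param min_span Minimum arc length in bases to report.
#' @param max_gap Longest run of non-low bases absorbed inside an arc.
#' @return One-row tibble with `first_deleted`, `last_deleted`, `length`,
#'   `heteroplasmy` (1 - arc depth / flanking depth), or a zero-row tibble
#'   when no qualifying arc exists. Errors when the whole genome is low
#'   (no reference depth level).
#' @export
detect_large_deletion <- function(profile, drop_factor = 0.5,
                                  min_span = 100, max_gap = 50) {
  depth <- if (is.numeric(profile)) profile else {
    assert_columns(profile, c("pos", "depth"), "coverage profile")
    profile$depth[order(profile$pos)]
  }
  n <- length(depth)
  if (n < 10) {
    abort("coverage profile must cover the whole circular genome")
  }
  reference <- stats::median(depth)
  if (reference <= 0) {
    abort("whole genome is low coverage: no reference depth level")
  }
  low <- depth < drop_factor * reference
  no_hit <- tibble(first_deleted = integer(), last_deleted = integer(),
                   length = integer(), heteroplasmy = numeric())
  if (!any(low)) return(no_hit)

  # Runs of low bases on the circle: rotate so the sequence starts deep
  # inside the longest high (non-deleted) stretch, then use linear
  # run-length encoding; this keeps any arc, wrapping or not, contiguous in
  # rotated space even under gap merging.
  r0 <- rle(low)
  e0 <- cumsum(r0$lengths)
  s0 <- e0 - r0$lengths + 1
  high_runs <- which(!r0$values)
  k <- high_runs[which.max(r0$lengths[high_runs])]
  start_offset <- s0[k] + (r0$lengths[k] %/% 2L)
  rot <- c(low[start_offset:n], low[seq_len(start_offset - 1)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(value = r$values, start = starts, end = ends)

  # Merge low runs separated by short high gaps.
  low_runs <- runs %>% filter(.data$value)
  if (nrow(low_runs) == 0) return(no_hit)
  merged <- list()
  cur <- c(low_runs$start[1], low_runs$end[1])
  if (nrow(low_runs) > 1) {
    for (i in 2:nrow(low_runs)) {
      if (low_runs$start[i] - cur[2] - 1 <= max_gap) {
        cur[2] <- low_runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- c(low_runs$start[i], low_runs$end[i])
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  spans <- purrr::map_int(merged, ~ .x[2] - .x[1] + 1L)
  best <- merged[[which.max(spans)]]
  if (max(spans) < min_span) return(no_hit)

  # Map rotated indices back to circle positions.
  unrotate <- function(i) ((i + start_offset - 2L) %% n) + 1L
  first_deleted <- unrotate(best[1])
  last_deleted <- unrotate(best[2])
  arc_idx <- unrotate(seq.int(best[1], best[2]))
  flank <- mean(depth[-arc_idx])
  tibble(
    first_deleted = as.integer(first_deleted),
    last_deleted = as.integer(last_deleted),
    length = as.integer(deletion_length(first_deleted, last_deleted, n)),
    heteroplasmy = 1 - mean(depth[arc_idx]) / flank
  )
}

#' The MTDPS depletion rule
#'
#' A diagnosis of mtDNA depletion syndrome requires the mtDNA:nuclear copy
#' ratio to be below 35% of the healthy-control level in every one of 4
#' independent experiments.
#'
#' @param ratio_threshold Fraction of the control level (default 0.35,
#'   strict `<`).
#' @param n_experiments Required replicate count (default 4).
#' @return A `mitodx_depletion_rule` list.
#' @export
depletion_rule <- function(ratio_threshold = 0.35, n_experiments = 4L) {
  stopifnot(ratio_threshold > 0, ratio_threshold < 1, n_experiments >= 1)
  structure(list(ratio_threshold = ratio_threshold,
                 n_experiments = as.integer(n_experiments)),
            class = "mitodx_depletion_rule")
}

#' Call mtDNA depletion from qPCR replicate ratios
#'
#' @param patient_ratios Replicate mtDNA:nuclear copy ratios for the
#'   patient; must have exactly `rule$n_experiments` values.
#' @param control_mean Mean ratio in healthy control tissue.
#' @param rule A [depletion_rule()].
#' @return `"MTDPS"` when every replicate is strictly below the threshold
#'   fraction of the control mean, else `"normal"`.
#' @export
call_depletion <- function(patient_ratios, control_mean = 1,
                           rule = depletion_rule()) {
  if (length(patient_ratios) != rule$n_experiments) {
    abort(sprintf("the depletion rule requires exactly %d replicate ratios",
                  rule$n_experiments))
  }
  stopifnot(control_mean > 0)
  if (all(patient_ratios / control_mean < rule$ratio_threshold)) {
    "MTDPS"
  } else {
    "normal"
  }
}
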
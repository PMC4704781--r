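# Internal helpers shared across modules.

# Round half-up to `digits` decimals. Cohort percentages are reported this
# way; base round() uses banker's rounding which differs at exact .5 ties.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Percentage of a count, rounded half-up to one decimal
#'
#' Cohort bookkeeping helper: `100 * count / total`, rounded half-up to one
#' decimal place, the convention used throughout the cohort summaries (e.g.
#' 102 of 142 patients -> 71.8).
#'
#' @param count Numerator count (vectorised).
#' @param total Denominator count.
#' @return Numeric vector of percentages.
#' @examples
#' percent_of(102, 142)
#' percent_of(c(61, 35), c(142, 49))
#' @export
percent_of <- function(count, total) {
  stopifnot(all(total > 0))
  round_half_up(100 * count / total, 1)
}

# Genotype vocabulary used in the long genotype table.
gt_levels <- c("hom_ref", "het", "hom_alt", "hemi_alt", "missing")

# Alternate-allele dose per genotype call (hemizygous counts one allele).
allele_dose <- c(hom_ref = 0, het = 1, hom_alt = 2, hemi_alt = 1, missing = 0)

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

is_hom <- function(gt) gt %in% c("hom_alt", "hemi_alt")
carries_alt <- function(gt) gt %in% c("het", "hom_alt", "hemi_alt")

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Overlap length of 1-based inclusive intervals [s1,e1] and [s2,e2].
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# Does a position fall inside any 1-based inclusive region on its chromosome?
pos_in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(rep(FALSE, length(pos)))
  }
  out <- logical(length(pos))
  for (i in seq_len(nrow(regions))) {
    hit <- chrom == regions$chrom[i] &
      pos >= regions$start[i] & pos <= regions$end[i]
    out <- out | hit
  }
  out
}
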
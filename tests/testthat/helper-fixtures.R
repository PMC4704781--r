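# Shared fixtures, built in code. The default synthetic cohort is expensive
# enough to build once and reuse across test files.

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(sim_config(seed = 1L))
  }
  .fixture_env$cohort
}

default_diagnosis <- function() {
  if (is.null(.fixture_env$diagnosis)) {
    .fixture_env$diagnosis <- diagnose_cohort(default_cohort())
  }
  .fixture_env$diagnosis
}

# Minimal annotated-variant tibble with every column the cascade consumes.
make_variants <- function(n = 1, chrom = "chr1", pos = seq_len(n) * 1000L,
                          ref = "A", alt = "G", gene = "G0001",
                          class = "missense",
                          maf_dbsnp137 = NA_real_, maf_esp6500 = NA_real_,
                          maf_1kg = NA_real_, maf_exac = NA_real_,
                          maf_hgvd = NA_real_, maf_1kjpn = NA_real_,
                          sift = NA_real_, gerp = NA_real_,
                          segdup = FALSE, dbsnp_medical_impact = FALSE,
                          artifact_flag = FALSE, kjpn_hom = FALSE) {
  v <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    class = class, maf_dbsnp137 = maf_dbsnp137, maf_esp6500 = maf_esp6500,
    maf_1kg = maf_1kg, maf_exac = maf_exac, maf_hgvd = maf_hgvd,
    maf_1kjpn = maf_1kjpn, sift = sift, gerp = gerp, segdup = segdup,
    dbsnp_medical_impact = dbsnp_medical_impact,
    artifact_flag = artifact_flag, kjpn_hom = kjpn_hom
  )
  v$variant_id <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  v
}

# Random annotated variants whose filter outcomes span every cascade step.
random_variant_table <- function(n, seed = 1) {
  withr::with_seed(seed, {
    pick <- function(x) sample(x, n, replace = TRUE)
    maybe <- function(gen, p_na = 0.3) {
      out <- gen(n)
      out[runif(n) < p_na] <- NA_real_
      out
    }
    make_variants(
      n = n,
      pos = sample.int(1e7, n),
      gene = sprintf("G%04d", sample.int(200, n, replace = TRUE)),
      class = pick(c("missense", "nonsense", "splice_site",
                     "frameshift_indel", "inframe_indel", "other")),
      maf_dbsnp137 = maybe(function(k) runif(k, 0, 0.05)),
      maf_esp6500 = maybe(function(k) runif(k, 0, 0.005)),
      maf_1kg = maybe(function(k) runif(k, 0, 0.05)),
      maf_exac = maybe(function(k) runif(k, 0, 0.005)),
      maf_hgvd = maybe(function(k) runif(k, 0, 0.02)),
      maf_1kjpn = maybe(function(k) runif(k, 0, 0.02)),
      sift = maybe(function(k) runif(k, 0, 1)),
      gerp = maybe(function(k) runif(k, -5, 6)),
      segdup = pick(c(TRUE, FALSE, FALSE, FALSE)),
      dbsnp_medical_impact = pick(c(TRUE, rep(FALSE, 9))),
      artifact_flag = pick(c(TRUE, rep(FALSE, 9))),
      kjpn_hom = pick(c(TRUE, rep(FALSE, 9)))
    ) %>%
      dplyr::mutate(case_alleles = sample(0:12, n, replace = TRUE))
  })
}

# A three-member pedigree (affected child + parents).
make_trio_ped <- function(child = "kid", sex = "female") {
  tibble::tibble(
    family_id = "F1",
    sample_id = c(child, "dad", "mum"),
    father_id = c("dad", NA, NA),
    mother_id = c("mum", NA, NA),
    sex = c(sex, "male", "female"),
    affected = c(TRUE, FALSE, FALSE)
  )
}

make_genotypes <- function(...) {
  rows <- list(...)
  tibble::tibble(
    variant_id = purrr::map_chr(rows, 1),
    sample_id = purrr::map_chr(rows, 2),
    gt = purrr::map_chr(rows, 3)
  )
}

# Independent oracle: exact Hardy-Weinberg p-value by direct closed-form
# enumeration of the conditional distribution (lgamma arithmetic, a
# different route than the package's recurrence).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_minor <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(h + 1) -
      lgamma(hom_minor + 1) + h * log(2) -
      (lgamma(2 * n + 1) - lgamma(n_minor + 1) -
         lgamma(2 * n - n_minor + 1))
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[hets == n_ab]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Independent oracle: circular inclusive span by walking the circle.
circular_span_oracle <- function(first, last, len) {
  pos <- first
  count <- 1L
  while (pos != last) {
    pos <- if (pos == len) 1L else pos + 1L
    count <- count + 1L
  }
  count
}

# Independent oracle: compound-het phase by exhaustive enumeration of
# parental haplotype assignments for a het/het child at two biallelic
# sites. Returns list(consistent, phase).
phase_oracle <- function(father_gt, mother_gt) {
  opts <- function(gt) switch(gt, hom_ref = 0L, het = c(0L, 1L), hom_alt = 1L)
  outcomes <- character()
  for (f1 in opts(father_gt[1])) for (f2 in opts(father_gt[2])) {
    for (m1 in opts(mother_gt[1])) for (m2 in opts(mother_gt[2])) {
      if (f1 + m1 == 1L && f2 + m2 == 1L) {
        hp <- c(f1, f2)
        outcomes <- c(outcomes,
                      if (all(hp == c(1L, 1L)) || all(hp == c(0L, 0L))) {
                        "in_cis"
                      } else {
                        "in_trans"
                      })
      }
    }
  }
  if (length(outcomes) == 0) {
    list(consistent = FALSE, phase = NA_character_)
  } else if (all(outcomes == "in_trans")) {
    list(consistent = TRUE, phase = "in_trans")
  } else if (all(outcomes == "in_cis")) {
    list(consistent = TRUE, phase = "in_cis")
  } else {
    list(consistent = TRUE, phase = "unknown")
  }
}
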
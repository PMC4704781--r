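# Readers and writers for the standard formats every stage touches.
#
# Coordinate conventions: variants are 1-based inclusive (VCF); BED region
# files are 0-based half-open on disk and are converted to 1-based inclusive
# tibbles at this boundary, nowhere else.

annotation_cols <- c(
  "chrom", "pos", "ref", "alt", "gene", "class",
  "maf_dbsnp137", "maf_esp6500", "maf_1kg", "maf_exac", "maf_hgvd",
  "maf_1kjpn", "sift", "gerp", "segdup"
)

functional_classes <- c(
  "nonsense", "splice_site", "frameshift_indel", "inframe_indel",
  "missense", "other"
)

#' Read a tab-delimited variant annotation table
#'
#' The table is keyed by `(chrom, pos, ref, alt)` and carries the gene
#' symbol, functional class, per-panel minor allele frequencies
#' (dbSNP137, ESP6500, 1KG, ExAC, HGVD, 1KJPN), SIFT and GERP scores, and a
#' segmental-duplication flag. Optional boolean columns
#' `dbsnp_medical_impact` (dbSNP entry has known medical impact; exempts the
#' variant from the dbSNP frequency filter) and `artifact_flag` (variant
#' judged an NGS artifact on manual read inspection) are honoured when
#' present and default to `FALSE`.
#'
#' Missing MAFs are kept as `NA` and treated as frequency 0 downstream:
#' absence from a population panel is the operational definition of a novel
#' variant.
#'
#' @param path Path to the tab-delimited annotation file.
#' @return A tibble with one row per allele, including a `variant_id`
#'   (`chrom:pos:ref:alt`) key column.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(ann, annotation_cols, "annotation table")
  bad_class <- setdiff(unique(ann$class), functional_classes)
  if (length(bad_class) > 0) {
    abort(sprintf("unknown functional class label(s): %s",
                  paste(bad_class, collapse = ", ")))
  }
  maf_cols <- grep("^maf_", annotation_cols, value = TRUE)
  for (col in maf_cols) {
    v <- ann[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort(sprintf("%s contains frequencies outside [0, 1]", col))
    }
  }
  if (is.null(ann$dbsnp_medical_impact)) ann$dbsnp_medical_impact <- FALSE
  if (is.null(ann$artifact_flag)) ann$artifact_flag <- FALSE
  ann <- mutate(ann,
    variant_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt),
    segdup = as.logical(.data$segdup),
    dbsnp_medical_impact = as.logical(.data$dbsnp_medical_impact),
    artifact_flag = as.logical(.data$artifact_flag)
  )
  if (anyDuplicated(ann$variant_id)) {
    dup <- ann$variant_id[duplicated(ann$variant_id)][1]
    abort(sprintf("annotation key collision: %s appears more than once", dup))
  }
  as_tibble(ann)
}

# Translate one VCF GT string into the genotype vocabulary.
decode_gt <- function(gt, alt_index) {
  gt <- sub(":.*$", "", gt)
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  dose <- sum(alleles == as.character(alt_index))
  if (length(alleles) == 1) {
    if (dose == 1) "hemi_alt" else "hom_ref"
  } else if (dose == 0) {
    "hom_ref"
  } else if (dose == length(alleles)) {
    "hom_alt"
  } else {
    "het"
  }
}

#' Read a multi-sample cohort VCF together with its annotation table
#'
#' VCF records are split per alternate allele (all downstream thresholds are
#' per-allele) and joined to the annotation table by `(chrom, pos, ref,
#' alt)`. Alleles without a matching annotation row are excluded with a
#' warning naming them, never silently dropped.
#'
#' @param vcf_path Path to a VCF 4.x file (plain or gzipped).
#' @param annotation_path Path to the annotation table; see
#'   [read_annotation()].
#' @return A list with `variants` (annotated allele tibble) and `genotypes`
#'   (long tibble: `variant_id`, `sample_id`, `gt` in
#'   hom_ref/het/hom_alt/hemi_alt/missing).
#' @export
read_cohort_vcf <- function(vcf_path, annotation_path) {
  ann <- read_annotation(annotation_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_mat)

  records <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      gts <- vapply(gt_mat[i, ], decode_gt, character(1), alt_index = k)
      records[[length(records) + 1L]] <- tibble(
        chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i],
        alt = alts[k],
        sample_id = samples,
        gt = unname(gts)
      )
    }
  }
  long <- bind_rows(records)
  long$variant_id <- variant_id(long$chrom, long$pos, long$ref, long$alt)

  keys <- distinct(long, .data$variant_id)
  unmatched <- setdiff(keys$variant_id, ann$variant_id)
  if (length(unmatched) > 0) {
    warn(sprintf("%d VCF allele(s) had no annotation row and were excluded: %s",
                 length(unmatched),
                 paste(head(unmatched, 5), collapse = ", ")))
  }
  variants <- semi_join(ann, keys, by = "variant_id")
  genotypes <- long %>%
    filter(.data$variant_id %in% variants$variant_id) %>%
    select("variant_id", "sample_id", "gt")
  list(variants = variants, genotypes = genotypes)
}

#' Read a 6-column PED pedigree file
#'
#' Columns: family, sample, father, mother, sex (1 = male, 2 = female),
#' phenotype (1 = unaffected, 2 = affected). `0` marks a founder parent.
#'
#' @param path Path to the PED file.
#' @return A tibble with `family_id`, `sample_id`, `father_id`, `mother_id`
#'   (`NA` for founders), `sex` ("male"/"female"), `affected` (logical).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(
    path,
    col_names = c("family_id", "sample_id", "father_id", "mother_id",
                  "sex", "phenotype"),
    col_types = "ccccii", progress = FALSE
  )
  ped <- mutate(ped,
    father_id = if_else(.data$father_id == "0", NA_character_, .data$father_id),
    mother_id = if_else(.data$mother_id == "0", NA_character_, .data$mother_id),
    sex = c("male", "female")[.data$sex],
    affected = .data$phenotype == 2L
  ) %>% select(-"phenotype")
  validate_pedigree(ped)
}

# Invariants: referenced parents exist, nobody is their own ancestor.
validate_pedigree <- function(ped) {
  parents <- c(ped$father_id, ped$mother_id)
  parents <- parents[!is.na(parents)]
  unknown <- setdiff(parents, ped$sample_id)
  if (length(unknown) > 0) {
    abort(sprintf("pedigree references unknown parent(s) not marked founder: %s",
                  paste(unknown, collapse = ", ")))
  }
  idx <- setNames(seq_len(nrow(ped)), ped$sample_id)
  for (s in ped$sample_id) {
    seen <- character()
    frontier <- s
    while (length(frontier) > 0) {
      i <- idx[[frontier[1]]]
      frontier <- frontier[-1]
      for (p in c(ped$father_id[i], ped$mother_id[i])) {
        if (is.na(p)) next
        if (p == s) abort(sprintf("cyclic parentage involving sample %s", s))
        if (!(p %in% seen)) {
          seen <- c(seen, p)
          frontier <- c(frontier, p)
        }
      }
    }
  }
  as_tibble(ped)
}

#' Resolvable parent-offspring trios in a pedigree
#'
#' @param pedigree A pedigree tibble from [read_pedigree()].
#' @return Tibble with `sample_id`, `father_id`, `mother_id`, one row per
#'   sample whose two parents are both present.
#' @export
pedigree_trios <- function(pedigree) {
  pedigree %>%
    filter(!is.na(.data$father_id), !is.na(.data$mother_id)) %>%
    select("sample_id", "father_id", "mother_id")
}

#' Read a BED region file into a 1-based inclusive tibble
#'
#' BED is 0-based half-open on disk; conversion to the package's 1-based
#' inclusive convention happens here and only here.
#'
#' @param path Path to a 3- or 4-column BED file.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` (NA when absent).
#' @export
read_bed_regions <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(bed) < 3) abort("BED file needs at least 3 columns")
  tibble(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    name = if (ncol(bed) >= 4) as.character(bed[[4]]) else NA_character_
  )
}

write_bed_regions <- function(regions, path) {
  df <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = if (!is.null(regions$name)) regions$name else "."
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a plain-text file with one gene symbol per line.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read an mtDNA pathogenicity catalog table
#'
#' Tab-delimited with columns `pos`, `ref`, `alt`, `status`; `status` is
#' `confirmed` (confirmed pathogenic) or `reported` (reported but not
#' confirmed). A small fully synthetic fixture ships with the package
#' (`system.file("extdata", "synthetic_mt_catalog.tsv", package = "mitodx")`).
#'
#' @param path Path to the catalog file.
#' @return Tibble with `pos`, `ref`, `alt`, `status`.
#' @export
read_mt_catalog <- function(path) {
  cat_tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(cat_tbl, c("pos", "ref", "alt", "status"), "mtDNA catalog")
  bad <- setdiff(unique(cat_tbl$status), c("confirmed", "reported"))
  if (length(bad) > 0) {
    abort(sprintf("unknown catalog status: %s", paste(bad, collapse = ", ")))
  }
  as_tibble(cat_tbl)
}

# --- writers ----------------------------------------------------------------

encode_gt <- function(gt) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
    hemi_alt = "1", missing = "./.")[gt]
}

#' Write cohort genotypes as a multi-sample VCF
#'
#' Minimal GT-only VCF 4.2 emitter used by the synthetic-cohort writer; the
#' output round-trips losslessly through [read_cohort_vcf()].
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param genotypes Long genotype tibble (`variant_id`, `sample_id`, `gt`).
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @param fill Genotype written for sample/variant pairs absent from
#'   `genotypes`: the long table is sparse with absence meaning homozygous
#'   reference (`"hom_ref"`, the default), or `"missing"` for `./.`.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, genotypes, path, contigs = NULL,
                             fill = c("hom_ref", "missing")) {
  fill <- encode_gt(match.arg(fill))
  samples <- sort(unique(genotypes$sample_id))
  v <- variants %>%
    mutate(variant_id = variant_id(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  gt_wide <- genotypes %>%
    mutate(code = encode_gt(.data$gt)) %>%
    select("variant_id", "sample_id", "code") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "code",
                       values_fill = NA_character_)
  gt_wide <- gt_wide[match(v$variant_id, gt_wide$variant_id), , drop = FALSE]

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mitodx",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_cols <- as.matrix(gt_wide[, samples, drop = FALSE])
  gt_cols[is.na(gt_cols)] <- fill
  body <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

write_pedigree <- function(pedigree, path) {
  df <- data.frame(
    family = if (!is.null(pedigree$family_id)) pedigree$family_id else pedigree$sample_id,
    sample = pedigree$sample_id,
    father = if_else(is.na(pedigree$father_id), "0", pedigree$father_id),
    mother = if_else(is.na(pedigree$mother_id), "0", pedigree$mother_id),
    sex = if_else(pedigree$sex == "male", 1L, 2L),
    phenotype = if_else(pedigree$affected, 2L, 1L)
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
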
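#' Write per-sample VCF files for a synthetic cohort
#'
#' Each sample's VCF v4.3 contains only its non-reference calls (GT `0/1`
#' or `1/1`), with the simulated record QUAL and a per-call `DP` in the
#' genotype field, one ALT allele per record. Calls flagged hidden by the
#' cohort's `missing_rate` are omitted from the VCF (their loci appear in
#' the sample's low-coverage BED instead, see [emit_coverage_beds()]).
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
emit_vcfs <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  subjects <- rownames(cohort$genotypes)
  paths <- set_names(file.path(out_dir, paste0(subjects, ".vcf")), subjects)
  for (s in subjects) {
    g <- cohort$genotypes[s, ]
    keep <- which(g > 0L & !cohort$hidden[s, ])
    gt <- ifelse(g[keep] == 1L, "0/1", "1/1")
    recs <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t.\tGT:DP\t%s:%d",
                    v$chrom[keep], v$pos[keep], v$ref[keep], v$alt[keep],
                    cohort$qual[s, keep], gt, cohort$depth[s, keep])
    writeLines(c(vcf_header(s), recs), paths[[s]])
  }
  invisible(paths)
}

vcf_header <- function(sample) {
  c("##fileformat=VCFv4.3",
    "##source=genophen synthetic cohort generator",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
}

#' Write per-sample BED files of sub-10X coverage intervals
#'
#' Emits, for every sample, a 0-based half-open BED file covering exactly
#' the loci hidden behind low coverage for that sample (a 1-based position
#' p becomes the interval `[p-1, p)`); runs of adjacent hidden positions
#' are merged.
#'
#' @inheritParams emit_vcfs
#' @return Invisibly, a named character vector of the written file paths.
#' @export
emit_coverage_beds <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  subjects <- rownames(cohort$genotypes)
  paths <- set_names(file.path(out_dir, paste0(subjects, ".bed")), subjects)
  for (s in subjects) {
    idx <- which(cohort$hidden[s, ])
    if (length(idx) == 0) {
      writeLines(character(0), paths[[s]])
      next
    }
    iv <- merge_positions(v$chrom[idx], v$pos[idx])
    writeLines(sprintf("%s\t%d\t%d", iv$chrom, iv$start, iv$end), paths[[s]])
  }
  invisible(paths)
}

# merge 1-based positions into sorted 0-based half-open intervals
merge_positions <- function(chrom, pos) {
  d <- distinct(tibble(chrom = chrom, pos = pos))
  d <- d[order_variants(d$chrom, d$pos), ]
  out <- d |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(1L, diff(.data$pos) != 1L))) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$pos) - 1L, end = max(.data$pos),
              .groups = "drop") |>
    select("chrom", "start", "end")
  out
}

#' Write the cohort's phenotype and clinical-classification tables
#'
#' Tab-separated files with a header row: `phenotypes.tsv` (subject, the
#' fourteen binary signs, age, suspicion, systemic_score) and
#' `classification.tsv` (variant id, clinical class label as delivered by
#' the laboratory, including `likely-pathogenic`).
#'
#' @inheritParams emit_vcfs
#' @return Invisibly, the two file paths.
#' @export
write_cohort_tables <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(out_dir, "phenotypes.tsv")
  p2 <- file.path(out_dir, "classification.tsv")
  readr::write_tsv(cohort$phenotypes, p1)
  readr::write_tsv(cohort$classification, p2)
  invisible(c(phenotypes = p1, classification = p2))
}
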
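#' Per-variant allele frequencies from a genotype matrix
#'
#' Alternate-allele frequency is `(het + 2 * hom_alt) / (2 * non-missing
#' calls)`; the minor-allele frequency (MAF) is that frequency folded to
#' at most 0.5. Variants with zero non-missing calls get an unknown MAF
#' and are flagged.
#'
#' @param x A `geno_matrix` (typically QC-filtered).
#' @return A tibble with columns `id`, `alt_count`, `called_alleles`,
#'   `alt_freq`, `maf`, `maf_known`.
#' @export
compute_maf <- function(x) {
  stopifnot(inherits(x, "geno_matrix"))
  calls <- x$calls
  alt <- unname(colSums(calls, na.rm = TRUE))
  called <- 2L * unname(colSums(!is.na(calls)))
  af <- ifelse(called > 0, alt / called, NA_real_)
  tibble(
    id = colnames(calls),
    alt_count = as.integer(alt),
    called_alleles = as.integer(called),
    alt_freq = af,
    maf = pmin(af, 1 - af),
    maf_known = called > 0
  )
}

#' Frequency classification of variants
#'
#' A variant is `common` when any available MAF (internal or any reference
#' database) exceeds 0.05; `rare` when every available MAF is below 0.01
#' (including variants absent from all references with internal MAF below
#' 0.01); `low_frequency` otherwise. Boundary values (MAF exactly 0.05 or
#' exactly 0.01) classify as `low_frequency`.
#'
#' @param maf_table Output of [compute_maf()], or any data frame with
#'   columns `id` and `maf`.
#' @param reference Optional long-format reference-frequency table with
#'   columns `id` and `af` (one row per variant per database, e.g. from
#'   [read_reference_frequencies()]); allele frequencies are folded to MAF.
#' @return The input with a `freq_class` column added (factor with levels
#'   common, low_frequency, rare).
#' @export
classify_frequency <- function(maf_table, reference = NULL) {
  mafs <- map(seq_len(nrow(maf_table)), function(i) {
    v <- maf_table$maf[i]
    if (isFALSE(maf_table$maf_known[i])) v <- NA_real_
    ref <- if (!is.null(reference)) {
      pmin(reference$af[reference$id == maf_table$id[i]],
           1 - reference$af[reference$id == maf_table$id[i]])
    } else numeric(0)
    c(v, ref)
  })
  cls <- map_chr(mafs, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return("rare") # unknown everywhere
    if (max(v) > 0.05) return("common")
    if (all(v < 0.01)) return("rare")
    "low_frequency"
  })
  mutate(maf_table, freq_class = factor(cls, levels = c("common",
                                                        "low_frequency",
                                                        "rare")))
}

#' Merge laboratory clinical classes onto the cohort's variants
#'
#' Relabels `likely-pathogenic` as `pathogenic` (the two are pooled for
#' statistical power) and defaults variants absent from the table to `VUS`
#' with a warning.
#'
#' @param variant_ids Character vector of canonical variant ids.
#' @param classification Data frame with columns `id` and `class`
#'   (levels benign, pathogenic, likely-pathogenic, VUS).
#' @return A tibble `id`, `clinical_class` (factor benign/pathogenic/VUS).
#' @export
merge_clinical <- function(variant_ids, classification) {
  allowed <- c("benign", "pathogenic", "likely-pathogenic", "VUS")
  bad <- setdiff(unique(classification$class), allowed)
  if (length(bad) > 0) {
    abort(sprintf("unknown clinical class label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  cls <- classification$class[match(variant_ids, classification$id)]
  if (anyNA(cls)) {
    warn(sprintf("%d variant(s) absent from the classification table default to VUS",
                 sum(is.na(cls))))
    cls[is.na(cls)] <- "VUS"
  }
  cls[cls == "likely-pathogenic"] <- "pathogenic"
  tibble(id = variant_ids,
         clinical_class = factor(cls, levels = c("benign", "pathogenic",
                                                 "VUS")))
}

#' Classify the variants of a genotype matrix
#'
#' Convenience wrapper: computes MAFs, assigns frequency classes (against
#' optional reference frequencies) and merges the clinical classification.
#'
#' @inheritParams compute_maf
#' @inheritParams classify_frequency
#' @param classification See [merge_clinical()]; `NULL` classifies
#'   everything as VUS (with a warning).
#' @return A tibble with one row per variant: frequencies, `freq_class`
#'   and `clinical_class`.
#' @export
classify_variants <- function(x, classification = NULL, reference = NULL) {
  maf <- classify_frequency(compute_maf(x), reference)
  clin <- merge_clinical(maf$id,
                         classification %||% tibble(id = character(),
                                                    class = character()))
  left_join(maf, clin, by = "id") |>
    left_join(select(x$variants, "id", "chrom", "pos"), by = "id")
}

#' Assign panel genes to variants by position
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos`.
#' @param genes Data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive); default [marfan_panel_genes()].
#' @return The input with a `gene` column (NA outside every gene).
#' @export
assign_genes <- function(variants, genes = marfan_panel_genes()) {
  gene <- rep(NA_character_, nrow(variants))
  for (g in seq_len(nrow(genes))) {
    hit <- variants$chrom == genes$chrom[g] &
      variants$pos >= genes$start[g] & variants$pos <= genes$end[g]
    gene[hit] <- genes$gene[g]
  }
  mutate(variants, gene = gene)
}

#' Compare cohort allele counts with a reference collective
#'
#' Fisher's exact test on the 2x2 table of alternate/other allele counts
#' in the cohort versus an external reference (e.g. gnomAD-style AC/AN
#' summaries); the odds ratio is the conditional maximum-likelihood
#' estimate of [stats::fisher.test()].
#'
#' @param alt_count,called_alleles Cohort alternate-allele count and total
#'   called alleles.
#' @param ref_alt_count,ref_called_alleles The same for the reference.
#' @return A tibble with `odds_ratio`, `p`, `conf_low`, `conf_high`, and a
#'   `degenerate` flag (zero margin: p = 1, OR undefined).
#' @export
compare_to_reference <- function(alt_count, called_alleles, ref_alt_count,
                                 ref_called_alleles) {
  stopifnot(length(alt_count) == length(called_alleles),
            length(ref_alt_count) == length(ref_called_alleles),
            length(alt_count) == length(ref_alt_count))
  map_dfr(seq_along(alt_count), function(i) {
    a <- alt_count[i]; n <- called_alleles[i]
    ra <- ref_alt_count[i]; rn <- ref_called_alleles[i]
    if (any(c(a, n - a, ra, rn - ra) < 0)) {
      abort("allele counts must form a valid 2x2 table")
    }
    tab <- matrix(c(a, n - a, ra, rn - ra), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      return(tibble(odds_ratio = NA_real_, p = 1, conf_low = NA_real_,
                    conf_high = NA_real_, degenerate = TRUE))
    }
    ft <- fisher.test(tab)
    tibble(odds_ratio = unname(ft$estimate), p = ft$p.value,
           conf_low = ft$conf.int[1], conf_high = ft$conf.int[2],
           degenerate = FALSE)
  })
}

#' Read a long-format reference allele-frequency table
#'
#' Tab-separated with header columns `id`, `database`, `ac`, `an`, `af`
#' (`af` computed from `ac/an` when missing).
#'
#' @param path File path.
#' @return A tibble with columns `id`, `database`, `ac`, `an`, `af`.
#' @export
read_reference_frequencies <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("id", "database") %in% names(d))) {
    abort("reference table must have columns id and database")
  }
  if (!"af" %in% names(d)) d$af <- d$ac / d$an
  d$af[is.na(d$af) & !is.na(d$ac) & !is.na(d$an)] <-
    (d$ac / d$an)[is.na(d$af) & !is.na(d$ac) & !is.na(d$an)]
  as_tibble(d)
}
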
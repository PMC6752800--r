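#' Run the full genotype-phenotype correlation pipeline
#'
#' End-to-end analysis from per-sample VCFs to the joint model
#' comparison: (1) build the coverage-aware genotype matrix and apply
#' quality control; (2) classify variants by frequency and clinical
#' class; (3) FAMD of the phenotype table and the Dim-1 carrier model;
#' (4) common-variant logistic scan with max-T correction and
#' sign-specific PRS construction; (5) rare-variant burden regressions
#' and the gene-by-sign SKAT-O scan; (6) the FBN1-only versus joint
#' path-model comparison. All report tables are written tab-separated
#' under `out_dir`.
#'
#' @param vcf_dir Directory of per-sample `.vcf` files.
#' @param bed_dir Directory of per-sample `.bed` low-coverage masks
#'   (basenames matching the VCF sample names).
#' @param pheno_path Phenotype table (see [read_phenotypes()]).
#' @param classes_path Clinical classification table (see
#'   [read_classification()]).
#' @param out_dir Output directory for the report tables.
#' @param reference_path Optional reference allele-frequency table.
#' @param n_perm max-T permutations (default 1000).
#' @param skat_resamples Bootstrap resamples per SKAT-O cell (default 0,
#'   asymptotic).
#' @param seed Integer seed for all randomized steps.
#' @param genes Panel gene table (default [marfan_panel_genes()]).
#' @return Invisibly, a list with all intermediate objects (`matrix`,
#'   `qc`, `classes`, `famd`, `carrier`, `assoc`, `prs_weights`,
#'   `prs_profiles`, `burden_overall`, `burden_by_class`, `skat_scan`,
#'   `joint`) and `tables`, the written file paths.
#' @export
run_panel_pipeline <- function(vcf_dir, bed_dir, pheno_path, classes_path,
                               out_dir, reference_path = NULL,
                               n_perm = 1000, skat_resamples = 0,
                               seed = 1L, genes = marfan_panel_genes()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcfs <- sort(list.files(vcf_dir, "\\.vcf$", full.names = TRUE))
  beds <- sort(list.files(bed_dir, "\\.bed$", full.names = TRUE))
  if (length(vcfs) == 0) abort("no VCF files found")
  masks <- read_coverage_beds(beds)

  raw <- build_genotype_matrix(vcfs, masks)
  qc <- qc_filter(raw)
  mat <- qc$matrix

  classification <- read_classification(classes_path)
  reference <- if (!is.null(reference_path))
    read_reference_frequencies(reference_path) else NULL
  classes <- classify_variants(mat, classification, reference) |>
    assign_genes(genes)

  pheno <- read_phenotypes(pheno_path) |> align_pheno(rownames(mat$calls))
  signs <- intersect(clinical_signs()$sign, names(pheno))

  famd <- fit_phenotype_famd(pheno)
  carrier <- carrier_status(mat, classes)
  carrier_fit <- carrier_logistic(famd$scores[, 1], carrier)

  assoc <- assoc_common_scan(mat, pheno, classes, signs = signs,
                             n_perm = n_perm, seed = seed)
  weights <- suppressWarnings(select_nominal(assoc))
  prs_profiles <- weights |>
    group_by(.data$sign) |>
    dplyr::group_modify(~ compute_prs(.x, mat)) |>
    ungroup()

  counts <- tibble(
    subject = rownames(mat$calls),
    n_signs = rowSums(as.matrix(pheno[signs])),
    n_rare_total = count_rare(mat, classes)$n_rare,
    n_benign = count_rare(mat, classes, clinical_filter = "benign")$n_rare,
    n_pathogenic = count_rare(mat, classes,
                              clinical_filter = "pathogenic")$n_rare,
    n_vus = count_rare(mat, classes, clinical_filter = "VUS")$n_rare,
    age = pheno$age
  )
  burden_overall <- nb_burden(counts, predictors = "n_rare_total")
  by_class_preds <- c("n_benign", "n_pathogenic", "n_vus")
  by_class_preds <- by_class_preds[vapply(by_class_preds, function(p)
    var(counts[[p]]) > 0, logical(1))]
  burden_by_class <- if (length(by_class_preds) > 0) {
    nb_burden(counts, predictors = by_class_preds)
  } else {
    burden_overall
  }

  scan <- run_gene_sign_scan(mat, pheno, classes, signs = signs,
                             resamples = skat_resamples, seed = seed)
  joint <- fit_joint_models(mat, pheno, classes, scan, prs_profiles,
                            signs = signs)

  tables <- c(
    qc_variants = "qc_variants.tsv", qc_samples = "qc_samples.tsv",
    variant_classes = "variant_classes.tsv",
    famd_eigenvalues = "famd_eigenvalues.tsv",
    famd_scores = "famd_scores.tsv",
    carrier_model = "carrier_model.tsv",
    assoc_common = "assoc_common.tsv",
    prs_weights = "prs_weights.tsv",
    prs_profiles = "prs_profiles.tsv",
    burden_overall = "burden_overall.tsv",
    burden_by_class = "burden_by_class.tsv",
    skat_scan = "skat_scan.tsv",
    model_comparison = "model_comparison.tsv"
  )
  tables <- set_names(file.path(out_dir, tables), names(tables))
  readr::write_tsv(qc$report$variants, tables["qc_variants"])
  readr::write_tsv(qc$report$samples, tables["qc_samples"])
  readr::write_tsv(classes, tables["variant_classes"])
  readr::write_tsv(tidy(famd), tables["famd_eigenvalues"])
  readr::write_tsv(
    mutate(as_tibble(famd),
           suspicion = pheno$suspicion %||% NA_character_,
           carrier = unname(carrier)),
    tables["famd_scores"])
  readr::write_tsv(tidy(carrier_fit), tables["carrier_model"])
  readr::write_tsv(assoc, tables["assoc_common"])
  readr::write_tsv(weights, tables["prs_weights"])
  readr::write_tsv(prs_profiles, tables["prs_profiles"])
  readr::write_tsv(tidy(burden_overall), tables["burden_overall"])
  readr::write_tsv(tidy(burden_by_class), tables["burden_by_class"])
  readr::write_tsv(scan, tables["skat_scan"])
  readr::write_tsv(tidy(joint$comparison), tables["model_comparison"])

  invisible(list(
    matrix = mat, qc = qc$report, classes = classes, famd = famd,
    carrier = carrier_fit, carrier_flags = carrier, assoc = assoc,
    prs_weights = weights, prs_profiles = prs_profiles,
    burden_overall = burden_overall, burden_by_class = burden_by_class,
    skat_scan = scan, joint = joint, tables = tables
  ))
}
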
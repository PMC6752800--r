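#' The Marfan-spectrum sequencing panel
#'
#' Genomic coordinates (GRCh37/hg19, 1-based inclusive) of the 11 genes
#' captured by the targeted panel the pipeline is designed around: FBN1 and
#' the TGF-beta receptors implicated in Marfan and Loeys-Dietz syndromes,
#' the fibrillar collagens of the Ehlers-Danlos spectrum, and the smooth
#' muscle genes of familial thoracic aortic aneurysm and dissection.
#'
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @examples
#' marfan_panel_genes()
#' @export
marfan_panel_genes <- function() {
  tibble(
    gene = c("FBN1", "ACTA2", "MYH11", "NOTCH1", "COL1A1", "COL1A2",
             "COL3A1", "COL5A1", "COL5A2", "TGFBR1", "TGFBR2"),
    chrom = c("chr15", "chr10", "chr16", "chr9", "chr17", "chr7",
              "chr2", "chr9", "chr2", "chr9", "chr3"),
    start = c(48700503L, 88935074L, 15703135L, 136494433L, 50183289L,
              94394561L, 188974320L, 134641774L, 189031898L, 99104038L,
              30606493L),
    end = c(48938046L, 88991390L, 15857033L, 136546048L, 50201648L,
            94431232L, 189012746L, 134844843L, 189225314L, 99154192L,
            30694142L)
  )
}

#' The fourteen binary clinical signs of the Marfan spectrum
#'
#' Sign labels (snake_case column names) and the default baseline
#' prevalences used by the synthetic cohort generator, matching the
#' frequencies observed in a published clinical cohort of 181
#' Marfan-spectrum patients.
#'
#' @return A tibble with columns `sign` and `prevalence`.
#' @export
clinical_signs <- function() {
  tibble(
    sign = c("wrist_sign", "hyperlaxity", "stretch_marks", "arachnodactyly",
             "mitral_valve_prolapse", "scoliosis", "flatfoot", "thumb_sign",
             "aortic_ectasia", "myopia", "pectus_carinatum", "ectopia_lentis",
             "aortic_dissection", "reduced_elbow_extension"),
    prevalence = c(0.624, 0.552, 0.508, 0.497, 0.475, 0.470, 0.459, 0.436,
                   0.387, 0.354, 0.182, 0.155, 0.099, 0.072)
  )
}

#' Specify a synthetic panel-sequencing cohort
#'
#' Defines the conditions under which [generate_cohort()] simulates a
#' cohort: panel composition, allele-frequency classes, clinical classes of
#' rare variants, planted genetic effects on the clinical signs, the age
#' distribution, and the fraction of calls hidden behind low coverage.
#'
#' Defaults emulate a real 181-subject Marfan-spectrum panel cohort:
#' 1273 variants across 11 genes split 361/128/784 (28/10/62%) into
#' common/low-frequency/rare classes, sign prevalences per
#' [clinical_signs()], and a lognormal age distribution with median 39.64
#' and interquartile range 28.66 years.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param genes Data frame of panel genes (`gene`, `chrom`, `start`, `end`);
#'   default [marfan_panel_genes()].
#' @param n_common,n_lowfreq,n_rare Number of variants per frequency class.
#' @param maf_ranges Named list of `c(lo, hi)` true-MAF sampling ranges per
#'   class. Must be disjoint and ordered rare < low_frequency < common.
#' @param clinical_class_probs Probabilities of benign/pathogenic/VUS among
#'   rare variants (common and low-frequency variants are emitted benign).
#' @param effect_plan Tibble with columns `target`, `sign` (a clinical
#'   sign), and `beta` (planted log-odds per allele). `target` is either a
#'   gene name (the effect acts per rare-pathogenic alternate allele in the
#'   gene), a symbolic `"GENE:class:k"` reference to the k-th variant
#'   (by descending true MAF) of
#'   that frequency class generated in the gene, or a literal variant id.
#'   `NULL` means no planted effects.
#' @param age_distribution `c(median, iqr)` of the lognormal age model.
#' @param age_beta Log-odds per year of age (applied to every sign, age
#'   centred at its median so baseline prevalences hold at the median age).
#' @param severity_sd Standard deviation of the shared latent severity
#'   factor added to every sign's liability; it induces the positive
#'   correlation among clinical signs seen in real systemic connective
#'   tissue disease (0 switches it off, making signs conditionally
#'   independent).
#' @param baseline_prevalences Named numeric vector of per-sign prevalence
#'   at zero genetic liability and median age; default [clinical_signs()].
#' @param missing_rate Fraction of calls hidden behind sub-10X coverage.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec` (a named list).
#' @examples
#' spec <- cohort_spec(n_subjects = 50, n_common = 20, n_lowfreq = 5,
#'                     n_rare = 40, seed = 1)
#' @export
cohort_spec <- function(n_subjects = 181,
                        genes = marfan_panel_genes(),
                        n_common = 361,
                        n_lowfreq = 128,
                        n_rare = 784,
                        maf_ranges = list(
                          common = c(0.05, 0.5),
                          low_frequency = c(0.01, 0.05),
                          rare = c(0.0005, 0.006)
                        ),
                        clinical_class_probs = c(benign = 0.802,
                                                 pathogenic = 0.042,
                                                 VUS = 0.156),
                        effect_plan = default_effect_plan(),
                        age_distribution = c(median = 39.64, iqr = 28.66),
                        age_beta = 0.01,
                        severity_sd = 0.8,
                        baseline_prevalences = NULL,
                        missing_rate = 0.005,
                        seed = 1L) {
  if (is.null(baseline_prevalences)) {
    baseline_prevalences <- set_names(clinical_signs()$prevalence,
                                      clinical_signs()$sign)
  }
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be at least 2")
  }
  req <- c("gene", "chrom", "start", "end")
  if (!all(req %in% names(genes))) {
    abort("`genes` must have columns gene, chrom, start, end")
  }
  for (cl in c("common", "low_frequency", "rare")) {
    r <- maf_ranges[[cl]]
    if (is.null(r) || length(r) != 2 || r[1] >= r[2] || r[1] < 0 || r[2] > 0.5) {
      abort(sprintf("`maf_ranges$%s` must be an increasing pair within [0, 0.5]", cl))
    }
  }
  if (maf_ranges$rare[2] > maf_ranges$low_frequency[1] ||
      maf_ranges$low_frequency[2] > maf_ranges$common[1]) {
    abort("`maf_ranges` must be disjoint and ordered rare < low_frequency < common")
  }
  check_probs(clinical_class_probs, "clinical_class_probs")
  if (!setequal(names(clinical_class_probs), c("benign", "pathogenic", "VUS"))) {
    abort("`clinical_class_probs` must be named benign, pathogenic, VUS")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1)")
  }
  if (any(baseline_prevalences <= 0) || any(baseline_prevalences >= 1)) {
    abort("`baseline_prevalences` must lie strictly in (0, 1)")
  }
  if (!is.null(effect_plan)) {
    effect_plan <- as_tibble(effect_plan)
    if (!all(c("target", "sign", "beta") %in% names(effect_plan))) {
      abort("`effect_plan` must have columns target, sign, beta")
    }
    bad_sign <- setdiff(effect_plan$sign,
                        c(names(baseline_prevalences), "carrier"))
    if (length(bad_sign) > 0) {
      abort(sprintf("`effect_plan` references unknown sign(s): %s",
                    paste(bad_sign, collapse = ", ")))
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    genes = as_tibble(genes),
    n_common = as.integer(n_common),
    n_lowfreq = as.integer(n_lowfreq),
    n_rare = as.integer(n_rare),
    maf_ranges = maf_ranges,
    clinical_class_probs = clinical_class_probs,
    effect_plan = effect_plan,
    age_distribution = age_distribution,
    age_beta = age_beta,
    severity_sd = severity_sd,
    baseline_prevalences = baseline_prevalences,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default planted-effect plan
#'
#' Rare pathogenic FBN1 variants drive the cardinal Marfan signs (aortic
#' ectasia, ectopia lentis, arachnodactyly, wrist sign, mitral valve
#' prolapse), and a protective common COL1A1 polymorphism acts on
#' scoliosis — the qualitative architecture a Marfan-spectrum panel study
#' expects.
#'
#' @return A tibble with columns `target`, `sign`, `beta`.
#' @export
default_effect_plan <- function() {
  tibble(
    target = c("FBN1", "FBN1", "FBN1", "FBN1", "FBN1", "COL1A1:common:1"),
    sign = c("aortic_ectasia", "ectopia_lentis", "arachnodactyly",
             "wrist_sign", "mitral_valve_prolapse", "scoliosis"),
    beta = c(1.5, 1.5, 1.2, 1.0, 1.0, -1.37)
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  subjects: %d   genes: %d\n", x$n_subjects, nrow(x$genes)))
  cat(sprintf("  variants: %d common / %d low-frequency / %d rare\n",
              x$n_common, x$n_lowfreq, x$n_rare))
  cat(sprintf("  planted effects: %d   missing rate: %.3f   seed: %d\n",
              if (is.null(x$effect_plan)) 0L else nrow(x$effect_plan),
              x$missing_rate, x$seed))
  invisible(x)
}
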
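#' Read a phenotype table
#'
#' Tab-separated with a header: a `subject` column, the binary sign
#' columns (0/1), `age` (years, > 0), a categorical `suspicion` label,
#' and optionally an integer `systemic_score`.
#'
#' @param path File path.
#' @return A tibble, validated.
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"subject" %in% names(d)) abort("phenotype table needs a 'subject' column")
  signs <- intersect(clinical_signs()$sign, names(d))
  if (length(signs) == 0) abort("phenotype table has no recognised sign columns")
  for (s in signs) {
    if (!all(d[[s]] %in% c(0, 1))) {
      abort(sprintf("sign column '%s' must be strictly binary 0/1", s))
    }
  }
  if ("age" %in% names(d) && any(d$age <= 0)) {
    abort("age must be positive")
  }
  d
}

#' Read a clinical classification table
#'
#' Tab-separated with header columns `id` (canonical variant id) and
#' `class` (benign, pathogenic, likely-pathogenic or VUS).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_classification <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("id", "class") %in% names(d))) {
    abort("classification table needs columns 'id' and 'class'")
  }
  d
}

#' Reference explained-variance comparison table
#'
#' Percentages of per-sign explained variance for the two path models
#' (FBN1-only versus joint rare-plus-common) as published for a real
#' 181-subject Marfan-spectrum panel cohort, including the
#' Ghent-criteria row. Useful as a worked example for
#' [compare_models()]: the mean increase over the 14 clinical-sign rows
#' is 11.07%.
#'
#' @return A tibble with columns `sign`, `r2_model1`, `r2_model2`.
#' @export
sem_reference_table <- function() {
  path <- system.file("extdata", "sem_explained_variance.tsv",
                      package = "genophen")
  readr::read_tsv(path, show_col_types = FALSE)
}
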
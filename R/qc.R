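#' Quality-control filtering of a genotype matrix
#'
#' Applies, in order: removal of variants whose first-quartile Phred
#' quality (over samples carrying a non-reference record with a recorded
#' QUAL) falls below `q1_phred`; removal of variants genotyped in fewer
#' than `call_rate` of samples; removal of variants failing the exact
#' Hardy-Weinberg test (computed on non-missing calls) at `hwe_alpha`;
#' then removal of samples with a missing-call fraction above
#' `sample_missing` (recomputed on the variant-filtered matrix). Calls are
#' never altered, only rows/columns removed, and every removal is logged
#' with its reason.
#'
#' Variants with no recorded quality at all (no carrier records) pass the
#' Phred filter with a warning, since per-sample VCFs only carry records
#' for non-reference calls.
#'
#' @param x A `geno_matrix` from [build_genotype_matrix()].
#' @param q1_phred Minimum first-quartile Phred score (default 30,
#'   i.e. base-calling error probability 0.001).
#' @param call_rate Minimum fraction of samples with a non-missing call
#'   (default 0.98).
#' @param hwe_alpha Significance level of the exact Hardy-Weinberg test
#'   (default 1e-3).
#' @param sample_missing Maximum per-sample missing fraction (default 0.02).
#' @return A list with elements `matrix` (the filtered `geno_matrix`) and
#'   `report` (a `qc_report`: per-variant and per-sample statistics, kept
#'   flags, reasons, and the thresholds used).
#' @export
qc_filter <- function(x, q1_phred = 30, call_rate = 0.98, hwe_alpha = 1e-3,
                      sample_missing = 0.02) {
  stopifnot(inherits(x, "geno_matrix"))
  calls <- x$calls
  m <- ncol(calls)

  q1 <- vapply(seq_len(m), function(j) {
    q <- x$qual[, j][!is.na(x$qual[, j]) & !is.na(calls[, j]) & calls[, j] > 0]
    if (length(q) == 0) NA_real_ else unname(quantile(q, 0.25))
  }, numeric(1))
  if (any(is.na(q1))) {
    warn(sprintf("%d variant(s) have no recorded quality; they pass the Phred filter",
                 sum(is.na(q1))))
  }
  cr <- colMeans(!is.na(calls))
  hwe_p <- vapply(seq_len(m), function(j) {
    g <- calls[, j][!is.na(calls[, j])]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))

  reason <- rep(NA_character_, m)
  reason[!is.na(q1) & q1 < q1_phred] <- "q1_phred"
  reason[is.na(reason) & cr < call_rate] <- "call_rate"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < hwe_alpha] <- "hwe"
  var_report <- tibble(
    id = colnames(calls), q1_phred = unname(q1), call_rate = unname(cr),
    hwe_p = unname(hwe_p), kept = is.na(reason), reason = reason
  )

  keep_v <- var_report$kept
  calls2 <- calls[, keep_v, drop = FALSE]
  miss <- unname(rowMeans(is.na(calls2)))
  samp_report <- tibble(
    sample = rownames(calls),
    missing_frac = unname(miss),
    kept = miss <= sample_missing,
    reason = ifelse(miss <= sample_missing, NA_character_,
                    "sample_missingness")
  )
  if (!any(samp_report$kept)) {
    abort("quality control removed every sample")
  }

  out <- geno_subset(x, samples = samp_report$kept, variants = keep_v)
  out$log <- c(out$log, sprintf(
    "QC: removed %d/%d variants (q1_phred<%g: %d, call_rate<%g: %d, HWE p<%g: %d) and %d/%d samples (missing>%g)",
    sum(!keep_v), m, q1_phred, sum(reason %in% "q1_phred"), call_rate,
    sum(reason %in% "call_rate"), hwe_alpha, sum(reason %in% "hwe"),
    sum(!samp_report$kept), nrow(calls), sample_missing))

  report <- structure(list(
    variants = var_report,
    samples = samp_report,
    thresholds = c(q1_phred = q1_phred, call_rate = call_rate,
                   hwe_alpha = hwe_alpha, sample_missing = sample_missing)
  ), class = "qc_report")
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  variants: %d kept / %d removed\n", sum(x$variants$kept),
              sum(!x$variants$kept)))
  cat(sprintf("  samples:  %d kept / %d removed\n", sum(x$samples$kept),
              sum(!x$samples$kept)))
  cat("  thresholds:", paste(sprintf("%s=%g", names(x$thresholds),
                                     x$thresholds), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  bind_rows(
    mutate(x$variants, unit = "variant", name = .data$id, .keep = "unused"),
    mutate(rename(x$samples, name = "sample"), unit = "sample")
  ) |>
    select("unit", "name", "kept", "reason", dplyr::everything())
}
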
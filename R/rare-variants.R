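#' Count rare variants per subject
#'
#' Site-level carrier counting: for each subject, the number of variant
#' sites (within the selected frequency and clinical classes) at which
#' the subject carries at least one alternate allele. Missing calls
#' contribute 0. The default frequency filter pools rare and
#' low-frequency variants, matching the "overall rare burden" analysis.
#'
#' @param x A `geno_matrix`.
#' @param classes Classification tibble from [classify_variants()].
#' @param freq_filter Frequency classes to include.
#' @param clinical_filter Optional clinical classes to include (default
#'   all).
#' @return Tibble: `subject`, `n_rare`.
#' @export
count_rare <- function(x, classes,
                       freq_filter = c("rare", "low_frequency"),
                       clinical_filter = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  if (length(freq_filter) == 0) abort("`freq_filter` must be non-empty")
  sel <- classes$freq_class %in% freq_filter
  if (!is.null(clinical_filter)) {
    if (length(clinical_filter) == 0) abort("`clinical_filter` must be non-empty")
    sel <- sel & classes$clinical_class %in% clinical_filter
  }
  ids <- intersect(classes$id[sel], colnames(x$calls))
  n <- if (length(ids) == 0) rep(0L, nrow(x$calls)) else
    as.integer(rowSums(x$calls[, ids, drop = FALSE] > 0, na.rm = TRUE))
  tibble(subject = rownames(x$calls), n_rare = n)
}

#' Negative-binomial burden regression
#'
#' NB2 maximum-likelihood regression (log link) of the number of positive
#' clinical manifestations on one or more rare-variant count predictors,
#' with age as covariate. The effect is reported as a rate ratio (RR) per
#' additional variant. If the NB fit does not converge (dispersion at the
#' Poisson boundary), the model falls back to Poisson with a warning.
#'
#' @param data Data frame containing the outcome, predictors and age.
#' @param outcome Name of the count outcome column (default `"n_signs"`).
#' @param predictors Character vector of predictor column names.
#' @param age_col Name of the age covariate column (`NULL` to omit).
#' @return An object of class `burden_fit`; `tidy()` gives one row per
#'   predictor with `rr`, Wald CI, `p`, and `glance()` the dispersion.
#' @export
nb_burden <- function(data, outcome = "n_signs", predictors,
                      age_col = "age") {
  stopifnot(all(c(outcome, predictors) %in% names(data)))
  if (nrow(data) < 10) abort("burden regression needs at least 10 subjects")
  for (p in predictors) {
    if (var(data[[p]]) == 0) abort(sprintf("constant predictor '%s'", p))
  }
  rhs <- c(predictors, if (!is.null(age_col)) age_col)
  form <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = data)),
    error = function(e) NULL
  )
  family_used <- "negative binomial"
  theta <- NULL
  if (is.null(fit) || !fit$converged) {
    warn("glm.nb did not converge (dispersion near the Poisson boundary); falling back to Poisson")
    fit <- glm(form, data = data, family = poisson())
    family_used <- "poisson"
  } else {
    theta <- fit$theta
  }
  est <- unname(coef(fit)[predictors])
  se <- unname(sqrt(diag(vcov(fit)))[predictors])
  res <- tibble(
    term = predictors,
    rr = exp(est),
    conf_low = exp(est - qnorm(0.975) * se),
    conf_high = exp(est + qnorm(0.975) * se),
    p = 2 * pnorm(-abs(est / se)),
    log_rr = est,
    se = se
  )
  structure(list(results = res, fit = fit, family = family_used,
                 theta = theta, n = nrow(data)), class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat(sprintf("<burden_fit> %s regression, n = %d%s\n", x$family, x$n,
              if (!is.null(x$theta)) sprintf(", dispersion theta = %.2f",
                                             x$theta) else ""))
  print(x$results)
  invisible(x)
}

#' @export
tidy.burden_fit <- function(x, ...) x$results

#' @export
glance.burden_fit <- function(x, ...) {
  tibble(n = x$n, family = x$family, theta = x$theta %||% NA_real_,
         aic = x$fit$aic)
}
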
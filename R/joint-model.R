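#' Fit a per-sign path model and report explained variance
#'
#' A system of per-sign regressions with uncorrelated residuals
#' (linear-probability convention): each binary sign, coded numeric 0/1,
#' is regressed by least squares on its predictor set, and the explained
#' variance is the coefficient of determination times 100. Collinear
#' predictors are dropped with a warning and recorded.
#'
#' @param data Data frame holding the signs and all predictors.
#' @param outcomes Character vector of sign columns.
#' @param predictors Either a character vector (same predictors for every
#'   sign) or a named list mapping each sign to its predictor columns.
#' @param label Estimator/model label stored in the fit.
#' @return An object of class `path_fit`; `tidy()` gives one row per sign
#'   with `r2_pct`.
#' @export
fit_path_model <- function(data, outcomes, predictors, label = "model") {
  pred_for <- function(s) {
    if (is.list(predictors)) predictors[[s]] %||% character(0) else predictors
  }
  rows <- map(outcomes, function(s) {
    y <- data[[s]]
    if (is.null(y)) abort(sprintf("outcome '%s' not found", s))
    if (length(unique(y[!is.na(y)])) < 2) {
      abort(sprintf("outcome '%s' has a single class", s))
    }
    preds <- pred_for(s)
    missing_p <- setdiff(preds, names(data))
    if (length(missing_p) > 0) {
      abort(sprintf("predictor(s) not found for '%s': %s", s,
                    paste(missing_p, collapse = ", ")))
    }
    if (length(preds) == 0) {
      return(list(sign = s, r2_pct = 0, fit = NULL, dropped = character(0)))
    }
    form <- as.formula(paste0("`", s, "` ~ ",
                              paste0("`", preds, "`", collapse = " + ")))
    fit <- lm(form, data = data)
    dropped <- names(coef(fit))[is.na(coef(fit))]
    if (length(dropped) > 0) {
      warn(sprintf("collinear predictor(s) dropped for '%s': %s", s,
                   paste(dropped, collapse = ", ")))
    }
    list(sign = s, r2_pct = 100 * summary(fit)$r.squared, fit = fit,
         dropped = dropped)
  })
  structure(list(
    results = tibble(sign = map_chr(rows, "sign"),
                     r2_pct = map_dbl(rows, "r2_pct"),
                     n_dropped = map_int(rows, ~ length(.x$dropped))),
    fits = set_names(map(rows, "fit"), outcomes),
    label = label, n = nrow(data)
  ), class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("<path_fit> '%s', %d signs, n = %d\n", x$label,
              nrow(x$results), x$n))
  print(x$results)
  invisible(x)
}

#' @export
tidy.path_fit <- function(x, ...) mutate(x$results, model = x$label)

#' @export
glance.path_fit <- function(x, ...) {
  tibble(model = x$label, n = x$n, n_signs = nrow(x$results),
         mean_r2_pct = mean(x$results$r2_pct))
}

#' Compare explained variance between two path models
#'
#' Per-sign difference in explained-variance percentage (model 2 minus
#' model 1), the mean increase over the clinical signs, and a two-sided
#' paired t-test on the differences. A Ghent-criteria row, when present,
#' is excluded from the mean by default (configurable and reported).
#'
#' @param fit1,fit2 `path_fit` objects (or tibbles with `sign` and
#'   `r2_pct`) over the same sign list.
#' @param include_ghent Include a `ghent_positivity` row in the mean and
#'   test.
#' @param ghent_label Name of the Ghent row.
#' @return An object of class `model_comparison` with the per-sign
#'   deltas, `mean_increase` and `p_paired`.
#' @export
compare_models <- function(fit1, fit2, include_ghent = FALSE,
                           ghent_label = "ghent_positivity") {
  t1 <- if (inherits(fit1, "path_fit")) fit1$results else as_tibble(fit1)
  t2 <- if (inherits(fit2, "path_fit")) fit2$results else as_tibble(fit2)
  if (!setequal(t1$sign, t2$sign) || nrow(t1) != nrow(t2)) {
    abort("the two fits must cover the same sign list")
  }
  d <- inner_join(select(t1, "sign", r2_model1 = "r2_pct"),
                  select(t2, "sign", r2_model2 = "r2_pct"), by = "sign") |>
    mutate(delta = .data$r2_model2 - .data$r2_model1,
           included = include_ghent | .data$sign != ghent_label)
  inc <- filter(d, .data$included)
  if (nrow(inc) < 2) abort("need at least two signs to compare")
  if (sd(inc$delta) == 0) {
    warn("identical explained variances in both models; paired test degenerate")
    p <- 1
  } else {
    p <- t.test(inc$delta)$p.value
  }
  structure(list(
    table = d,
    mean_increase = mean(inc$delta),
    p_paired = p,
    include_ghent = include_ghent,
    n_signs = nrow(inc)
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "<model_comparison> mean explained-variance increase %.2f%% over %d signs (paired p = %.3g)%s\n",
    x$mean_increase, x$n_signs, x$p_paired,
    if (x$include_ghent) " [Ghent row included]" else ""))
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) x$table

#' @export
glance.model_comparison <- function(x, ...) {
  tibble(mean_increase = x$mean_increase, p_paired = x$p_paired,
         n_signs = x$n_signs, include_ghent = x$include_ghent)
}

#' Operational Ghent-2010 positivity flag
#'
#' A simplified, rule-table version of the revised Ghent nosology
#' restricted to the fields available here: positive when the aortic
#' criterion (aortic ectasia or dissection) combines with ectopia
#' lentis, or with a systemic score of at least `score_threshold`, or
#' when ectopia lentis combines with a systemic score at threshold.
#'
#' @param aortic Logical/0-1: aortic criterion present.
#' @param ectopia Logical/0-1: ectopia lentis present.
#' @param systemic_score Integer systemic feature score.
#' @param score_threshold Systemic-score cutoff (default 7).
#' @return Integer 0/1 vector; NA inputs give NA with a warning.
#' @export
ghent_positivity <- function(aortic, ectopia, systemic_score,
                             score_threshold = 7) {
  if (anyNA(aortic) || anyNA(ectopia) || anyNA(systemic_score)) {
    warn("missing fields: Ghent positivity undefined for those subjects")
  }
  a <- as.logical(aortic)
  e <- as.logical(ectopia)
  s <- systemic_score >= score_threshold
  as.integer((a & e) | (a & s) | (e & s))
}

#' Joint rare-plus-common model comparison on a cohort
#'
#' Builds and compares the two genotype-phenotype path models: Model 1
#' (age + FBN1 pathogenic and VUS rare-variant counts, emulating a
#' classic FBN1-only association study) and Model 2 (Model 1's
#' predictors plus the per-gene rare-variant counts of gene/class cells
#' significant in the SKAT-O scan for that sign, plus the sign-specific
#' PRS). Model 2 always nests Model 1 so its explained variance can only
#' grow.
#'
#' @param x QC-filtered `geno_matrix`.
#' @param pheno Phenotype tibble.
#' @param classes Classification tibble (with `gene`).
#' @param scan SKAT-O scan results from [run_gene_sign_scan()].
#' @param prs_profiles Tibble `sign`, `subject`, `prs` (e.g. built from
#'   [select_nominal()] + [compute_prs()] per sign); may omit signs.
#' @param signs Signs to model (default all present).
#' @param scan_alpha Unadjusted p threshold selecting scan cells
#'   (default 0.05).
#' @param include_ghent Add a Ghent-positivity endogenous row.
#' @return A list with `fit1`, `fit2` (`path_fit`) and `comparison`
#'   (`model_comparison`).
#' @export
fit_joint_models <- function(x, pheno, classes, scan, prs_profiles,
                             signs = NULL, scan_alpha = 0.05,
                             include_ghent = TRUE) {
  signs <- signs %||% intersect(clinical_signs()$sign, names(pheno))
  pheno <- align_pheno(pheno, rownames(x$calls))
  d <- as.data.frame(pheno)

  # FBN1 pathogenic / VUS rare counts (Model 1 predictors)
  fbn1 <- filter(classes, !is.na(.data$gene), .data$gene == "FBN1")
  d$fbn1_pathogenic <- count_rare(x, fbn1, clinical_filter = "pathogenic")$n_rare
  d$fbn1_vus <- count_rare(x, fbn1, clinical_filter = "VUS")$n_rare
  m1_base <- c("fbn1_pathogenic", "fbn1_vus")
  m1_preds <- c("age", m1_base[vapply(m1_base, function(p)
    var(d[[p]]) > 0, logical(1))])

  # per-gene/class rare counts for scan-significant cells, per sign
  sig <- filter(scan, !is.na(.data$p_optimal), .data$p_optimal < scan_alpha)
  gene_count_col <- function(gene, stratum) {
    col <- paste0("n_", tolower(gene), "_", tolower(stratum))
    if (!col %in% names(d)) {
      gc <- filter(classes, !is.na(.data$gene), .data$gene == gene)
      d[[col]] <<- count_rare(x, gc, clinical_filter = stratum)$n_rare
    }
    col
  }
  m2_preds <- set_names(map(signs, function(s) {
    extra <- character(0)
    cells <- filter(sig, .data$sign == s)
    if (nrow(cells) > 0) {
      extra <- map_chr(seq_len(nrow(cells)), function(i)
        gene_count_col(cells$gene[i], cells$stratum[i]))
    }
    prs_col <- paste0("prs_", s)
    psub <- filter(prs_profiles, .data$sign == s)
    if (nrow(psub) > 0) {
      d[[prs_col]] <<- psub$prs[match(pheno$subject, psub$subject)]
      extra <- c(extra, prs_col)
    }
    unique(c(m1_preds, extra))
  }), signs)

  outcomes <- signs
  if (include_ghent) {
    d$ghent_positivity <- ghent_positivity(
      pmax(d$aortic_ectasia, d$aortic_dissection),
      d$ectopia_lentis, d$systemic_score)
    outcomes <- c(signs, "ghent_positivity")
    m2_preds$ghent_positivity <- unique(c(
      m1_preds, unlist(m2_preds[signs], use.names = FALSE)))
  }
  fit1 <- fit_path_model(d, outcomes, m1_preds, label = "model1_fbn1_only")
  fit2 <- fit_path_model(d, outcomes, m2_preds, label = "model2_joint")
  list(fit1 = fit1, fit2 = fit2,
       comparison = compare_models(fit1, fit2, include_ghent = FALSE))
}
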
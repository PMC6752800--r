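#' Single-variant logistic association
#'
#' Additive-dosage maximum-likelihood logistic regression of one binary
#' clinical sign on one variant's alternate-allele dosage, adjusted for
#' covariates (in the panel pipeline: age and the per-subject counts of
#' benign, pathogenic and VUS rare variants). The p-value is the Wald
#' test of the dosage coefficient.
#'
#' @param outcome 0/1 vector (both classes required).
#' @param dosage 0/1/2 alternate-allele dosage vector.
#' @param covariates Optional data frame of covariates.
#' @return One-row tibble: `beta`, `se`, `or`, `p_unadjusted`,
#'   `converged`.
#' @export
single_variant_logistic <- function(outcome, dosage, covariates = NULL) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("outcome must have both classes present")
  }
  df <- data.frame(.y = y, .g = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  converged <- fit$converged && all(abs(coef(fit)) < 20, na.rm = TRUE) &&
    !is.na(coef(fit)[".g"])
  if (!converged) {
    return(tibble(beta = NA_real_, se = NA_real_, or = NA_real_,
                  p_unadjusted = NA_real_, converged = FALSE))
  }
  beta <- coef(fit)[[".g"]]
  se <- sqrt(diag(vcov(fit)))[[".g"]]
  tibble(beta = beta, se = se, or = exp(beta),
         p_unadjusted = 2 * pnorm(-abs(beta / se)), converged = TRUE)
}

# Rao score statistics of all variant columns of G for outcome y under the
# null logistic model with design X (mu, w precomputed from the null fit)
score_stats_null <- function(r, w, G, X, XtWX_inv = NULL) {
  U <- drop(crossprod(G, r))
  WX <- X * w
  if (is.null(XtWX_inv)) XtWX_inv <- solve(crossprod(X, WX))
  XtWG <- crossprod(WX, G)
  V <- colSums(G * G * w) - colSums(XtWG * (XtWX_inv %*% XtWG))
  U / sqrt(pmax(V, .Machine$double.eps))
}

#' Max-T permutation adjustment across a variant family
#'
#' Single-step family-wise error control in the Westfall-Young style used
#' by plink's `mperm`: outcome labels are permuted across subjects (the
#' covariates staying attached to their subjects), all per-variant tests
#' are recomputed per permutation, and the maximum absolute statistic
#' over the family is recorded. The adjusted p-value of variant v is
#' `(1 + #\{perm max >= |t_v|\}) / (n_perm + 1)`; the pointwise
#' permutation p (`p_perm`) uses the variant's own permuted statistics
#' and is never above `p_maxT`.
#'
#' Per-variant statistics are Rao score tests of the dosage under the
#' covariate-only null model, recomputed identically for the observed and
#' every permuted outcome.
#'
#' @param outcome 0/1 outcome vector.
#' @param dosages Subject x variant dosage matrix (no missing values;
#'   mean-impute first).
#' @param covariates Optional data frame of covariates.
#' @param n_perm Number of random permutations (>= 1).
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all distinct label arrangements instead of
#'   sampling (feasible only for small cohorts); p-values are then exact
#'   proportions over the full permutation distribution.
#' @return Tibble: `id`, `stat`, `p_perm`, `p_maxT`.
#' @export
maxt_adjust <- function(outcome, dosages, covariates = NULL, n_perm = 1000,
                        seed = NULL, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 1) abort("`n_perm` must be at least 1")
  y <- as.integer(outcome)
  G <- as.matrix(dosages)
  if (anyNA(G)) abort("`dosages` must not contain missing values")
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (!is.null(seed)) set.seed(seed)

  obs <- abs(perm_score(y, G, X))
  if (exhaustive) {
    k <- sum(y)
    idx <- utils::combn(n, k)
    B <- ncol(idx)
    stat <- matrix(0, B, ncol(G))
    for (b in seq_len(B)) {
      yb <- integer(n)
      yb[idx[, b]] <- 1L
      stat[b, ] <- abs(perm_score(yb, G, X))
    }
    maxs <- apply(stat, 1, max)
    p_perm <- map_dbl(seq_len(ncol(G)),
                      function(j) mean(stat[, j] >= obs[j] - 1e-12))
    p_maxT <- map_dbl(seq_len(ncol(G)),
                      function(j) mean(maxs >= obs[j] - 1e-12))
  } else {
    stat <- matrix(0, n_perm, ncol(G))
    for (b in seq_len(n_perm)) {
      stat[b, ] <- abs(perm_score(sample(y), G, X))
    }
    maxs <- apply(stat, 1, max)
    p_perm <- map_dbl(seq_len(ncol(G)), function(j)
      (1 + sum(stat[, j] >= obs[j] - 1e-12)) / (n_perm + 1))
    p_maxT <- map_dbl(seq_len(ncol(G)), function(j)
      (1 + sum(maxs >= obs[j] - 1e-12)) / (n_perm + 1))
  }
  tibble(id = colnames(G) %||% paste0("V", seq_len(ncol(G))),
         stat = obs, p_perm = p_perm, p_maxT = p_maxT)
}

# fit the covariate-only null for a given outcome and return score stats
perm_score <- function(y, G, X) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  w <- pmax(mu * (1 - mu), 1e-12)
  score_stats_null(y - mu, w, G, X)
}

#' Scan all common variants against all clinical signs
#'
#' For each sign, fits the covariate-adjusted logistic model of
#' [single_variant_logistic()] for every common variant, then applies
#' [maxt_adjust()] within the sign's variant family. Covariates are age
#' and the per-subject counts of benign, pathogenic and VUS rare (and
#' low-frequency) variants, computed panel-wide.
#'
#' @param x QC-filtered `geno_matrix`.
#' @param pheno Phenotype tibble (subjects must match the matrix rows).
#' @param classes Variant classification from [classify_variants()].
#' @param signs Character vector of sign columns (default: all present).
#' @param n_perm Permutations for the max-T correction.
#' @param seed Integer seed for the permutations.
#' @return Tibble: one row per sign x common variant with `beta`, `se`,
#'   `or`, `p_unadjusted`, `stat`, `p_perm`, `p_maxT`.
#' @export
assoc_common_scan <- function(x, pheno, classes, signs = NULL,
                              n_perm = 1000, seed = 1L) {
  stopifnot(inherits(x, "geno_matrix"))
  signs <- signs %||% intersect(clinical_signs()$sign, names(pheno))
  pheno <- align_pheno(pheno, rownames(x$calls))
  covars <- rare_count_covariates(x, classes, age = pheno$age)
  common_ids <- classes$id[classes$freq_class == "common"]
  common_ids <- intersect(common_ids, colnames(x$calls))
  if (length(common_ids) == 0) {
    abort("no common variants to test")
  }
  G <- mean_impute(x$calls[, common_ids, drop = FALSE])

  map_dfr(signs, function(s) {
    y <- pheno[[s]]
    if (length(unique(y)) < 2) {
      return(tibble(sign = s, id = common_ids, beta = NA_real_,
                    se = NA_real_, or = NA_real_, p_unadjusted = NA_real_,
                    converged = FALSE, stat = NA_real_, p_perm = NA_real_,
                    p_maxT = NA_real_))
    }
    fits <- map_dfr(common_ids, function(v)
      single_variant_logistic(y, G[, v], covars))
    mt <- maxt_adjust(y, G, covars, n_perm = n_perm, seed = seed)
    bind_cols(tibble(sign = s, id = common_ids), fits,
              select(mt, "stat", "p_perm", "p_maxT"))
  })
}

# age + per-clinical-class rare/low-frequency variant counts
rare_count_covariates <- function(x, classes, age) {
  data.frame(
    age = age,
    n_benign = count_rare(x, classes, clinical_filter = "benign")$n_rare,
    n_pathogenic = count_rare(x, classes, clinical_filter = "pathogenic")$n_rare,
    n_vus = count_rare(x, classes, clinical_filter = "VUS")$n_rare
  )
}

align_pheno <- function(pheno, samples) {
  if (!"subject" %in% names(pheno)) {
    if (nrow(pheno) != length(samples)) {
      abort("phenotype table does not match the genotype matrix samples")
    }
    return(pheno)
  }
  idx <- match(samples, pheno$subject)
  if (anyNA(idx)) {
    abort(sprintf("phenotypes missing for sample(s): %s",
                  paste(head(samples[is.na(idx)], 5), collapse = ", ")))
  }
  pheno[idx, ]
}

mean_impute <- function(G) {
  nas <- which(is.na(G), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mns <- colMeans(G, na.rm = TRUE)
    G[nas] <- mns[nas[, 2]]
  }
  G
}

#' Select nominally associated variants and build PRS weights
#'
#' Keeps, per sign, the variants with unadjusted p below `alpha` and
#' weights each by `beta / SE(beta)`, so variants with more precisely
#' estimated effects weigh more. The effect allele is the alternate
#' allele counted by the genotype matrix.
#'
#' @param results Association table from [assoc_common_scan()].
#' @param alpha Nominal selection threshold (default 0.05).
#' @return Tibble of PRS weights: `sign`, `id`, `effect_allele`, `beta`,
#'   `se`, `weight`. Signs with no selected variant are absent (warned).
#' @export
select_nominal <- function(results, alpha = 0.05) {
  sel <- filter(results, .data$converged, !is.na(.data$p_unadjusted),
                .data$p_unadjusted < alpha)
  empty <- setdiff(unique(results$sign), unique(sel$sign))
  if (length(empty) > 0) {
    warn(sprintf("no nominally associated variants for sign(s): %s (PRS undefined)",
                 paste(empty, collapse = ", ")))
  }
  sel |>
    mutate(effect_allele = parse_variant_id(.data$id)$alt,
           weight = .data$beta / .data$se) |>
    select("sign", "id", "effect_allele", "beta", "se", "weight")
}

#' Compute polygenic risk scores
#'
#' `PRS_i = sum_j w_j g_ji` over the selected variants, with `g` the
#' number of effect (alternate) alleles. Missing dosages are imputed with
#' the variant's mean dosage (default) or the variant is dropped for that
#' subject (`impute = "drop"`, i.e. dosage 0); imputations are counted
#' per subject.
#'
#' @param weights One sign's PRS weights (rows of [select_nominal()]).
#' @param x A `geno_matrix`, or a subject x variant dosage matrix.
#' @param impute `"mean"` or `"drop"`.
#' @return Tibble: `subject`, `prs`, `n_imputed`.
#' @export
compute_prs <- function(weights, x, impute = c("mean", "drop")) {
  impute <- match.arg(impute)
  if (nrow(weights) == 0) abort("`weights` must contain at least one variant")
  G <- if (inherits(x, "geno_matrix")) x$calls else as.matrix(x)
  missing_ids <- setdiff(weights$id, colnames(G))
  if (length(missing_ids) > 0) {
    abort(sprintf("variant(s) in weights absent from the matrix: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  G <- G[, weights$id, drop = FALSE]
  n_imp <- rowSums(is.na(G))
  if (impute == "mean") {
    G <- mean_impute(G)
  } else {
    G[is.na(G)] <- 0
  }
  tibble(subject = rownames(G) %||% as.character(seq_len(nrow(G))),
         prs = unname(drop(G %*% weights$weight)),
         n_imputed = as.integer(n_imp))
}
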
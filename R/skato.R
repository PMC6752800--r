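#' Optimal sequence kernel association test (SKAT-O)
#'
#' Gene-level rare-variant association of a binary trait. The statistic
#' `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` interpolates between the
#' variance-component kernel statistic (rho = 0) and the weighted burden
#' statistic (rho = 1); each `Q_rho` is a quadratic form in the score
#' residuals of the null logistic model `outcome ~ covariates`, whose
#' tail is a mixture of one-degree chi-squares evaluated by moment
#' matching (Liu-type, default) or by Imhof numerical integration. The
#' optimal p-value is that of the minimum per-rho p over the grid,
#' computed by the one-dimensional integral over the common burden
#' component. An optional parametric bootstrap (resampling outcomes from
#' the fitted null) gives an empirical p-value
#' `(1 + #\{resample p <= observed p\}) / (R + 1)`.
#'
#' Variant weights default to the Beta(1, 25) density of the observed
#' MAF, upweighting rarer variants; equal weights with rho = 1 reduce to
#' an unweighted allele-count burden test.
#'
#' @param genotypes Subject x variant dosage matrix of the gene's rare
#'   variants (missing calls are mean-imputed).
#' @param outcome 0/1 trait vector (both classes required).
#' @param covariates Optional data frame of covariates for the null
#'   model.
#' @param weights Per-variant weights; default `dbeta(MAF, 1, 25)`.
#' @param rho_grid Grid of rho values; default `(0, 0.1^2, ..., 0.9^2, 1)`.
#' @param method Tail approximation for the chi-square mixtures:
#'   `"liu"` (moment matching) or `"imhof"` (numerical integration).
#' @param resamples Number of bootstrap resamples (0 = asymptotic only).
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `skat_fit`: `p_optimal`, per-rho p-values
#'   and statistics, `n_variants`, the weights and method used, and
#'   (when `resamples > 0`) the bootstrap p-value.
#' @export
skat_o <- function(genotypes, outcome, covariates = NULL, weights = NULL,
                   rho_grid = ((0:10) / 10)^2, method = c("liu", "imhof"),
                   resamples = 0, seed = NULL) {
  method <- match.arg(method)
  G <- as.matrix(genotypes)
  if (ncol(G) < 1) abort("at least one variant is required")
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) abort("outcome must have both classes present")
  G <- mean_impute(G)
  n <- nrow(G)
  X <- cbind(rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))

  if (is.null(weights)) {
    maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
    weights <- dbeta(maf, 1, 25)
  }
  stopifnot(length(weights) == ncol(G), all(is.finite(weights)))

  null <- fit_skat_null(y, X)
  core <- skato_core(null, G, X, weights, rho_grid, method)

  boot <- NULL
  if (resamples > 0) {
    if (!is.null(seed)) set.seed(seed)
    pstar <- numeric(resamples)
    used <- 0L
    for (b in seq_len(resamples)) {
      yb <- rbinom(n, 1L, null$mu)
      if (length(unique(yb)) < 2) {
        pstar[b] <- NA_real_
        next
      }
      nb <- fit_skat_null(yb, X)
      pstar[b] <- skato_core(nb, G, X, weights, rho_grid, method)$p_optimal
      used <- used + 1L
    }
    pstar <- pstar[!is.na(pstar)]
    boot <- list(
      p_bootstrap = (1 + sum(pstar <= core$p_optimal)) / (length(pstar) + 1),
      n_resamples = length(pstar)
    )
  }
  structure(c(core, list(
    n_variants = ncol(G), weights = weights, method = method,
    n = n, bootstrap = boot
  )), class = "skat_fit")
}

fit_skat_null <- function(y, X) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  if (!fit$converged || any(mu < 1e-10 | mu > 1 - 1e-10)) {
    # separation in the null model: penalized fallback, flagged
    warn("separation in SKAT-O null model; using Firth-type penalized fit")
    ff <- firth_logistic(X, y)
    mu <- plogis(drop(X %*% ff$coef))
  }
  list(mu = mu, r = y - mu, w = pmax(mu * (1 - mu), 1e-12))
}

# core SKAT-O computation given a fitted null model
skato_core <- function(null, G, X, weights, rho_grid, method) {
  Z <- sweep(G, 2, weights, `*`)
  m <- ncol(Z)
  S <- drop(crossprod(Z, null$r))
  q_skat <- sum(S^2)
  q_burden <- sum(S)^2
  Q_rho <- (1 - rho_grid) * q_skat + rho_grid * q_burden

  # K = Z' P0 Z under the null working weights
  WZ <- Z * null$w
  WX <- X * null$w
  XtWX_inv <- solve(crossprod(X, WX))
  XtWZ <- crossprod(WX, Z)
  K <- crossprod(Z, WZ) - crossprod(XtWZ, XtWX_inv %*% XtWZ)

  p_rho <- map_dbl(seq_along(rho_grid), function(i) {
    lam <- lambda_rho(K, rho_grid[i])
    if (length(lam) == 0) return(NA_real_)
    qf_pvalue(Q_rho[i], lam, method)
  })
  if (all(is.na(p_rho))) abort("no genotype variation among the variants tested")
  pmin_obs <- min(p_rho, na.rm = TRUE)

  if (m == 1 || length(rho_grid) == 1) {
    return(list(p_optimal = pmin_obs, rho_grid = rho_grid, p_rho = p_rho,
                Q_rho = Q_rho))
  }
  p_opt <- skato_optimal_p(K, rho_grid, p_rho, pmin_obs, method)
  list(p_optimal = p_opt, rho_grid = rho_grid, p_rho = p_rho, Q_rho = Q_rho)
}

# eigenvalues of R_rho^{1/2} K R_rho^{1/2} with R_rho = (1-rho)I + rho J
lambda_rho <- function(K, rho) {
  m <- ncol(K)
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  Rh <- diag(a, m) + matrix(b, m, m)
  B <- Rh %*% K %*% Rh
  lam <- eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam[lam > max(lam, 0) * 1e-10 & lam > 0]
}

# p-value of the minimum-p statistic over the rho grid (Lee et al. style
# one-dimensional integration over the shared burden chi-square)
skato_optimal_p <- function(K, rho_grid, p_rho, pmin_obs, method) {
  m <- ncol(K)
  u <- colSums(K) / m          # z-bar' z_j
  s <- sum(K) / m^2            # z-bar' z-bar
  if (s <= max(diag(K)) * 1e-12) {
    # burden direction carries no information; minimum-p is the answer
    return(pmin_obs)
  }
  Kadj <- K - tcrossprod(u) / s
  lam <- eigen((Kadj + t(Kadj)) / 2, symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > max(lam, 0) * 1e-10 & lam > 0]
  if (length(lam) == 0) return(pmin_obs)

  MuQ <- sum(lam)
  var_remain <- max(0, 4 * (drop(crossprod(u, K %*% u)) - sum(u^2)^2 / s) / s)
  VarQ <- 2 * sum(lam^2) + var_remain
  Df <- sum(lam^2)^2 / sum(lam^4)
  tau <- m^2 * rho_grid * s + (1 - rho_grid) * sum(u^2) / s

  # per-rho quantiles of Q_rho at the observed minimum p
  qmin <- map_dbl(seq_along(rho_grid), function(i) {
    lam_i <- lambda_rho(K, rho_grid[i])
    liu_quantile(pmin_obs, lam_i)
  })

  r_cap <- pmin(rho_grid, 0.999)
  integrand <- function(x) {
    tmp <- vapply(x, function(xx)
      min((qmin - tau * xx) / (1 - r_cap)), numeric(1))
    q <- (tmp - MuQ) / sqrt(VarQ) * sqrt(2 * Df) + Df
    pchisq(q, df = Df) * dchisq(x, df = 1)
  }
  int <- tryCatch(
    integrate(integrand, 0, 40, subdivisions = 2000, abs.tol = 1e-25),
    error = function(e) NULL
  )
  if (is.null(int)) return(min(1, pmin_obs * length(rho_grid)))
  p <- 1 - int$value
  # guard against approximation undershoot; Bonferroni cap over the grid
  min(max(p, pmin_obs), min(1, pmin_obs * length(rho_grid)))
}

# Liu-type moment-matched quantile of a chi-square mixture at upper-tail
# probability p
liu_quantile <- function(p, lambda) {
  pr <- liu_params(lambda)
  q <- qchisq(p, df = pr$l, ncp = pr$d, lower.tail = FALSE)
  (q - pr$muX) / pr$sigmaX * pr$sigmaQ + pr$muQ
}

liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), muX = l + d,
       sigmaX = sqrt(2) * a, l = l, d = d)
}

#' Upper-tail probability of a mixture of chi-squared(1) variables
#'
#' `P(sum_k lambda_k chi2_1 > q)` by Liu-type moment matching (default)
#' or Imhof's exact numerical integration.
#'
#' @param q Observed statistic.
#' @param lambda Positive mixture coefficients.
#' @param method `"liu"` or `"imhof"`.
#' @return Upper-tail probability in (0, 1].
#' @export
qf_pvalue <- function(q, lambda, method = c("liu", "imhof")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0) abort("at least one positive eigenvalue required")
  if (method == "liu") {
    pr <- liu_params(lambda)
    stat <- (q - pr$muQ) / pr$sigmaQ * pr$sigmaX + pr$muX
    p <- pchisq(stat, df = pr$l, ncp = pr$d, lower.tail = FALSE)
  } else {
    theta <- function(x) {
      vapply(x, function(u)
        0.5 * sum(atan(lambda * u)) - 0.5 * q * u, numeric(1))
    }
    rho_f <- function(x) {
      vapply(x, function(u) prod((1 + lambda^2 * u^2)^0.25), numeric(1))
    }
    int <- integrate(function(u) sin(theta(u)) / (u * rho_f(u)),
                     0, Inf, subdivisions = 5000, rel.tol = 1e-10,
                     stop.on.error = FALSE)
    p <- 0.5 + int$value / pi
  }
  min(max(p, 1e-300), 1)
}

#' @export
print.skat_fit <- function(x, ...) {
  cat(sprintf("<skat_fit> %d variants, n = %d, p_optimal = %.4g (%s)\n",
              x$n_variants, x$n, x$p_optimal, x$method))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap p = %.4g (%d resamples)\n",
                x$bootstrap$p_bootstrap, x$bootstrap$n_resamples))
  }
  invisible(x)
}

#' @export
tidy.skat_fit <- function(x, ...) {
  tibble(rho = x$rho_grid, Q = x$Q_rho, p = x$p_rho)
}

#' @export
glance.skat_fit <- function(x, ...) {
  tibble(p_optimal = x$p_optimal, n = x$n, n_variants = x$n_variants,
         method = x$method,
         p_bootstrap = if (!is.null(x$bootstrap))
           x$bootstrap$p_bootstrap else NA_real_)
}

#' Gene-by-sign SKAT-O scan over clinical-class strata
#'
#' One SKAT-O test per (gene x clinical sign x clinical-class stratum)
#' cell: the gene's variants of that clinical class with MAF at or below
#' `maf_cutoff` are tested against the sign, with age and the
#' per-subject counts of the other clinical classes as covariates. No
#' multiple-testing correction is applied (the scan is exploratory with
#' pre-planned complementary outcomes); unadjusted p-values are reported
#' with their stratum labels. Cells with no variants after the MAF
#' filter, or a degenerate outcome, yield NA with a reason.
#'
#' @param x QC-filtered `geno_matrix`.
#' @param pheno Phenotype tibble.
#' @param classes Classification tibble from [classify_variants()] (with
#'   a `gene` column, see [assign_genes()]).
#' @param signs Sign columns to test (default all present).
#' @param strata Clinical-class strata (default pathogenic, VUS, benign).
#' @param maf_cutoff Variants above this MAF are removed before testing.
#' @param resamples Bootstrap resamples per cell (0 = asymptotic).
#' @param method Tail method, see [skat_o()].
#' @param seed Seed for bootstrap resampling.
#' @return Long tibble: `gene`, `sign`, `stratum`, `p_optimal`,
#'   `p_bootstrap`, `n_variants`, `reason` (NA when tested).
#' @export
run_gene_sign_scan <- function(x, pheno, classes, signs = NULL,
                               strata = c("pathogenic", "VUS", "benign"),
                               maf_cutoff = 0.05, resamples = 0,
                               method = "liu", seed = 1L) {
  stopifnot(inherits(x, "geno_matrix"))
  signs <- signs %||% intersect(clinical_signs()$sign, names(pheno))
  pheno <- align_pheno(pheno, rownames(x$calls))
  genes <- sort(unique(na.omit(classes$gene)))
  counts <- map(c("benign", "pathogenic", "VUS"), function(cl)
    count_rare(x, classes, clinical_filter = cl)$n_rare)
  names(counts) <- c("benign", "pathogenic", "VUS")

  grid <- tidyr::expand_grid(gene = genes, sign = signs, stratum = strata)
  pmap(grid, function(gene, sign, stratum) {
    ids <- classes$id[!is.na(classes$gene) & classes$gene == gene &
                        classes$clinical_class == stratum &
                        !is.na(classes$maf) & classes$maf <= maf_cutoff]
    ids <- intersect(ids, colnames(x$calls))
    base <- tibble(gene = gene, sign = sign, stratum = stratum,
                   p_optimal = NA_real_, p_bootstrap = NA_real_,
                   n_variants = length(ids), reason = NA_character_)
    if (length(ids) == 0) {
      base$reason <- "no variants after MAF filter"
      return(base)
    }
    y <- pheno[[sign]]
    if (length(unique(y)) < 2) {
      base$reason <- "outcome has a single class"
      return(base)
    }
    others <- setdiff(c("benign", "pathogenic", "VUS"), stratum)
    covs <- data.frame(age = pheno$age,
                       counts[[others[1]]], counts[[others[2]]])
    names(covs) <- c("age", paste0("n_", others))
    fit <- tryCatch(
      skat_o(x$calls[, ids, drop = FALSE], y, covariates = covs,
             resamples = resamples, method = method, seed = seed),
      error = function(e) NULL)
    if (is.null(fit)) {
      base$reason <- "test failed"
      return(base)
    }
    base$p_optimal <- fit$p_optimal
    if (!is.null(fit$bootstrap)) {
      base$p_bootstrap <- fit$bootstrap$p_bootstrap
    }
    base
  }) |> list_rbind()
}
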
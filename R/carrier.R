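#' Predict pathogenic-variant carriage from the first FAMD dimension
#'
#' Maximum-likelihood logistic regression of carrier status (at least one
#' rare pathogenic variant in the configured gene set, by default FBN1,
#' TGFBR1 and TGFBR2) on the Dim 1 score. Because lower Dim 1 means a
#' more Marfan-like phenotype, the effect is reported as the odds ratio
#' per unit *decrease* of Dim 1 (the coefficient negated), with a Wald
#' 95% confidence interval. Complete or quasi-complete separation is
#' detected and handled by a Firth-type penalized-likelihood refit,
#' flagged prominently.
#'
#' @param dim1_scores Numeric vector of Dim 1 subject scores.
#' @param carrier_flags Logical/0-1 vector of carrier status.
#' @param conf_level Confidence level for the Wald interval.
#' @return An object of class `carrier_fit` with the fitted coefficient
#'   and SE, `or_per_unit_decrease`, its confidence interval, and the
#'   fitting method (`"ml"` or `"firth"`).
#' @export
carrier_logistic <- function(dim1_scores, carrier_flags, conf_level = 0.95) {
  y <- as.integer(carrier_flags)
  stopifnot(length(y) == length(dim1_scores))
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("no outcome variation: both carrier classes must be present")
  }
  keep <- !is.na(y) & !is.na(dim1_scores)
  y <- y[keep]
  x <- dim1_scores[keep]

  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  mu <- fit$fitted.values
  separated <- !fit$converged || any(mu < 1e-8 | mu > 1 - 1e-8) ||
    any(abs(coef(fit)) > 15)
  if (separated) {
    warn("separation detected in carrier model; using Firth-type penalized likelihood")
    ff <- firth_logistic(cbind(1, x), y)
    beta <- ff$coef[2]
    se <- ff$se[2]
    method <- "firth"
  } else {
    beta <- coef(fit)[["x"]]
    se <- sqrt(diag(vcov(fit)))[["x"]]
    method <- "ml"
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- sort(exp(-c(beta - z * se, beta + z * se)))
  structure(list(
    coefficient = beta, se = se,
    or_per_unit_decrease = exp(-beta),
    conf_low = ci[1], conf_high = ci[2],
    conf_level = conf_level, method = method, n = length(y),
    n_carriers = sum(y)
  ), class = "carrier_fit")
}

#' @export
print.carrier_fit <- function(x, ...) {
  cat(sprintf(
    "<carrier_fit> OR per unit decrease of Dim 1 = %.3f (%d%% CI %.3f-%.3f), %s fit, n = %d (%d carriers)\n",
    x$or_per_unit_decrease, round(100 * x$conf_level), x$conf_low,
    x$conf_high, x$method, x$n, x$n_carriers))
  invisible(x)
}

#' @export
tidy.carrier_fit <- function(x, ...) {
  tibble(term = "dim1_decrease", estimate = x$or_per_unit_decrease,
         coefficient = x$coefficient, std.error = x$se,
         conf.low = x$conf_low, conf.high = x$conf_high)
}

#' @export
glance.carrier_fit <- function(x, ...) {
  tibble(n = x$n, n_carriers = x$n_carriers, method = x$method,
         or_per_unit_decrease = x$or_per_unit_decrease)
}

# Firth-type penalized logistic regression (Jeffreys-prior score
# correction): score U* = X'(y - mu + h(0.5 - mu)) with h the hat values
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    inv <- solve(info)
    h <- rowSums((X %*% inv) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(inv %*% U)
    # step-halving for stability
    step <- 1
    while (max(abs(step * delta)) > 5) step <- step / 2
    beta <- beta + step * delta
    if (max(abs(delta)) < tol) break
  }
  list(coef = beta, se = sqrt(diag(solve(info))), iterations = it)
}

#' Flag carriers of rare pathogenic variants in a gene set
#'
#' @param x A `geno_matrix`.
#' @param classes Variant classification tibble from [classify_variants()]
#'   (needs `id`, `freq_class`, `clinical_class`, `gene`).
#' @param genes Gene set defining carriage (default the Marfan main genes).
#' @return Named logical vector, one element per sample.
#' @export
carrier_status <- function(x, classes,
                           genes = c("FBN1", "TGFBR1", "TGFBR2")) {
  stopifnot(inherits(x, "geno_matrix"))
  sel <- classes$id[classes$gene %in% genes &
                      classes$clinical_class == "pathogenic" &
                      classes$freq_class == "rare"]
  sel <- intersect(sel, colnames(x$calls))
  if (length(sel) == 0) {
    return(set_names(rep(FALSE, nrow(x$calls)), rownames(x$calls)))
  }
  rowSums(x$calls[, sel, drop = FALSE] > 0, na.rm = TRUE) > 0
}
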
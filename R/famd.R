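#' Factor analysis of mixed data (FAMD)
#'
#' Principal-axes factorization of a table mixing quantitative and
#' categorical variables. Quantitative columns are standardized to mean 0
#' and unit variance; each observed level of a categorical variable
#' becomes an indicator column divided by the square root of its
#' proportion and then centred — so quantitative variables enter PCA-like
#' and categorical variables MCA-like, each variable carrying comparable
#' inertia. The combined matrix is decomposed by SVD with uniform row
#' weights; eigenvalue k is the squared singular value divided by `n - 1`
#' (convention recorded in the model), so an all-quantitative table
#' reproduces correlation-matrix PCA exactly.
#'
#' @param data A data frame; numeric columns are treated as quantitative,
#'   everything else (factor, character, logical) as categorical.
#' @param n_dims Number of dimensions to keep (capped at the rank).
#' @return An object of class `famd`: eigenvalues, percent variance,
#'   subject coordinates (mean 0 on every dimension), variable
#'   coordinates (correlation loadings for quantitative variables,
#'   category centroids for levels), preprocessing parameters, and the
#'   orientation sign per dimension.
#' @examples
#' d <- data.frame(x = rnorm(20), g = sample(c("a", "b"), 20, TRUE))
#' fit <- famd_fit(d, n_dims = 2)
#' fit$percent_variance
#' @export
famd_fit <- function(data, n_dims = 5) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n < 2) abort("FAMD needs at least 2 subjects")
  if (ncol(data) < 1) abort("FAMD needs at least one variable")

  is_quant <- vapply(data, is.numeric, logical(1))
  blocks <- list()
  col_var <- character(0)
  col_level <- character(0)
  means <- list(); sds <- list(); props <- list()

  for (v in names(data)) {
    x <- data[[v]]
    if (is_quant[[v]]) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) {
        abort(sprintf("quantitative column '%s' is constant", v))
      }
      means[[v]] <- mean(x)
      sds[[v]] <- s
      blocks[[v]] <- matrix((x - mean(x)) / s, ncol = 1)
      col_var <- c(col_var, v)
      col_level <- c(col_level, NA_character_)
    } else {
      f <- droplevels(as.factor(x))
      if (nlevels(f) < 2) {
        abort(sprintf("categorical column '%s' has fewer than 2 observed levels", v))
      }
      p <- as.numeric(table(f)) / n
      ind <- vapply(levels(f), function(l) as.numeric(f == l), numeric(n))
      z <- sweep(ind, 2, p, `-`)
      z <- sweep(z, 2, sqrt(p), `/`)
      props[[v]] <- set_names(p, levels(f))
      blocks[[v]] <- z
      col_var <- c(col_var, rep(v, nlevels(f)))
      col_level <- c(col_level, levels(f))
    }
  }
  M <- do.call(cbind, blocks)
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r == 0) abort("preprocessed matrix has rank 0")
  eig <- sv$d[seq_len(r)]^2 / (n - 1)
  ndk <- min(n_dims, r)

  scores <- sv$u[, seq_len(ndk), drop = FALSE] %*%
    diag(sv$d[seq_len(ndk)], ndk)
  colnames(scores) <- paste0("Dim", seq_len(ndk))
  rownames(scores) <- rownames(data)

  # variable coordinates: quantitative loadings are correlations with the
  # components; categorical levels get their subject-centroid coordinate
  loadings <- sv$v[, seq_len(ndk), drop = FALSE] %*%
    diag(sv$d[seq_len(ndk)] / sqrt(n - 1), ndk)
  var_coords <- map_dfr(seq_along(col_var), function(j) {
    if (is.na(col_level[j])) {
      tibble(variable = col_var[j], level = NA_character_,
             dim = seq_len(ndk), coord = loadings[j, ])
    } else {
      rows <- data[[col_var[j]]] == col_level[j]
      tibble(variable = col_var[j], level = col_level[j],
             dim = seq_len(ndk), coord = colMeans(scores[rows, , drop = FALSE]))
    }
  })

  structure(list(
    eigenvalues = eig,
    percent_variance = 100 * eig / sum(eig),
    scores = scores,
    var_coords = var_coords,
    n = n,
    n_dims = ndk,
    scaling = "n-1",
    orientation = rep(1, ndk),
    preprocessing = list(means = means, sds = sds, proportions = props),
    total_inertia = sum(eig),
    data = data
  ), class = "famd")
}

#' @export
print.famd <- function(x, ...) {
  cat(sprintf("<famd> %d subjects, %d dimensions kept (of rank %d)\n",
              x$n, x$n_dims, length(x$eigenvalues)))
  cat("  eigenvalues: ",
      paste(sprintf("%.3f (%.1f%%)", head(x$eigenvalues, x$n_dims),
                    head(x$percent_variance, x$n_dims)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.famd <- function(x, ...) {
  tibble(dim = seq_along(x$eigenvalues),
         eigenvalue = x$eigenvalues,
         percent_variance = x$percent_variance,
         cumulative = cumsum(x$percent_variance))
}

#' @export
glance.famd <- function(x, ...) {
  tibble(n = x$n, n_dims = x$n_dims, rank = length(x$eigenvalues),
         total_inertia = x$total_inertia,
         pct_dim1 = x$percent_variance[1],
         pct_dim2 = if (length(x$percent_variance) > 1)
           x$percent_variance[2] else NA_real_)
}

#' Subject coordinates of a FAMD fit as a tibble
#'
#' @param x A `famd` object.
#' @param ... Unused.
#' @return A tibble with `subject` and one column per kept dimension.
#' @export
as_tibble.famd <- function(x, ...) {
  bind_cols(tibble(subject = rownames(x$scores) %||%
                     as.character(seq_len(x$n))),
            as_tibble(x$scores))
}

#' Orient a FAMD dimension against an anchor category
#'
#' Factor axes are sign-indeterminate; this fixes a dimension's sign so
#' that a chosen anchor category (or quantitative variable) points in the
#' requested direction. The conventional anchor puts "ectopia lentis
#' present" — the most Marfan-specific sign — on the negative side of
#' Dim 1, so that more Marfan-like subjects have lower Dim 1 scores.
#'
#' @param model A `famd` fit.
#' @param dim Dimension to orient (default 1).
#' @param anchor `"variable=level"` for a category (or just the variable
#'   name for a quantitative column).
#' @param direction `"negative"` or `"positive"`.
#' @return The model, with the dimension flipped if needed; eigenvalues
#'   and absolute coordinates are unchanged.
#' @export
orient_dimension <- function(model, dim = 1,
                             anchor = "ectopia_lentis=present",
                             direction = c("negative", "positive")) {
  stopifnot(inherits(model, "famd"))
  direction <- match.arg(direction)
  if (grepl("=", anchor, fixed = TRUE)) {
    parts <- strsplit(anchor, "=", fixed = TRUE)[[1]]
    row <- model$var_coords$variable == parts[1] &
      !is.na(model$var_coords$level) & model$var_coords$level == parts[2] &
      model$var_coords$dim == dim
  } else {
    row <- model$var_coords$variable == anchor &
      is.na(model$var_coords$level) & model$var_coords$dim == dim
  }
  if (!any(row)) abort(sprintf("anchor '%s' not found in the model", anchor))
  coord <- model$var_coords$coord[row][1]
  if (coord == 0) {
    warn("anchor coordinate is exactly 0; orientation unchanged")
    return(model)
  }
  want_neg <- direction == "negative"
  if ((coord < 0) == want_neg) return(model)
  model$scores[, dim] <- -model$scores[, dim]
  flip <- model$var_coords$dim == dim
  model$var_coords$coord[flip] <- -model$var_coords$coord[flip]
  model$orientation[dim] <- -model$orientation[dim]
  model
}

#' FAMD of a Marfan-spectrum phenotype table
#'
#' Prepares the phenotype table for [famd_fit()]: the fourteen binary
#' signs become two-level categorical variables (`absent`/`present`), age
#' stays active quantitative (configurable), and the clinical-suspicion
#' label and systemic score are excluded from the factorization (kept
#' only for display). Dim 1 is then oriented so that "ectopia lentis
#' present" is negative.
#'
#' @param pheno Phenotype tibble as produced by [generate_cohort()] or
#'   [read_phenotypes()].
#' @param n_dims Dimensions to keep.
#' @param include_age Include age as an active quantitative variable.
#' @return A `famd` fit (Dim 1 oriented).
#' @export
fit_phenotype_famd <- function(pheno, n_dims = 5, include_age = TRUE) {
  signs <- intersect(clinical_signs()$sign, names(pheno))
  if (length(signs) == 0) abort("no clinical sign columns found")
  d <- as.data.frame(pheno[signs])
  for (s in signs) {
    d[[s]] <- factor(ifelse(d[[s]] == 1, "present", "absent"),
                     levels = c("absent", "present"))
  }
  if (include_age && "age" %in% names(pheno)) d$age <- pheno$age
  rownames(d) <- pheno$subject %||% NULL
  fit <- famd_fit(d, n_dims = n_dims)
  anchor <- if ("ectopia_lentis" %in% signs) "ectopia_lentis=present" else
    paste0(signs[1], "=present")
  orient_dimension(fit, 1, anchor, "negative")
}
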
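test_that("FAMD on an all-quantitative table equals correlation-matrix PCA", {
  set.seed(101)
  X <- as.data.frame(matrix(rnorm(35 * 6), 35, 6))
  fit <- famd_fit(X, n_dims = 6)
  expect_equal(fit$eigenvalues, eigen(cor(X))$values, tolerance = 1e-8)
  # subject coordinates are centred and their variance equals the eigenvalue
  expect_lt(max(abs(colMeans(fit$scores))), 1e-8)
  expect_equal(unname(apply(fit$scores, 2, var)), fit$eigenvalues[1:6],
               tolerance = 1e-8)
})

test_that("two identical standardized variables put 100% of variance on Dim 1", {
  set.seed(5)
  x <- rnorm(25)
  fit <- famd_fit(data.frame(a = x, b = 2 * x + 3), n_dims = 2)
  expect_equal(fit$percent_variance[1], 100)
  expect_length(fit$eigenvalues, 1) # rank 1
})

test_that("mixed 8x3 toy table matches an explicit eigendecomposition oracle", {
  d <- data.frame(
    x = c(1.2, -0.5, 0.3, 2.1, -1.4, 0.8, -0.2, 1.0),
    g = factor(c("a", "b", "a", "c", "b", "a", "c", "b")),
    h = factor(c("u", "u", "v", "v", "u", "v", "u", "v")))
  fit <- famd_fit(d, n_dims = 5)
  # oracle: build the preprocessed matrix by hand and eigendecompose
  n <- 8
  xs <- (d$x - mean(d$x)) / sd(d$x)
  blk <- function(f) {
    p <- table(f) / n
    sapply(levels(f), function(l) ((f == l) - p[[l]]) / sqrt(p[[l]]))
  }
  M <- cbind(xs, blk(d$g), blk(d$h))
  ev <- eigen(crossprod(M) / (n - 1), symmetric = TRUE)$values
  ev <- ev[ev > 1e-10]
  expect_equal(fit$eigenvalues, ev, tolerance = 1e-10)
  # total inertia conservation
  expect_equal(sum(fit$eigenvalues), sum(M^2) / (n - 1), tolerance = 1e-10)
  expect_equal(sum(fit$percent_variance), 100, tolerance = 1e-8)
})

test_that("FAMD is invariant to row order and category relabeling", {
  set.seed(77)
  d <- data.frame(x = rnorm(30), y = rnorm(30),
                  g = sample(c("low", "mid", "high"), 30, replace = TRUE))
  f1 <- famd_fit(d, 3)
  perm <- sample(30)
  f2 <- famd_fit(d[perm, ], 3)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(f1$scores[perm, ]), abs(f2$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  d3 <- d
  d3$g <- factor(d3$g, levels = c("low", "mid", "high"),
                 labels = c("L", "M", "H"))
  f3 <- famd_fit(d3, 3)
  expect_equal(f1$eigenvalues, f3$eigenvalues, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with the column named", {
  expect_error(famd_fit(data.frame(x = rep(1, 10), y = rnorm(10))),
               "'x' is constant")
  expect_error(famd_fit(data.frame(g = factor(rep("a", 10)), y = rnorm(10))),
               "fewer than 2")
  expect_error(famd_fit(data.frame(x = 1)), "at least 2 subjects")
})

test_that("orientation flips signs only, is idempotent, and preserves eigenvalues", {
  set.seed(13)
  d <- data.frame(x = rnorm(40),
                  ectopia_lentis = factor(sample(c("absent", "present"),
                                                 40, TRUE)))
  fit <- famd_fit(d, 2)
  o1 <- orient_dimension(fit, 1, "ectopia_lentis=present", "negative")
  o2 <- orient_dimension(o1, 1, "ectopia_lentis=present", "negative")
  expect_identical(o1$scores, o2$scores) # idempotent
  coord <- o1$var_coords$coord[o1$var_coords$level %in% "present" &
                                 o1$var_coords$dim == 1]
  expect_lt(coord[1], 0)
  flipped <- orient_dimension(fit, 1, "ectopia_lentis=present", "positive")
  expect_equal(flipped$scores[, 1], -o1$scores[, 1])
  expect_equal(flipped$scores[, 2], o1$scores[, 2]) # other dims untouched
  expect_equal(flipped$eigenvalues, o1$eigenvalues)
  expect_equal(abs(flipped$var_coords$coord), abs(o1$var_coords$coord))
  expect_error(orient_dimension(fit, 1, "nope=present"), "not found")
})

test_that("the carrier logistic model matches a likelihood grid-search oracle", {
  dim1 <- c(-2.1, -1.3, -0.4, 0.2, 1.1, 1.9)
  carrier <- c(1, 1, 1, 0, 1, 0)
  fit <- carrier_logistic(dim1, carrier)
  oracle <- logistic_grid_oracle(carrier, dim1, c(-3, 3), c(-4, 2))
  expect_equal(fit$coefficient, unname(oracle[2]), tolerance = 1e-3)
  expect_equal(fit$or_per_unit_decrease, exp(-unname(oracle[2])),
               tolerance = 1e-3)
  # CI brackets the OR
  expect_lt(fit$conf_low, fit$or_per_unit_decrease)
  expect_gt(fit$conf_high, fit$or_per_unit_decrease)
})

test_that("carrier model handles degenerate and separated data", {
  expect_error(carrier_logistic(rnorm(10), rep(1, 10)), "no outcome variation")
  # complete separation triggers the penalized fallback
  x <- c(-3, -2.5, -2, -1.5, 1.5, 2, 2.5, 3)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(carrier_logistic(x, y), "Firth")
  fit <- suppressWarnings(carrier_logistic(x, y))
  expect_equal(fit$method, "firth")
  expect_true(is.finite(fit$coefficient) && is.finite(fit$se))
  expect_gt(fit$or_per_unit_decrease, 1)
})

test_that("carrier status independent of Dim 1 gives OR near 1 at large n", {
  set.seed(201)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, 0.3)
  fit <- carrier_logistic(x, y)
  expect_gt(fit$or_per_unit_decrease, 0.9)
  expect_lt(fit$or_per_unit_decrease, 1.1)
})

test_that("phenotype FAMD treats signs as categorical and orients Dim 1", {
  co <- generate_cohort(small_spec(n_subjects = 120, seed = 55))
  fit <- fit_phenotype_famd(co$phenotypes)
  lev <- fit$var_coords$coord[fit$var_coords$variable == "ectopia_lentis" &
                                fit$var_coords$level %in% "present" &
                                fit$var_coords$dim == 1]
  expect_lt(lev, 0)
  # age active quantitative by default; suspicion excluded
  expect_true("age" %in% fit$var_coords$variable)
  expect_false("suspicion" %in% fit$var_coords$variable)
  # binary signs enter as two-level categoricals (absent/present rows)
  expect_true(all(c("absent", "present") %in%
                    fit$var_coords$level[fit$var_coords$variable == "wrist_sign"]))
})

test_that("recovered Dim-1 carrier association is directionally consistent under planted severity", {
  # carriers get a liability shift on five signs; the fitted OR per unit
  # decrease of Dim 1 should exceed 1 in nearly all replicates
  hits <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    plan <- default_effect_plan()[1:5, ]
    plan$beta <- 2
    co <- generate_cohort(cohort_spec(
      n_subjects = 500, n_common = 20, n_lowfreq = 10, n_rare = 150,
      clinical_class_probs = c(benign = 0.5, pathogenic = 0.3, VUS = 0.2),
      maf_ranges = list(common = c(0.05, 0.5),
                        low_frequency = c(0.01, 0.05),
                        rare = c(0.004, 0.009)),
      effect_plan = plan, seed = 300 + r))
    carrier <- genophen:::carrier_dosage(co$variants, co$genotypes,
                                         c("FBN1", "TGFBR1", "TGFBR2")) > 0
    if (sum(carrier) < 5) next
    fam <- fit_phenotype_famd(co$phenotypes)
    fit <- carrier_logistic(fam$scores[, 1], carrier)
    if (fit$or_per_unit_decrease > 1) hits <- hits + 1
  }
  expect_gte(hits, reps - 1)
})
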
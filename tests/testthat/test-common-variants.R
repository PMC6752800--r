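test_that("single-variant logistic matches a likelihood grid-search oracle", {
  g <- c(0, 1, 2, 0, 1, 0, 2, 1)
  y <- c(0, 1, 1, 0, 0, 1, 1, 0)
  fit <- single_variant_logistic(y, g)
  oracle <- logistic_grid_oracle(y, g, c(-5, 5), c(-5, 5))
  expect_equal(fit$beta, unname(oracle[2]), tolerance = 1e-3)
  expect_equal(fit$or, exp(fit$beta))
  expect_error(single_variant_logistic(rep(1, 8), g), "both classes")
})

test_that("a planted common-variant effect is recovered within its 95% CI", {
  set.seed(61)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  age <- rlnorm(n, log(40), 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * g + 0.005 * (age - 40)))
  fit <- single_variant_logistic(y, g, data.frame(age = age))
  expect_lt(fit$beta - 1.96 * fit$se, 0.5)
  expect_gt(fit$beta + 1.96 * fit$se, 0.5)
})

test_that("null single-variant p-values are approximately uniform", {
  set.seed(62)
  ps <- replicate(300, {
    g <- rbinom(400, 2, runif(1, 0.1, 0.4))
    y <- rbinom(400, 1, 0.4)
    single_variant_logistic(y, g)$p_unadjusted
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("max-T with a single variant collapses to its own permutation p", {
  set.seed(63)
  g <- matrix(rbinom(40, 2, 0.3), 40, 1, dimnames = list(NULL, "v1"))
  y <- rbinom(40, 1, 0.5)
  mt <- maxt_adjust(y, g, n_perm = 300, seed = 4)
  expect_equal(mt$p_maxT, mt$p_perm)
})

test_that("exhaustive max-T equals a naive full-enumeration oracle", {
  set.seed(64)
  G <- cbind(a = c(0, 1, 2, 0, 1, 1, 0),
             b = c(2, 1, 0, 0, 1, 0, 1),
             c = c(1, 0, 1, 2, 0, 1, 0))
  y <- c(1, 1, 1, 0, 0, 0, 0)
  mt <- maxt_adjust(y, G, exhaustive = TRUE)
  idx <- utils::combn(7, 3)
  st <- sapply(seq_len(ncol(idx)), function(b) {
    yy <- integer(7); yy[idx[, b]] <- 1L
    abs(vapply(1:3, function(j) naive_score_stat(yy, G[, j]), numeric(1)))
  })
  obs <- abs(vapply(1:3, function(j) naive_score_stat(y, G[, j]), numeric(1)))
  maxs <- apply(st, 2, max)
  expect_equal(mt$p_maxT,
               vapply(1:3, function(j) mean(maxs >= obs[j] - 1e-12),
                      numeric(1)))
  expect_equal(mt$p_perm,
               vapply(1:3, function(j) mean(st[j, ] >= obs[j] - 1e-12),
                      numeric(1)))
})

test_that("max-T p-values dominate pointwise permutation p-values and grow with the family", {
  set.seed(65)
  n <- 60
  G <- sapply(runif(5, 0.1, 0.4), function(f) rbinom(n, 2, f))
  colnames(G) <- paste0("v", 1:5)
  y <- rbinom(n, 1, 0.5)
  mt <- maxt_adjust(y, G, n_perm = 400, seed = 9)
  expect_true(all(mt$p_maxT >= mt$p_perm))
  # adding an uncorrelated variant never decreases existing p_maxT
  G2 <- cbind(G, v6 = rbinom(n, 2, 0.25))
  mt2 <- maxt_adjust(y, G2, n_perm = 400, seed = 9)
  expect_true(all(mt2$p_maxT[1:5] >= mt$p_maxT))
  expect_error(maxt_adjust(y, G, n_perm = 0), "n_perm")
})

test_that("nominal selection filters at alpha and weights by beta over SE", {
  res <- tibble::tibble(
    sign = "scoliosis",
    id = c("chr1-1-A-T", "chr1-2-A-T", "chr1-3-A-T"),
    beta = c(0.693, -0.4, 1.1), se = c(0.347, 0.2, 0.8),
    p_unadjusted = c(0.04, 0.06, 0.03), converged = TRUE)
  w <- select_nominal(res)
  expect_equal(nrow(w), 2) # 0.04 and 0.03 kept, 0.06 dropped
  expect_equal(w$weight[w$id == "chr1-1-A-T"], 0.693 / 0.347)
  expect_equal(w$weight[w$id == "chr1-1-A-T"], 2, tolerance = 0.01)
  expect_equal(w$effect_allele, c("T", "T"))
  # selection equals a brute-force filter on random tables
  set.seed(66)
  res2 <- tibble::tibble(
    sign = sample(c("a_sign", "b_sign"), 50, TRUE),
    id = paste0("chr2-", 1:50, "-A-G"),
    beta = rnorm(50), se = runif(50, 0.1, 1),
    p_unadjusted = runif(50), converged = sample(c(TRUE, FALSE), 50, TRUE,
                                                 c(0.9, 0.1)))
  w2 <- suppressWarnings(select_nominal(res2, alpha = 0.2))
  manual <- res2[res2$converged & res2$p_unadjusted < 0.2, ]
  expect_setequal(w2$id, manual$id)
  expect_equal(w2$weight, manual$beta / manual$se)
})

test_that("PRS is the weighted dosage sum with mean imputation counted", {
  w <- tibble::tibble(sign = "s", id = c("chr1-1-A-T", "chr1-2-A-G"),
                      effect_allele = c("T", "G"), beta = c(1, -1),
                      se = c(0.5, 1), weight = c(2, -1))
  G <- matrix(c(1, 0, 2, 2, 0, NA), 3, 2,
              dimnames = list(paste0("S", 1:3),
                              c("chr1-1-A-T", "chr1-2-A-G")))
  prs <- compute_prs(w, G)
  # S1: 2*1 + (-1)*2 = 0 ; S2: 0*2 + 0*(-1) = 0
  expect_equal(prs$prs[1:2], c(0, 0))
  # S3 imputed with mean dosage of variant 2 over observed = 1
  expect_equal(prs$prs[3], 2 * 2 - 1 * 1)
  expect_equal(prs$n_imputed, c(0L, 0L, 1L))
  # drop mode scores missing as zero
  prs0 <- compute_prs(w, G, impute = "drop")
  expect_equal(prs0$prs[3], 4)
  expect_error(compute_prs(w[0, ], G), "at least one")
  expect_error(
    compute_prs(dplyr::mutate(w, id = c("chr1-1-A-T", "chr9-9-A-G")), G),
    "chr9-9-A-G")
})

test_that("PRS equals a naive double loop and is additive over weight subsets", {
  set.seed(67)
  m <- 12; n <- 20
  ids <- paste0("chr5-", 1:m, "-A-C")
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(paste0("S", 1:n), ids))
  w <- tibble::tibble(sign = "s", id = ids, effect_allele = "C",
                      beta = rnorm(m), se = runif(m, 0.2, 1))
  w$weight <- w$beta / w$se
  prs <- compute_prs(w, G)
  naive <- numeric(n)
  for (i in 1:n) for (j in 1:m) naive[i] <- naive[i] + w$weight[j] * G[i, j]
  expect_equal(prs$prs, naive)
  # additivity over disjoint weight subsets
  p1 <- compute_prs(w[1:5, ], G)$prs
  p2 <- compute_prs(w[6:m, ], G)$prs
  expect_equal(p1 + p2, prs$prs)
  # flipping the effect allele (g -> 2 - g, w -> -w) shifts all scores
  # by a constant, leaving differences unchanged
  Gf <- 2 - G
  wf <- dplyr::mutate(w, weight = -weight)
  pf <- compute_prs(wf, Gf)$prs
  expect_equal(diff(pf), diff(prs$prs), tolerance = 1e-12)
})

test_that("the common-variant scan ties the pieces together on a synthetic cohort", {
  co <- generate_cohort(small_spec(n_subjects = 80, n_common = 8,
                                   n_lowfreq = 3, n_rare = 20, seed = 91))
  d <- withr::local_tempdir()
  m <- build_genotype_matrix(emit_vcfs(co, file.path(d, "v")),
                             read_coverage_beds(
                               emit_coverage_beds(co, file.path(d, "b"))))
  cls <- classify_variants(m, co$classification) |> assign_genes()
  res <- assoc_common_scan(m, co$phenotypes, cls,
                           signs = c("scoliosis", "myopia"),
                           n_perm = 100, seed = 2)
  n_common <- sum(cls$freq_class == "common")
  expect_equal(nrow(res), 2 * n_common)
  ok <- res[res$converged, ]
  expect_true(all(ok$p_unadjusted > 0 & ok$p_unadjusted <= 1))
  expect_true(all(ok$p_maxT >= ok$p_perm))
  expect_equal(ok$or, exp(ok$beta))
})
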
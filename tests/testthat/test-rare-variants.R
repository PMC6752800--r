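test_that("rare-variant counting is site-level carrier counting", {
  ids <- c("chr1-1-A-T", "chr1-2-A-T", "chr1-3-A-T", "chr1-4-A-T")
  calls <- rbind(S1 = c(0L, 0L, 0L, 0L),
                 S2 = c(1L, 1L, 2L, 0L),
                 S3 = c(NA, 1L, 0L, 2L))
  colnames(calls) <- ids
  x <- genophen:::new_geno_matrix(
    calls, calls * 0L + 100L, calls * 0 + 60,
    parse_variant_id(ids), "fixture")
  cls <- tibble::tibble(
    id = ids,
    freq_class = c("rare", "rare", "rare", "common"),
    clinical_class = c("pathogenic", "VUS", "benign", "benign"))
  # hom-ref everywhere -> 0; het at 2 rare + hom-alt at 1 -> 3 sites
  cnt <- count_rare(x, cls, freq_filter = "rare")
  expect_equal(cnt$n_rare, c(0L, 3L, 1L))
  # missing calls contribute 0; clinical filter restricts
  expect_equal(count_rare(x, cls, freq_filter = "rare",
                          clinical_filter = "pathogenic")$n_rare,
               c(0L, 1L, 0L))
  expect_error(count_rare(x, cls, freq_filter = character(0)), "non-empty")
})

test_that("cohort rare counts equal a brute-force recount oracle", {
  co <- generate_cohort(small_spec(n_subjects = 40, seed = 71))
  d <- withr::local_tempdir()
  m <- build_genotype_matrix(emit_vcfs(co, file.path(d, "v")),
                             read_coverage_beds(
                               emit_coverage_beds(co, file.path(d, "b"))))
  cls <- classify_variants(m, co$classification)
  cnt <- count_rare(m, cls)
  sel <- cls$id[cls$freq_class %in% c("rare", "low_frequency")]
  for (i in seq_len(nrow(m$calls))) {
    manual <- sum(m$calls[i, sel] > 0, na.rm = TRUE)
    expect_equal(cnt$n_rare[i], manual)
  }
})

test_that("negative-binomial burden recovers a planted log rate ratio", {
  set.seed(72)
  n <- 1000
  x <- rpois(n, 2)
  age <- rlnorm(n, log(40), 0.4)
  mu <- exp(0.3 + 0.4 * x + 0.002 * (age - 40))
  y <- rnbinom(n, size = 8, mu = mu)
  fit <- nb_burden(tibble::tibble(n_signs = y, n_pathogenic = x, age = age),
                   predictors = "n_pathogenic")
  res <- tidy(fit)
  expect_lt(res$conf_low, exp(0.4))
  expect_gt(res$conf_high, exp(0.4))
  expect_equal(res$rr, exp(res$log_rr))
})

test_that("null burden regressions center on RR 1 with nominal type-I error", {
  set.seed(73)
  reps <- 120
  hits <- 0; rrs <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- tibble::tibble(n_signs = rpois(150, 4), n_rare_total = rpois(150, 6),
                        age = rlnorm(150, log(40), 0.4))
    res <- tidy(suppressWarnings(
      nb_burden(d, predictors = "n_rare_total")))
    rrs[r] <- res$rr
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_equal(mean(log(rrs)), 0, tolerance = 0.02)
  expect_lt(hits / reps, 0.12)
})

test_that("degenerate burden inputs error cleanly", {
  d <- tibble::tibble(n_signs = rpois(30, 3), n_pathogenic = 0, age = 40)
  expect_error(nb_burden(d, predictors = "n_pathogenic"), "constant predictor")
  expect_error(nb_burden(d[1:5, ], predictors = "n_pathogenic"), "at least 10")
})

test_that("SKAT-O with one variant collapses to the score test", {
  set.seed(74)
  n <- 150
  g <- matrix(rbinom(n, 2, 0.03), n, 1)
  age <- rnorm(n, 40, 10)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * g[, 1]))
  fit <- skat_o(g, y, covariates = data.frame(age = age))
  z <- naive_score_stat(y, g[, 1] * fit$weights, cbind(age))
  expect_equal(fit$p_optimal, pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("rho = 1 SKAT-O equals the weighted burden score test", {
  set.seed(75)
  n <- 200; m <- 7
  G <- sapply(runif(m, 0.01, 0.04), function(f) rbinom(n, 2, f))
  y <- rbinom(n, 1, 0.35)
  age <- rnorm(n, 45, 12)
  w <- dbeta(pmin(colMeans(G) / 2, 1 - colMeans(G) / 2), 1, 25)
  fit <- skat_o(G, y, covariates = data.frame(age = age), rho_grid = 1,
                weights = w)
  z <- naive_score_stat(y, drop(G %*% w), cbind(age))
  expect_equal(fit$p_rho[1], pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # equal weights with rho = 1 reduce to the unweighted allele-count burden
  fit_eq <- skat_o(G, y, covariates = data.frame(age = age), rho_grid = 1,
                   weights = rep(1, m))
  z_eq <- naive_score_stat(y, rowSums(G), cbind(age))
  expect_equal(fit_eq$p_rho[1], pchisq(z_eq^2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("Q_rho interpolates monotonically between the SKAT and burden statistics", {
  set.seed(76)
  n <- 100; m <- 5
  G <- sapply(runif(m, 0.02, 0.05), function(f) rbinom(n, 2, f))
  y <- rbinom(n, 1, 0.4)
  fit <- skat_o(G, y)
  q_skat <- fit$Q_rho[fit$rho_grid == 0]
  q_burden <- fit$Q_rho[fit$rho_grid == 1]
  expect_equal(fit$Q_rho, (1 - fit$rho_grid) * q_skat +
                 fit$rho_grid * q_burden)
  expect_true(all(diff(fit$Q_rho) * sign(q_burden - q_skat) >= 0))
  # p_optimal is bounded by the minimum per-rho p and its Bonferroni cap
  expect_gte(fit$p_optimal, min(fit$p_rho) - 1e-12)
  expect_lte(fit$p_optimal, min(1, min(fit$p_rho) * length(fit$rho_grid)))
})

test_that("Liu and Imhof tail methods agree on chi-square mixtures", {
  lambda <- c(3.2, 1.4, 0.7, 0.2)
  # oracle: a plain chi-square when all weights are equal
  expect_equal(qf_pvalue(7.8, rep(2, 3)), pchisq(3.9, 3, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(qf_pvalue(7.8, rep(2, 3), method = "imhof"),
               pchisq(3.9, 3, lower.tail = FALSE), tolerance = 1e-6)
  # the two approximations agree in the moderate tail (absolute scale)
  for (q in c(2, 6, 12, 20)) {
    expect_lt(abs(qf_pvalue(q, lambda) - qf_pvalue(q, lambda, "imhof")),
              0.015)
  }
})

test_that("bootstrap p-values agree with asymptotic p on null data", {
  set.seed(78)
  n <- 120; m <- 6
  G <- sapply(runif(m, 0.02, 0.05), function(f) rbinom(n, 2, f))
  y <- rbinom(n, 1, 0.5)
  fit <- skat_o(G, y, resamples = 400, seed = 5)
  pb <- fit$bootstrap$p_bootstrap
  mc_se <- sqrt(fit$p_optimal * (1 - fit$p_optimal) /
                  fit$bootstrap$n_resamples)
  expect_lt(abs(pb - fit$p_optimal), 4 * mc_se + 0.02)
})

test_that("the gene-by-sign scan labels strata and flags empty cells", {
  plan <- tibble::tibble(target = "FBN1", sign = "aortic_ectasia", beta = 2.5)
  co <- generate_cohort(cohort_spec(
    n_subjects = 150, n_common = 10, n_lowfreq = 5, n_rare = 120,
    clinical_class_probs = c(benign = 0.4, pathogenic = 0.3, VUS = 0.3),
    maf_ranges = list(common = c(0.05, 0.5), low_frequency = c(0.01, 0.05),
                      rare = c(0.004, 0.009)),
    effect_plan = plan, seed = 79))
  d <- withr::local_tempdir()
  m <- build_genotype_matrix(emit_vcfs(co, file.path(d, "v")),
                             read_coverage_beds(
                               emit_coverage_beds(co, file.path(d, "b"))))
  cls <- classify_variants(m, co$classification) |> assign_genes()
  scan <- run_gene_sign_scan(m, co$phenotypes, cls,
                             signs = c("aortic_ectasia", "myopia"))
  expect_setequal(unique(scan$stratum), c("pathogenic", "VUS", "benign"))
  # cells with no qualifying variants carry the documented reason
  empty <- scan[scan$n_variants == 0, ]
  expect_true(all(empty$reason == "no variants after MAF filter"))
  expect_true(all(is.na(empty$p_optimal)))
  # the planted FBN1-pathogenic cell is present and small
  cell <- scan[scan$gene == "FBN1" & scan$sign == "aortic_ectasia" &
                 scan$stratum == "pathogenic", ]
  expect_true(is.finite(cell$p_optimal))
  others <- scan[scan$sign == "aortic_ectasia" & !is.na(scan$p_optimal), ]
  expect_lte(cell$p_optimal, quantile(others$p_optimal, 0.25))
})
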
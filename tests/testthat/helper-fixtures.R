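# shared fixtures and independent oracle helpers

# a small cohort spec with explicit planted effects that resolve at any size
small_spec <- function(n_subjects = 40, n_common = 15, n_lowfreq = 5,
                       n_rare = 40, seed = 1, effect_plan = NULL, ...) {
  cohort_spec(n_subjects = n_subjects, n_common = n_common,
              n_lowfreq = n_lowfreq, n_rare = n_rare, seed = seed,
              effect_plan = effect_plan, ...)
}

# write a hand-rolled single-sample VCF (for fixtures the generator
# deliberately never produces: multi-allelic records, declared-missing GTs)
write_mini_vcf <- function(path, sample, records) {
  header <- c(
    "##fileformat=VCFv4.3",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gt, qual = 60, dp = 100) {
  sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.\tGT:DP\t%s:%d",
          chrom, pos, ref, alt, format(qual), gt, dp)
}

# brute-force HWE oracle: enumerate every genotype configuration with the
# observed sample size and minor-allele count, normalise multinomial mass
hwe_oracle <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  n_a <- 2 * min(n_homref, n_homalt) + n_het
  if (n_a == 0) return(1)
  hets <- seq.int(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  mass <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    nbb <- n - naa - h
    exp(lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
          h * log(2))
  }, numeric(1))
  mass <- mass / sum(mass)
  obs <- mass[hets == n_het]
  sum(mass[mass <= obs * (1 + 1e-9)])
}

# naive per-variant logistic score statistic (intercept + covariates null),
# written independently of the package internals
naive_score_stat <- function(y, g, X = NULL) {
  X <- if (is.null(X)) matrix(1, length(y), 1) else cbind(1, X)
  f0 <- glm.fit(X, y, family = binomial())
  mu <- f0$fitted.values
  w <- pmax(mu * (1 - mu), 1e-12)
  r <- y - mu
  U <- sum(g * r)
  WX <- X * w
  V <- sum(g^2 * w) -
    drop(t(crossprod(WX, g)) %*% solve(crossprod(X, WX)) %*% crossprod(WX, g))
  U / sqrt(max(V, 1e-300))
}

# brute-force log-likelihood grid search for a two-parameter logistic fit
logistic_grid_oracle <- function(y, x, b0_range, b1_range, step = 1e-4) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  # coarse-to-fine search
  best <- c(mean(b0_range), mean(b1_range))
  width <- diff(b0_range) / 2
  while (width > 1e-5) {
    b0s <- seq(best[1] - width, best[1] + width, length.out = 41)
    b1s <- seq(best[2] - width, best[2] + width, length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- mapply(ll, grid$b0, grid$b1)
    best <- unlist(grid[which.max(vals), ])
    width <- width / 5
  }
  best
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
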
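#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts: with the allele counts fixed,
#' the number of heterozygotes follows a hypergeometric-type distribution
#' over heterozygote counts of the same parity; the p-value is the total
#' probability of all heterozygote counts no more probable than the one
#' observed.
#'
#' @param n_homref,n_het,n_homalt Non-negative genotype counts (total >= 1).
#' @return A p-value in (0, 1]. Monomorphic variants return 1 by convention.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(50, 0, 50) # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  counts <- c(n_homref, n_het, n_homalt)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) abort("at least one genotyped sample is required")
  # minor allele count
  n_a <- 2 * min(n_homref, n_homalt) + n_het
  if (n_a == 0) return(1) # monomorphic
  hets <- hwe_het_support(n, n_a)
  logp <- hwe_log_prob(hets, n, n_a)
  logp_obs <- hwe_log_prob(n_het, n, n_a)
  p <- sum(exp(logp[logp <= logp_obs + 1e-10]))
  min(p, 1)
}

# heterozygote counts compatible with n samples and minor-allele count n_a
# (same parity as n_a, at most min(n_a, 2n - n_a))
hwe_het_support <- function(n, n_a) {
  hmax <- min(n_a, 2 * n - n_a)
  seq.int(n_a %% 2, hmax, by = 2)
}

# log P(het = h | n, n_a) under the exact conditional HWE distribution
hwe_log_prob <- function(h, n, n_a) {
  n_b <- 2 * n - n_a
  n_aa <- (n_a - h) / 2
  n_bb <- n - n_aa - h
  lgamma(n + 1) - lgamma(n_aa + 1) - lgamma(h + 1) - lgamma(n_bb + 1) +
    h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
}
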
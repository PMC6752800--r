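#' Generate a synthetic panel-sequencing cohort
#'
#' Simulates a complete Marfan-spectrum panel cohort under a known truth:
#' variant positions across the panel genes, true minor-allele frequencies
#' per frequency class, genotypes drawn as Binomial(2, MAF) under
#' Hardy-Weinberg equilibrium, clinical classes for rare variants, and the
#' fourteen binary clinical signs drawn from a logistic liability model
#' with planted genetic effects plus age. A fraction of calls is flagged
#' hidden behind sub-10X coverage so that the VCF/BED emitters and the
#' matrix builder can be round-trip tested.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `spec`, `variants` (tibble of variant truth: id, gene, position,
#'   alleles, frequency class, clinical class, true MAF), `genotypes`
#'   (subjects x variants integer matrix of alternate-allele dosages),
#'   `hidden` (logical matrix of calls masked by low coverage), `depth` and
#'   `qual` matrices, `phenotypes` (tibble of signs, age, suspicion,
#'   systemic score), `classification` (tibble id/class as a clinical
#'   laboratory would deliver it, including `likely-pathogenic` labels),
#'   and `truth` (resolved planted effects and per-subject liabilities).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 40, n_common = 10,
#'                                       n_lowfreq = 5, n_rare = 30, seed = 3))
#' dim(cohort$genotypes)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec")
  set.seed(spec$seed)

  variants <- simulate_variants(spec)
  n <- spec$n_subjects
  m <- nrow(variants)
  subjects <- sprintf("S%04d", seq_len(n))

  # HWE genotypes: dosage ~ Binomial(2, MAF) per variant, conditioned on
  # the variant being observed in the cohort (>= 1 alternate allele), as
  # a panel's variant list only ever contains observed sites
  geno <- matrix(0L, n, m, dimnames = list(subjects, variants$id))
  for (j in seq_len(m)) {
    g <- rbinom(n, 2L, variants$true_maf[j])
    tries <- 1L
    while (sum(g) == 0L && tries < 50L) {
      g <- rbinom(n, 2L, variants$true_maf[j])
      tries <- tries + 1L
    }
    if (sum(g) == 0L) g[sample.int(n, 1L)] <- 1L
    geno[, j] <- g
  }

  # age: lognormal calibrated to the target median and IQR
  med <- spec$age_distribution[["median"]]
  iqr <- spec$age_distribution[["iqr"]]
  sdlog <- asinh(iqr / (2 * med)) / qnorm(0.75)
  age <- rlnorm(n, meanlog = log(med), sdlog = sdlog)

  # resolve planted effects to per-subject dosage vectors
  effects <- resolve_effects(spec$effect_plan, variants, geno)

  # logistic liability per sign
  signs <- names(spec$baseline_prevalences)
  eta <- matrix(rep(qlogis(spec$baseline_prevalences), each = n), n,
                length(signs), dimnames = list(subjects, signs))
  eta <- eta + spec$age_beta * (age - med)
  severity <- rnorm(n, 0, spec$severity_sd %||% 0)
  eta <- eta + severity
  if (nrow(effects) > 0) {
    for (k in seq_len(nrow(effects))) {
      eta[, effects$sign[k]] <- eta[, effects$sign[k]] +
        effects$beta[k] * effects$dosage[[k]]
    }
  }
  sign_mat <- matrix(rbinom(length(eta), 1L, plogis(eta)), n,
                     length(signs), dimnames = dimnames(eta))

  # clinical suspicion: carriers of rare pathogenic variants in the core
  # Marfan genes lean towards an MFS label; others follow the cohort mix
  carrier <- carrier_dosage(variants, geno,
                            genes = c("FBN1", "TGFBR1", "TGFBR2")) > 0
  susp_levels <- c("MFS", "EDS", "Uncertain", "TAAD", "BAV", "LDS", "MASS")
  susp_base <- c(0.5913, 0.1879, 0.1215, 0.0552, 0.0331, 0.0055, 0.0055)
  suspicion <- character(n)
  for (i in seq_len(n)) {
    pr <- if (carrier[i]) c(0.85, 0.05, 0.06, 0.02, 0.01, 0.005, 0.005) else susp_base
    suspicion[i] <- sample(susp_levels, 1, prob = pr)
  }

  phenotypes <- bind_cols(
    tibble(subject = subjects),
    as_tibble(sign_mat),
    tibble(age = age, suspicion = suspicion)
  )
  phenotypes$systemic_score <- compute_systemic_score(phenotypes)

  # calls hidden behind low coverage; depth/qual metadata
  hidden <- matrix(runif(n * m) < spec$missing_rate, n, m,
                   dimnames = dimnames(geno))
  depth <- matrix(10L + rpois(n * m, 140L), n, m, dimnames = dimnames(geno))
  depth[hidden] <- sample(0:9, sum(hidden), replace = TRUE)
  qual <- matrix(round(pmax(31, rnorm(n * m, 60, 8)), 2), n, m,
                 dimnames = dimnames(geno))

  # laboratory-style classification table: a third of the truly pathogenic
  # variants are delivered as "likely-pathogenic" to exercise merging
  classification <- tibble(id = variants$id, class = variants$clinical_class)
  path_idx <- which(classification$class == "pathogenic")
  if (length(path_idx) >= 3) {
    lp <- path_idx[seq_len(floor(length(path_idx) / 3))]
    classification$class[lp] <- "likely-pathogenic"
  }

  structure(list(
    spec = spec,
    variants = variants,
    genotypes = geno,
    hidden = hidden,
    depth = depth,
    qual = qual,
    phenotypes = phenotypes,
    classification = classification,
    truth = list(effects = effects, liabilities = eta, severity = severity)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d subjects x %d variants (%d genes)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$variants$gene))))
  cat(sprintf("  frequency classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$variants$freq_class)),
                            table(x$variants$freq_class)), collapse = ", ")))
  cat(sprintf("  hidden calls: %d (%.2f%%)\n", sum(x$hidden),
              100 * mean(x$hidden)))
  invisible(x)
}

# sample variant sites across genes proportional to gene length
simulate_variants <- function(spec) {
  genes <- spec$genes
  counts <- c(common = spec$n_common, low_frequency = spec$n_lowfreq,
              rare = spec$n_rare)
  m <- sum(counts)
  len <- genes$end - genes$start + 1
  gene_idx <- sample(seq_len(nrow(genes)), m, replace = TRUE,
                     prob = len / sum(len))
  pos <- integer(m)
  for (g in unique(gene_idx)) {
    sel <- gene_idx == g
    pos[sel] <- sample(seq(genes$start[g], genes$end[g]), sum(sel))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- map_chr(ref, function(r) sample(setdiff(bases, r), 1))

  freq_class <- rep(names(counts), counts)
  maf <- numeric(m)
  for (cl in names(counts)) {
    r <- spec$maf_ranges[[cl]]
    maf[freq_class == cl] <- runif(counts[[cl]], r[1], r[2])
  }
  clin <- rep("benign", m)
  is_rare <- freq_class == "rare"
  clin[is_rare] <- sample(names(spec$clinical_class_probs), sum(is_rare),
                          replace = TRUE, prob = spec$clinical_class_probs)

  out <- tibble(
    chrom = genes$chrom[gene_idx],
    pos = pos,
    ref = ref,
    alt = alt,
    gene = genes$gene[gene_idx],
    freq_class = freq_class,
    clinical_class = clin,
    true_maf = maf
  )
  out <- distinct(out, .data$chrom, .data$pos, .keep_all = TRUE)
  out <- out[order_variants(out$chrom, out$pos, out$ref, out$alt), ]
  out$id <- variant_id(out$chrom, out$pos, out$ref, out$alt)
  select(out, "id", "chrom", "pos", "ref", "alt", "gene", "freq_class",
         "clinical_class", "true_maf")
}

# per-subject rare-pathogenic alternate-allele count in a gene set
carrier_dosage <- function(variants, geno, genes) {
  sel <- variants$gene %in% genes & variants$clinical_class == "pathogenic" &
    variants$freq_class == "rare"
  if (!any(sel)) return(rep(0L, nrow(geno)))
  rowSums(geno[, variants$id[sel], drop = FALSE])
}

# resolve effect_plan targets into dosage vectors
resolve_effects <- function(plan, variants, geno) {
  if (is.null(plan) || nrow(plan) == 0) {
    return(tibble(target = character(), sign = character(),
                  beta = numeric(), resolved = character(),
                  dosage = list()))
  }
  res <- map(seq_len(nrow(plan)), function(k) {
    tgt <- plan$target[k]
    if (tgt %in% variants$gene) {
      sel <- variants$gene == tgt & variants$clinical_class == "pathogenic" &
        variants$freq_class == "rare"
      if (!any(sel)) {
        abort(sprintf("effect target gene '%s' has no rare pathogenic variants", tgt))
      }
      list(resolved = sprintf("%s (rare pathogenic count, %d variants)",
                              tgt, sum(sel)),
           dosage = rowSums(geno[, variants$id[sel], drop = FALSE]))
    } else if (grepl("^[^:]+:[^:]+:[0-9]+$", tgt)) {
      parts <- strsplit(tgt, ":", fixed = TRUE)[[1]]
      sel <- which(variants$gene == parts[1] & variants$freq_class == parts[2])
      # k-th by descending true MAF, so class-level references resolve to
      # the class's most representative (most frequent) variants
      sel <- sel[order(variants$true_maf[sel], decreasing = TRUE)]
      kth <- as.integer(parts[3])
      if (length(sel) < kth) {
        abort(sprintf("effect target '%s': only %d such variants generated",
                      tgt, length(sel)))
      }
      id <- variants$id[sel[kth]]
      list(resolved = id, dosage = geno[, id])
    } else if (tgt %in% variants$id) {
      list(resolved = tgt, dosage = geno[, tgt])
    } else {
      abort(sprintf("effect target '%s' matches no gene or variant", tgt))
    }
  })
  tibble(
    target = plan$target,
    sign = plan$sign,
    beta = plan$beta,
    resolved = map_chr(res, "resolved"),
    dosage = map(res, "dosage")
  )
}

#' Simplified systemic score from the available clinical signs
#'
#' An operational version of the Ghent-2010 systemic feature score
#' restricted to the signs recorded in the phenotype table: combined
#' wrist-and-thumb sign scores 3 (either alone 1), pectus carinatum 2, and
#' flatfoot, scoliosis, reduced elbow extension, stretch marks, myopia and
#' mitral valve prolapse score 1 each.
#'
#' @param signs Data frame with the binary sign columns of
#'   [clinical_signs()].
#' @return Integer vector of scores.
#' @export
compute_systemic_score <- function(signs) {
  w <- signs$wrist_sign
  t <- signs$thumb_sign
  as.integer(
    ifelse(w & t, 3L, (w | t) * 1L) +
      2L * signs$pectus_carinatum +
      signs$flatfoot + signs$scoliosis + signs$reduced_elbow_extension +
      signs$stretch_marks + signs$myopia + signs$mitral_valve_prolapse
  )
}
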
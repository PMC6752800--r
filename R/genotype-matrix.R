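#' Read one-sample VCF files and collect the variant union
#'
#' Builds the ordered list of all variants seen in any of the per-sample
#' VCFs, deduplicated by (chrom, pos, ref, alt). Multi-allelic records are
#' split into one entry per alternate allele. Variants are sorted by
#' natural chromosome order, then position, then alleles.
#'
#' @param vcf_paths Character vector of per-sample VCF files (one sample
#'   per file).
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `id`.
#' @export
collect_variant_union <- function(vcf_paths) {
  recs <- map(vcf_paths, read_sample_vcf)
  all <- bind_rows(map(recs, "records"))
  if (nrow(all) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), id = character()))
  }
  u <- distinct(all, .data$chrom, .data$pos, .data$ref, .data$alt)
  u <- u[order_variants(u$chrom, u$pos, u$ref, u$alt), ]
  u$id <- variant_id(u$chrom, u$pos, u$ref, u$alt)
  u
}

# parse a single-sample VCF into split biallelic records
# returns list(sample=, records=tibble(chrom,pos,ref,alt,code,qual,depth))
read_sample_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  sample <- if (!is.null(gt) && ncol(gt) >= 2) colnames(gt)[2] else
    sub("\\.vcf(\\.gz)?$", "", basename(path))
  if (nrow(fix) == 0) {
    return(list(sample = sample, records = tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), code = integer(), qual = numeric(),
      depth = integer())))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (any(is.na(pos))) {
    abort(sprintf("malformed VCF record in %s (record %d): bad POS",
                  path, which(is.na(pos))[1]))
  }
  ref <- toupper(fix[, "REF"])
  altf <- toupper(fix[, "ALT"])
  bad <- !grepl("^[ACGT]+$", ref) | is.na(altf) | !grepl("^[ACGT]+(,[ACGT]+)*$", altf)
  if (any(bad)) {
    abort(sprintf("malformed VCF record in %s (record %d): bad alleles",
                  path, which(bad)[1]))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gt_str <- vcfR::extract.gt(v, element = "GT")[, 1]
  dp <- tryCatch(
    suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1])),
    error = function(e) rep(NA_integer_, nrow(fix)))

  allele_lists <- strsplit(ifelse(is.na(gt_str), ".", gt_str), "[/|]")
  multi <- grepl(",", altf, fixed = TRUE)

  code_for <- function(alleles, a) {
    if (length(alleles) == 0 || any(is.na(alleles)) || any(alleles == ".")) {
      NA_integer_
    } else {
      sum(alleles == as.character(a))
    }
  }
  # fast path: biallelic records, vectorised
  simple <- tibble(
    chrom = fix[!multi, "CHROM"], pos = pos[!multi], ref = ref[!multi],
    alt = altf[!multi],
    code = vapply(allele_lists[!multi], code_for, integer(1), a = 1L),
    qual = qual[!multi], depth = dp[!multi]
  )
  split_multi <- map_dfr(which(multi), function(i) {
    alts <- strsplit(altf[i], ",", fixed = TRUE)[[1]]
    tibble(chrom = fix[i, "CHROM"], pos = pos[i], ref = ref[i], alt = alts,
           code = vapply(seq_along(alts), function(a)
             code_for(allele_lists[[i]], a), integer(1)),
           qual = qual[i], depth = dp[i])
  })
  list(sample = sample, records = bind_rows(simple, split_multi))
}

#' Build a genotype matrix from per-sample VCFs and coverage masks
#'
#' Implements the coverage-aware merging framework: (i) collect the union
#' of all variants seen in the cohort, (ii) record each sample's zygosity
#' from its VCF (`0/1` -> 1, `1/1` -> 2), (iii) infer sites absent from a
#' sample's VCF to be homozygous reference (0), (iv-v) except where the
#' site falls in that sample's sub-10X coverage mask, in which case the
#' inferred call becomes missing, and (vi) key every variant by its
#' canonical `chrom-pos-ref-alt` id. Genotypes declared missing (`./.`) in
#' a VCF stay missing.
#'
#' @param vcf_paths Character vector of per-sample VCF files.
#' @param masks Named list (by sample) of data frames with columns `chrom`,
#'   `start`, `end` giving 0-based half-open low-coverage intervals, e.g.
#'   from [read_coverage_beds()]. Samples without an entry get an empty
#'   mask (logged).
#' @return A `geno_matrix` object: integer call matrix (subjects x
#'   variants; NA = missing) plus per-call depth and quality metadata, the
#'   variant table, and a provenance log.
#' @export
build_genotype_matrix <- function(vcf_paths, masks = list()) {
  parsed <- map(vcf_paths, read_sample_vcf)
  samples <- unname(map_chr(parsed, "sample"))
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample name(s): %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  union <- collect_variant_union_parsed(parsed)
  n <- length(samples)
  m <- nrow(union)
  log <- c(sprintf("read %d per-sample VCFs; %d variants in union", n, m))

  calls <- matrix(0L, n, m, dimnames = list(samples, union$id))
  depth <- matrix(NA_integer_, n, m, dimnames = list(samples, union$id))
  qual <- matrix(NA_real_, n, m, dimnames = list(samples, union$id))

  for (k in seq_len(n)) {
    rec <- parsed[[k]]$records
    if (nrow(rec) > 0) {
      ids <- variant_id(rec$chrom, rec$pos, rec$ref, rec$alt)
      calls[k, ids] <- rec$code
      depth[k, ids] <- rec$depth
      qual[k, ids] <- rec$qual
    }
    mask <- masks[[samples[k]]]
    if (is.null(mask) || nrow(mask) == 0) {
      log <- c(log, sprintf("sample %s: empty coverage mask", samples[k]))
      mask <- tibble(chrom = character(), start = integer(), end = integer())
    }
    # absent from VCF (inferred 0/0) and inside the mask -> missing
    absent <- is.na(match(union$id, if (nrow(rec) > 0)
      variant_id(rec$chrom, rec$pos, rec$ref, rec$alt) else character(0)))
    if (any(absent) && nrow(mask) > 0) {
      masked <- rep(FALSE, m)
      for (ch in unique(mask$chrom)) {
        onch <- union$chrom == ch
        if (any(onch)) {
          masked[onch] <- pos_in_intervals(union$pos[onch],
                                           mask[mask$chrom == ch, ])
        }
      }
      calls[k, absent & masked] <- NA_integer_
    }
  }
  new_geno_matrix(calls, depth, qual, union, log)
}

collect_variant_union_parsed <- function(parsed) {
  all <- bind_rows(map(parsed, "records"))
  u <- distinct(all, .data$chrom, .data$pos, .data$ref, .data$alt)
  u <- u[order_variants(u$chrom, u$pos, u$ref, u$alt), ]
  u$id <- variant_id(u$chrom, u$pos, u$ref, u$alt)
  u
}

new_geno_matrix <- function(calls, depth, qual, variants, log) {
  structure(list(calls = calls, depth = depth, qual = qual,
                 variants = as_tibble(variants), log = log),
            class = "geno_matrix")
}

#' Read per-sample low-coverage BED files
#'
#' @param bed_paths Character vector of BED files (0-based half-open), one
#'   per sample; sample names are taken from the file basenames.
#' @return A named list of tibbles with columns `chrom`, `start`, `end`.
#' @export
read_coverage_beds <- function(bed_paths) {
  out <- map(bed_paths, function(p) {
    if (file.size(p) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer()))
    }
    b <- read.table(p, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end"),
                    colClasses = c("character", "integer", "integer"))
    as_tibble(b)
  })
  set_names(out, sub("\\.bed$", "", basename(bed_paths)))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants, %d missing calls (%.2f%%)\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Long-format view of a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `id`, `code`, `depth`, `qual`.
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  tibble(
    subject = rep(rownames(x$calls), times = ncol(x$calls)),
    id = rep(colnames(x$calls), each = nrow(x$calls)),
    code = as.integer(x$calls),
    depth = as.integer(x$depth),
    qual = as.numeric(x$qual)
  )
}

# subset a geno_matrix by logical/character index
geno_subset <- function(x, samples = NULL, variants = NULL) {
  s <- samples %||% rownames(x$calls)
  v <- variants %||% colnames(x$calls)
  new_geno_matrix(
    x$calls[s, v, drop = FALSE],
    x$depth[s, v, drop = FALSE],
    x$qual[s, v, drop = FALSE],
    x$variants[match(colnames(x$calls[s, v, drop = FALSE]), x$variants$id), ],
    x$log
  )
}

#' Write a genotype matrix to disk
#'
#' Two dialects: `"tsv"`, a tab-separated subject-by-variant table with the
#' canonical variant ids as column headers and `NA` for missing calls; or
#' `"ped"`, a PLINK-compatible pedigree/map pair (`<stem>.ped`,
#' `<stem>.map`) with ref/alt allele pairs and `0 0` for missing.
#'
#' @param x A `geno_matrix`.
#' @param stem Output path (for `"ped"`, without extension).
#' @param format `"tsv"` or `"ped"`.
#' @return Invisibly, the written path(s).
#' @export
write_genotype_matrix <- function(x, stem, format = c("tsv", "ped")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- bind_cols(tibble(subject = rownames(x$calls)),
                    as_tibble(as.data.frame(x$calls)))
    readr::write_tsv(df, stem)
    return(invisible(stem))
  }
  map_path <- paste0(stem, ".map")
  ped_path <- paste0(stem, ".ped")
  v <- x$variants
  readr::write_tsv(tibble(chrom = v$chrom, id = v$id, cm = 0, pos = v$pos),
                   map_path, col_names = FALSE)
  lines <- vapply(seq_len(nrow(x$calls)), function(i) {
    g <- x$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, v$alt, v$ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, v$alt, v$ref))
    paste(c(rownames(x$calls)[i], rownames(x$calls)[i], "0", "0", "0", "-9",
            rbind(a1, a2)), collapse = "\t")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}
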
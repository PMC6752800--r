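test_that("variant union is the deduplicated, sorted set across VCFs", {
  d <- withr::local_tempdir()
  write_mini_vcf(file.path(d, "a.vcf"), "A", c(
    vcf_record("chr2", 100, "A", "T", "0/1"),
    vcf_record("chr10", 50, "G", "C", "1/1")))
  write_mini_vcf(file.path(d, "b.vcf"), "B", c(
    vcf_record("chr2", 100, "A", "T", "0/1"),
    vcf_record("chr2", 300, "C", "G", "0/1")))
  u <- collect_variant_union(list.files(d, full.names = TRUE))
  expect_equal(nrow(u), 3)
  # natural chromosome sort: chr2 before chr10
  expect_equal(u$id, c("chr2-100-A-T", "chr2-300-C-G", "chr10-50-G-C"))
})

test_that("multi-allelic records split into one key per alternate allele", {
  d <- withr::local_tempdir()
  write_mini_vcf(file.path(d, "a.vcf"), "A",
                 vcf_record("chr1", 10, "G", "A,T", "1/2"))
  u <- collect_variant_union(file.path(d, "a.vcf"))
  expect_equal(u$id, c("chr1-10-G-A", "chr1-10-G-T"))
  m <- build_genotype_matrix(file.path(d, "a.vcf"))
  expect_equal(unname(m$calls["A", ]), c(1L, 1L))
})

test_that("union of random synthetic VCFs equals a concatenate-and-unique oracle", {
  co <- generate_cohort(small_spec(n_subjects = 20, seed = 31,
                                   missing_rate = 0))
  d <- withr::local_tempdir()
  paths <- emit_vcfs(co, d)
  u <- collect_variant_union(paths)
  # oracle: read the raw text, paste keys, unique, sort lexically then
  # reorder to the package's natural order for comparison
  keys <- unlist(lapply(paths, function(p) {
    lines <- readLines(p)
    recs <- lines[!startsWith(lines, "#")]
    if (length(recs) == 0) return(character(0))
    f <- strsplit(recs, "\t")
    vapply(f, function(x) paste(x[1], x[2], x[4], x[5], sep = "-"),
           character(1))
  }))
  expect_setequal(u$id, unique(keys))
})

test_that("matrix building follows the absent/masked call rules", {
  d <- withr::local_tempdir()
  # sample A carries two sites; sample B carries one and misses the other
  write_mini_vcf(file.path(d, "A.vcf"), "A", c(
    vcf_record("chr1", 100, "A", "T", "0/1"),
    vcf_record("chr1", 200, "G", "C", "1/1")))
  write_mini_vcf(file.path(d, "B.vcf"), "B",
                 vcf_record("chr1", 100, "A", "T", "./."))
  masks <- list(B = tibble::tibble(chrom = "chr1", start = 199L, end = 200L))
  m <- build_genotype_matrix(list.files(d, full.names = TRUE), masks)
  # A: het then hom-alt
  expect_equal(unname(m$calls["A", ]), c(1L, 2L))
  # B: declared missing at site 1; absent + masked at site 2 -> missing
  expect_true(all(is.na(m$calls["B", ])))
  # same without the mask: absent + unmasked -> inferred wild type 0
  m2 <- build_genotype_matrix(list.files(d, full.names = TRUE))
  expect_equal(unname(m2$calls["B", "chr1-200-G-C"]), 0L)
})

test_that("round-trip from synthetic truth through VCF+BED is exact at unhidden calls", {
  co <- generate_cohort(small_spec(n_subjects = 30, seed = 17,
                                   missing_rate = 0.03))
  d <- withr::local_tempdir()
  vp <- emit_vcfs(co, file.path(d, "vcf"))
  bp <- emit_coverage_beds(co, file.path(d, "bed"))
  m <- build_genotype_matrix(vp, read_coverage_beds(bp))
  truth <- co$genotypes
  for (v in colnames(m$calls)) {
    vis <- !co$hidden[, v]
    expect_identical(unname(m$calls[rownames(truth)[vis], v]),
                     unname(truth[vis, v]))
    expect_true(all(is.na(m$calls[rownames(truth)[!vis], v])))
  }
  # variants absent from the union had no visible carriers
  absent <- setdiff(colnames(truth), colnames(m$calls))
  if (length(absent) > 0) {
    expect_true(all(colSums(truth[, absent, drop = FALSE] *
                              !co$hidden[, absent, drop = FALSE]) == 0))
  }
})

test_that("matrix construction is order independent and mask monotone", {
  co <- generate_cohort(small_spec(n_subjects = 15, seed = 23,
                                   missing_rate = 0.02))
  d <- withr::local_tempdir()
  vp <- emit_vcfs(co, file.path(d, "vcf"))
  bp <- emit_coverage_beds(co, file.path(d, "bed"))
  masks <- read_coverage_beds(bp)
  m1 <- build_genotype_matrix(vp, masks)
  m2 <- build_genotype_matrix(rev(vp), masks)
  samp <- rownames(m1$calls)
  expect_identical(m1$calls, m2$calls[samp, colnames(m1$calls)])
  # enlarging a sample's mask only converts 0 -> missing
  s <- samp[1]
  big <- masks
  big[[s]] <- dplyr::bind_rows(
    big[[s]], tibble::tibble(chrom = co$variants$chrom,
                             start = co$variants$pos - 1L,
                             end = co$variants$pos))
  m3 <- build_genotype_matrix(vp, big)
  before <- m1$calls[s, ]
  after <- m3$calls[s, colnames(m1$calls)]
  changed <- which(!is.na(before) & is.na(after))
  expect_true(all(before[changed] == 0L))
  kept <- which(!is.na(after))
  expect_identical(after[kept], before[kept])
})

test_that("malformed VCF records raise a parse error naming the file", {
  d <- withr::local_tempdir()
  p <- write_mini_vcf(file.path(d, "bad.vcf"), "X",
                      "chr1\t10\t.\tA\tZ\t50\tPASS\t.\tGT:DP\t0/1:9")
  expect_error(build_genotype_matrix(p), "bad.vcf")
})

test_that("duplicate sample names are rejected", {
  d <- withr::local_tempdir()
  write_mini_vcf(file.path(d, "a.vcf"), "S1",
                 vcf_record("chr1", 10, "A", "T", "0/1"))
  write_mini_vcf(file.path(d, "b.vcf"), "S1",
                 vcf_record("chr1", 20, "A", "T", "0/1"))
  expect_error(build_genotype_matrix(list.files(d, full.names = TRUE)),
               "duplicate")
})

test_that("matrix export writes both dialects", {
  co <- generate_cohort(small_spec(n_subjects = 8, seed = 2,
                                   missing_rate = 0.05))
  d <- withr::local_tempdir()
  m <- build_genotype_matrix(emit_vcfs(co, file.path(d, "v")),
                             read_coverage_beds(
                               emit_coverage_beds(co, file.path(d, "b"))))
  tsv <- file.path(d, "m.tsv")
  write_genotype_matrix(m, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$subject, rownames(m$calls))
  expect_equal(unname(as.matrix(back[-1])), unname(m$calls))
  pm <- write_genotype_matrix(m, file.path(d, "plink"), format = "ped")
  ped <- readLines(pm["ped"])
  expect_length(ped, nrow(m$calls))
  map <- readr::read_tsv(pm["map"], col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(map), ncol(m$calls))
  # allele pairs: 6 leading columns + 2 per variant
  expect_equal(length(strsplit(ped[1], "\t")[[1]]), 6 + 2 * ncol(m$calls))
})
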
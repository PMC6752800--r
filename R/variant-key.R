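#' Canonical variant identifiers
#'
#' A variant is keyed by chromosome, 1-based position, reference allele and
#' alternate allele, and carries the canonical string id
#' `"chrom-pos-ref-alt"` (e.g. `"chr1-542354454-A-T"`). The id is
#' reconstructible from the four fields and unique within a cohort.
#'
#' @param chrom Chromosome label (no `-` allowed).
#' @param pos 1-based position, positive integer.
#' @param ref,alt Non-empty uppercase ACGT allele strings; `ref != alt`.
#'   The `-` character is rejected (reserved as the id separator).
#' @return `variant_id()` returns a character vector of ids;
#'   `parse_variant_id()` returns a tibble with columns `chrom`, `pos`,
#'   `ref`, `alt`, `id`.
#' @examples
#' variant_id("chr1", 542354454, "A", "T")
#' parse_variant_id("chr15-48713412-G-C")
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    abort(sprintf(
      "invalid alleles (must be non-empty ACGT strings without '-'): %s",
      paste(unique(paste0(ref[bad], "/", alt[bad])), collapse = ", ")))
  }
  if (any(ref == alt)) abort("ref and alt alleles must differ")
  if (any(grepl("-", chrom, fixed = TRUE))) {
    abort("chromosome labels must not contain '-' (reserved separator)")
  }
  if (any(pos < 1 | pos != floor(pos))) abort("pos must be a positive integer")
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ref, alt,
        sep = "-")
}

#' @rdname variant_id
#' @param id Character vector of canonical ids.
#' @export
parse_variant_id <- function(id) {
  m <- regmatches(id, regexec("^([^-]+)-([0-9]+)-([ACGT]+)-([ACGT]+)$", id))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    abort(sprintf("malformed variant id(s): %s",
                  paste(head(id[bad], 5), collapse = ", ")))
  }
  tibble(
    chrom = vapply(m, `[`, character(1), 2),
    pos = as.integer(vapply(m, `[`, character(1), 3)),
    ref = vapply(m, `[`, character(1), 4),
    alt = vapply(m, `[`, character(1), 5),
    id = id
  )
}

#' Phred-scaled quality from an error probability
#'
#' `Q = -10 log10(P)`; a Phred score below 30 corresponds to a base-calling
#' error probability above 0.001.
#'
#' @param p Error probability in (0, 1].
#' @return Numeric vector of Phred scores.
#' @examples
#' phred_from_error(0.001) # 30
#' @export
phred_from_error <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("error probability must lie in (0, 1]")
  }
  -10 * log10(p)
}
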
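# internal helpers shared across modules

# natural chromosome ordering: chr1 < chr2 < ... < chr22 < chrX < chrY < chrM,
# anything else after, alphabetically
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(core))
  rank <- ifelse(!is.na(num), num,
    ifelse(core %in% c("X", "x"), 23,
      ifelse(core %in% c("Y", "y"), 24,
        ifelse(core %in% c("M", "MT", "m", "mt"), 25, 26))))
  order2 <- ifelse(rank == 26, core, "")
  list(rank = rank, tie = order2)
}

order_variants <- function(chrom, pos, ref = NULL, alt = NULL) {
  cr <- chrom_rank(chrom)
  if (is.null(ref)) {
    order(cr$rank, cr$tie, pos, method = "radix")
  } else {
    order(cr$rank, cr$tie, pos, ref, alt, method = "radix")
  }
}

# 1-based genomic position inside 0-based half-open [start, end) intervals?
# intervals: data frame with columns start, end (may be empty)
pos_in_intervals <- function(pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  p0 <- pos - 1L # convert to 0-based
  res <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    res <- res | (p0 >= intervals$start[i] & p0 < intervals$end[i])
  }
  res
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# check a probability vector sums to one
check_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort(sprintf("`%s` must be non-negative and sum to 1", what))
  }
  invisible(TRUE)
}

`%0%` <- function(x, y) if (length(x) == 0) y else x
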
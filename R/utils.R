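# Shared low-level helpers. All coordinates in this package are 0-based,
# half-open [start, end) unless a function is explicitly an I/O boundary
# (GFF3 and bedGraph/BED are converted on read/write).

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

GENETIC_CODE_SENSE <- {
  gc <- Biostrings::GENETIC_CODE
  gc[gc != "*"]
}

#' @noRd
tl_translate <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# sample a random codon for a given amino acid
codon_for_aa <- function(aa) {
  cands <- names(GENETIC_CODE_SENSE)[GENETIC_CODE_SENSE == aa]
  cands[sample.int(length(cands), 1L)]
}

random_protein <- function(n_aa) {
  paste(sample(AA_ALPHABET20, n_aa, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intervals ------------------------------------------------------------------

#' @noRd
interval_df <- function(start = integer(), end = integer()) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

# logical mask of length len from an interval data.frame (0-based half-open)
intervals_to_mask <- function(intervals, len) {
  m <- logical(len)
  if (is.null(intervals) || nrow(intervals) == 0L) return(m)
  for (i in seq_len(nrow(intervals))) {
    s <- max(0L, intervals$start[i])
    e <- min(len, intervals$end[i])
    if (e > s) m[(s + 1L):e] <- TRUE
  }
  m
}

# maximal runs of TRUE as 0-based half-open intervals
mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  interval_df(starts[keep], ends[keep])
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# run-length encode an integer depth vector into a bedGraph-style data.frame
depth_to_runs <- function(depth) {
  r <- rle(as.integer(depth))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts, end = ends, depth = r$values)
}

runs_to_depth <- function(runs, len) {
  depth <- integer(len)
  if (nrow(runs) > 0L) for (i in seq_len(nrow(runs))) {
    s <- max(0L, runs$start[i]); e <- min(len, runs$end[i])
    if (e > s) depth[(s + 1L):e] <- as.integer(runs$depth[i])
  }
  depth
}

`%||%` <- function(a, b) if (is.null(a)) b else a
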
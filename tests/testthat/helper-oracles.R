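# Independent oracles used across tests. These deliberately re-derive
# results with different algorithms from the package implementations.

# global Needleman-Wunsch alignment; identity = matches / aligned residue
# pairs (gap columns excluded from the denominator)
nw_identity <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1, j + 1] <- max(
      S[i, j] + ifelse(x[i] == y[j], match, mismatch),
      S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  # traceback
  i <- n; j <- m; matches <- 0L; pairs <- 0L
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + ifelse(x[i] == y[j], match, mismatch)) {
      pairs <- pairs + 1L
      if (x[i] == y[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  matches / pairs
}

# tryptic digestion oracle: regex pattern scan, independent of the
# index-arithmetic implementation
digest_oracle <- function(protein) {
  marked <- gsub("(?<=[KR])(?!P)", "\x01", protein, perl = TRUE)
  strsplit(marked, "\x01", fixed = TRUE)[[1]]
}

# brute-force O(n*m) substring scan: genes whose protein contains the
# peptide, by explicit positionwise comparison
brute_matching_genes <- function(peptide, proteome) {
  hits <- character(0)
  np <- nchar(peptide)
  for (gid in names(proteome)) {
    prot <- proteome[[gid]]
    found <- FALSE
    if (nchar(prot) >= np) {
      for (s in 1:(nchar(prot) - np + 1)) {
        if (substr(prot, s, s + np - 1) == peptide) { found <- TRUE; break }
      }
    }
    if (found) hits <- c(hits, gid)
  }
  hits
}

# reverse-translate an amino-acid string with a fixed codon choice
aa_to_nt <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  first_codon <- vapply(unique(gc), function(a)
    names(gc)[gc == a][1], character(1))
  paste(first_codon[strsplit(aa, "")[[1]]], collapse = "")
}

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
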
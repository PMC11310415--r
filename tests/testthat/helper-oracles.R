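# Brute-force affine-gap Smith-Waterman (quadratic DP), independent of
# the package's aligner. A gap of length L costs open + L * ext; N never
# matches anything.
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                            Iy[i - 1, j - 1]) + s)
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

sw_oracle_both_strands <- function(a, b, ...) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  max(sw_oracle(a, b, ...), sw_oracle(rc, b, ...))
}

# Small alignment builder: rows given as equal-length strings.
toy_alignment <- function(rows, headers = NULL) {
  ortholog_alignment(rows, headers)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Synthetic hit builder for vote() tests: full coverage of given calls.
toy_hit <- function(read_id, calls_named, score = 100) {
  positions <- as.integer(names(calls_named))
  structure(
    list(read_id = read_id, score = score, strand = "+",
         query_start = min(positions), query_end = max(positions),
         calls = calls_named),
    class = "alignment_hit"
  )
}
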
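#' Scoring scheme for local read-to-query alignment
#'
#' blastn-like defaults: match +2, mismatch -3, gap open 5, gap extend 2
#' (a gap of length L costs open + L * extend). Scores are in this
#' scheme, not BLAST bit scores; the default filter threshold of 80
#' mirrors the published raw-score cut-off.
#'
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (penalties positive).
#' @return list of scoring parameters plus the substitution matrix used
#'   (`N` never matches anything, itself included).
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2) {
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- match
  mat["N", ] <- mismatch
  mat[, "N"] <- mismatch
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, matrix = mat)
}

#' Optimal local alignment of one read against the query
#'
#' Affine-gap Smith-Waterman on both strands; the better orientation is
#' kept. Read bases are projected onto query coordinates: insertions in
#' the read are dropped, deletions appear as `-`.
#'
#' @param read nucleotide string over `{A,C,G,T,N}`.
#' @param query query (exon) nucleotide string.
#' @param read_id identifier carried into the hit.
#' @param scoring an [align_scoring()] list.
#' @return An `alignment_hit`: list with `read_id`, `score`, `strand`
#'   (`+`/`-`), `query_start`, `query_end` (1-based inclusive) and
#'   `calls` (character vector named by query position).
#' @export
local_align <- function(read, query, read_id = "read", scoring = align_scoring()) {
  if (nchar(read) == 0L || nchar(query) == 0L) stop("empty sequence")
  fwd <- Biostrings::DNAString(toupper(read))
  candidates <- list(`+` = fwd, `-` = Biostrings::reverseComplement(fwd))
  best <- NULL
  for (strand in names(candidates)) {
    pa <- Biostrings::pairwiseAlignment(
      candidates[[strand]], Biostrings::DNAString(toupper(query)),
      type = "local", substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
    )
    sc <- BiocGenerics::score(pa)
    if (is.null(best) || sc > best$sc) best <- list(pa = pa, sc = sc, strand = strand)
  }
  pa <- best$pa
  aligned_read <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  aligned_query <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qstart <- BiocGenerics::start(Biostrings::subject(pa))
  calls <- character(0)
  qpos <- qstart - 1L
  for (i in seq_along(aligned_query)) {
    if (aligned_query[i] != "-") {
      qpos <- qpos + 1L
      calls[as.character(qpos)] <- aligned_read[i]
    }
  }
  structure(
    list(read_id = read_id, score = max(0, best$sc), strand = best$strand,
         query_start = qstart, query_end = qpos, calls = calls),
    class = "alignment_hit"
  )
}

#' Align a whole read set against the query
#'
#' @param reads named character vector of read sequences (names = read
#'   ids) or a FASTA/FASTQ path (see [read_sequences()]).
#' @inheritParams local_align
#' @return list of `alignment_hit`.
#' @export
align_reads <- function(reads, query, scoring = align_scoring()) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_sequences(reads)
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  mapply(local_align, reads, names(reads),
         MoreArgs = list(query = query, scoring = scoring),
         SIMPLIFY = FALSE)
}

#' Read nucleotide sequences from FASTA or FASTQ
#'
#' Format is inferred from the file extension (`.fastq`/`.fq` vs FASTA);
#' qualities are ignored.
#'
#' @param path input path.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fastq"
  } else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Filter alignment hits by score and cap at the best N
#'
#' Keeps hits scoring strictly above `min_score`, sorts by descending
#' score (ties by read id), and truncates to the top `cap` (the published
#' procedure: top 100 reads with alignment score > 80).
#'
#' @param hits list of `alignment_hit`.
#' @param min_score strict lower bound on the score (default 80).
#' @param cap maximum number of hits kept (default 100).
#' @return filtered, sorted list of hits.
#' @export
filter_hits <- function(hits, min_score = 80, cap = 100) {
  stopifnot(min_score >= 0, cap >= 1)
  scores <- vapply(hits, `[[`, numeric(1), "score")
  ids <- vapply(hits, `[[`, character(1), "read_id")
  keep <- scores > min_score
  hits <- hits[keep][order(-scores[keep], ids[keep])]
  head(hits, cap)
}

#' Per-position base vote over the motif interval
#'
#' For each query position of the motif region, tallies the base calls of
#' covering hits and the percentage matching the reference motif base.
#' `N` calls count towards coverage but never match; positions with zero
#' coverage are undefined (`NA` percent).
#'
#' @param hits filtered hits from [filter_hits()].
#' @param motif_start,motif_end 1-based inclusive interval on the query
#'   coding for the motif.
#' @param reference_motif reference nucleotides over the interval
#'   (default the human KKRR codons `aagaagagacgg`).
#' @param query_length length of the query, used to validate the interval
#'   (optional).
#' @return data.frame with `position`, `ref_base`, counts `A`,`C`,`G`,
#'   `T`,`N`,`gap`, `coverage` and `percent_match`.
#' @export
vote <- function(hits, motif_start, motif_end,
                 reference_motif = "aagaagagacgg", query_length = NULL) {
  positions <- motif_start:motif_end
  ref <- strsplit(toupper(reference_motif), "")[[1]]
  if (length(ref) != length(positions)) {
    stop("reference motif length does not match the motif interval")
  }
  if (!is.null(query_length) && (motif_start < 1L || motif_end > query_length)) {
    stop("motif interval outside the query")
  }
  symbols <- c("A", "C", "G", "T", "N", "-")
  rows <- lapply(seq_along(positions), function(i) {
    pos <- positions[i]
    calls <- unlist(lapply(hits, function(h) h$calls[as.character(pos)]))
    calls <- calls[!is.na(calls)]
    counts <- table(factor(calls, levels = symbols))
    coverage <- sum(counts)
    data.frame(
      position = pos, ref_base = ref[i],
      A = as.integer(counts["A"]), C = as.integer(counts["C"]),
      G = as.integer(counts["G"]), T = as.integer(counts["T"]),
      N = as.integer(counts["N"]), gap = as.integer(counts["-"]),
      coverage = coverage,
      percent_match = if (coverage > 0L) {
        100 * as.integer(counts[ref[i]]) / coverage
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Majority-base consensus over the vote table, translated
#'
#' Per position, the majority base among `A`,`C`,`G`,`T`; ties fall back
#' to the reference base (flagged); uncovered positions become `N` and
#' translate to `X`.
#'
#' @param vote_table output of [vote()].
#' @return list with `nt` (nucleotide motif), `aa` (translated motif),
#'   `ties` (positions resolved by the reference fallback) and
#'   `uncovered` (positions with no A/C/G/T call).
#' @export
consensus_motif <- function(vote_table) {
  bases <- c("A", "C", "G", "T")
  ties <- integer(0)
  uncovered <- integer(0)
  nt <- vapply(seq_len(nrow(vote_table)), function(i) {
    counts <- unlist(vote_table[i, bases])
    if (sum(counts) == 0L) {
      uncovered <<- c(uncovered, vote_table$position[i])
      return("N")
    }
    top <- bases[counts == max(counts)]
    if (length(top) > 1L) {
      ties <<- c(ties, vote_table$position[i])
      ref <- toupper(vote_table$ref_base[i])
      if (ref %in% top) return(ref)
      top <- sort(top)
    }
    top[1]
  }, character(1))
  nt <- paste(nt, collapse = "")
  aa <- if (nchar(nt) %% 3L == 0L) translate_codons(nt) else NA_character_
  list(nt = tolower(nt), aa = aa, ties = ties, uncovered = uncovered)
}

#' Full read-vote analysis
#'
#' Convenience wrapper: align reads to the query, filter, vote and call
#' the consensus motif.
#'
#' @inheritParams align_reads
#' @inheritParams filter_hits
#' @inheritParams vote
#' @return list with `hits` (filtered), `vote_table`, `consensus` and
#'   `n_input_reads`.
#' @export
read_vote <- function(reads, query, motif_start, motif_end,
                      reference_motif = "aagaagagacgg",
                      min_score = 80, cap = 100,
                      scoring = align_scoring()) {
  hits <- align_reads(reads, query, scoring)
  n_input <- length(hits)
  hits <- filter_hits(hits, min_score, cap)
  vt <- vote(hits, motif_start, motif_end, reference_motif,
             query_length = nchar(query))
  list(hits = hits, vote_table = vt, consensus = consensus_motif(vt),
       n_input_reads = n_input)
}
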
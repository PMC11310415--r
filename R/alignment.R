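#' Ortholog alignment container
#'
#' An `ortholog_alignment` holds equal-length aligned amino-acid rows
#' (alphabet: the 20 amino acids, `X`, and the gap `-`) together with
#' per-sequence metadata parsed from FASTA headers. The header convention
#' is `species|accession|isoform`; headers that do not follow it keep the
#' full header as the species label.
#'
#' @param residues character vector of aligned sequences (equal length).
#' @param headers character vector of FASTA headers (used as sequence ids).
#' @return An `ortholog_alignment`: list with `matrix` (character matrix,
#'   rows = sequences), `meta` (data.frame with `sequence_id`, `species`,
#'   `accession`, `isoform`, `header`) and `column_count`.
#' @export
ortholog_alignment <- function(residues, headers = NULL) {
  if (length(residues) == 0L) stop("alignment has no sequences")
  if (is.null(headers)) headers <- paste0("seq", seq_along(residues))
  widths <- nchar(residues)
  if (length(unique(widths)) != 1L) {
    stop("unequal row lengths: alignment rows must all have the same width")
  }
  if (widths[1] < 1L) stop("alignment has zero columns")
  if (anyDuplicated(headers)) {
    headers <- make.unique(headers, sep = "#")
  }
  mat <- do.call(rbind, strsplit(toupper(residues), ""))
  rownames(mat) <- headers
  meta <- parse_fasta_headers(headers)
  structure(
    list(matrix = mat, meta = meta, column_count = ncol(mat)),
    class = "ortholog_alignment"
  )
}

#' @export
print.ortholog_alignment <- function(x, ...) {
  cat(sprintf(
    "ortholog_alignment: %d sequences x %d columns (%d species)\n",
    nrow(x$matrix), x$column_count, length(unique(x$meta$species))
  ))
  invisible(x)
}

# "species|accession|isoform" with graceful fallback to the full header.
parse_fasta_headers <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  species <- vapply(parts, function(p) {
    if (length(p) >= 2L) p[[1]] else paste(p, collapse = "|")
  }, character(1))
  accession <- vapply(parts, function(p) {
    if (length(p) >= 2L) p[[2]] else NA_character_
  }, character(1))
  isoform <- vapply(parts, function(p) {
    if (length(p) >= 3L) p[[3]] else NA_character_
  }, character(1))
  data.frame(
    sequence_id = headers, species = gsub("_", " ", species),
    accession = accession, isoform = isoform, header = headers,
    stringsAsFactors = FALSE
  )
}

#' Read a multi-FASTA protein alignment
#'
#' @param path path to an aligned multi-FASTA file (gap character `-`).
#' @return An [ortholog_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty alignment file: ", path)
  ortholog_alignment(as.character(seqs), names(seqs))
}

#' Write an alignment back to multi-FASTA
#'
#' Round-trips losslessly with [read_alignment()].
#'
#' @param aln an [ortholog_alignment()].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- aln$meta$header
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Anchor reference residue coordinates on alignment columns
#'
#' Residue `i` (1-based, on the ungapped reference) maps to the alignment
#' column holding the i-th non-gap symbol of the reference row.
#'
#' @param aln an [ortholog_alignment()].
#' @param reference_id sequence id of the reference row (e.g. the human
#'   sequence).
#' @return A `reference_map`: list with `reference_id`,
#'   `residue_to_column` (integer vector, index = residue, value = 1-based
#'   column) and `column_to_residue` (integer vector over columns, `NA`
#'   where the reference is gapped).
#' @export
build_reference_map <- function(aln, reference_id) {
  idx <- match(reference_id, rownames(aln$matrix))
  if (is.na(idx)) stop("reference id not in alignment: ", reference_id)
  row <- aln$matrix[idx, ]
  cols <- which(row != "-")
  if (length(cols) == 0L) stop("reference row is all gaps")
  col_to_res <- rep(NA_integer_, length(row))
  col_to_res[cols] <- seq_along(cols)
  structure(
    list(reference_id = reference_id, residue_to_column = cols,
         column_to_residue = col_to_res),
    class = "reference_map"
  )
}

#' Modal (most frequent) symbol per alignment column
#'
#' Gaps count as an ordinary symbol. Ties are broken deterministically:
#' any amino acid beats the gap, and among tied amino acids the
#' lexicographically smallest one-letter code wins, so a tie never turns
#' a column gap-modal.
#'
#' @param aln an [ortholog_alignment()].
#' @return data.frame with `column`, `modal` (symbol), `count` and
#'   `gap_modal` (logical).
#' @export
modal_consensus <- function(aln) {
  cons <- apply(aln$matrix, 2L, function(col) {
    tab <- table(col)
    top <- names(tab)[tab == max(tab)]
    aa <- sort(setdiff(top, "-"))
    modal <- if (length(aa) > 0L) aa[1] else "-"
    c(modal = modal, count = as.character(max(tab)))
  })
  data.frame(
    column = seq_len(ncol(aln$matrix)),
    modal = unname(cons["modal", ]),
    count = as.integer(cons["count", ]),
    gap_modal = unname(cons["modal", ] == "-"),
    stringsAsFactors = FALSE
  )
}

#' Remove columns where the gap is the modal symbol
#'
#' @param aln an [ortholog_alignment()].
#' @param consensus output of [modal_consensus()] computed on `aln`.
#' @return list with `alignment` (filtered [ortholog_alignment()], or
#'   `NULL` when every column is gap-modal) and `retained_columns`
#'   (1-based original column indices, in order).
#' @export
drop_gap_modal_columns <- function(aln, consensus) {
  if (nrow(consensus) != aln$column_count) {
    stop("consensus does not match the alignment's column count")
  }
  keep <- which(!consensus$gap_modal)
  filtered <- if (length(keep) == 0L) NULL else {
    out <- aln
    out$matrix <- aln$matrix[, keep, drop = FALSE]
    out$column_count <- length(keep)
    out
  }
  list(alignment = filtered, retained_columns = keep)
}

#' Per-column consensus table export
#'
#' @param consensus output of [modal_consensus()].
#' @param path output TSV path.
#' @export
write_consensus <- function(consensus, path) {
  write.table(consensus, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
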
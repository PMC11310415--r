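#' Extract the KKRR-core motif of a sequence from the alignment
#'
#' Returns the symbols at the alignment columns of the reference residues
#' spanning the motif (default 82-85, the KKRR core of the NLS). Gaps are
#' preserved.
#'
#' @param aln an [ortholog_alignment()].
#' @param sequence_id row to extract from.
#' @param refmap a [build_reference_map()] result.
#' @param motif_domain a [domain_spec()] (default [kkrr_domain()]).
#' @return character scalar (length = motif width, may contain `-`/`X`).
#' @export
extract_motif <- function(aln, sequence_id, refmap,
                          motif_domain = kkrr_domain()) {
  idx <- match(sequence_id, rownames(aln$matrix))
  if (is.na(idx)) stop("sequence id not in alignment: ", sequence_id)
  res <- motif_domain$start:motif_domain$end
  if (max(res) > length(refmap$residue_to_column)) {
    stop("motif residues absent from the reference map")
  }
  cols <- refmap$residue_to_column[res]
  paste(aln$matrix[idx, cols], collapse = "")
}

#' Classify a 4-residue KKRR-core motif
#'
#' Classes: `intact` (exactly `KKRR`), `conservative` (every substitution
#' is to K or R, preserving basic character), `loss` (any substitution to
#' a non-basic residue, or a gap), `unknown` (contains `X`).
#'
#' @param motif 4-character string over the amino-acid alphabet plus
#'   `X` and `-`.
#' @return one of `"intact"`, `"conservative"`, `"loss"`, `"unknown"`.
#' @export
classify_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) != 4L) {
    stop("motif must be a single 4-character string")
  }
  chars <- strsplit(toupper(motif), "")[[1]]
  if (any(chars == "X")) return("unknown")
  if (identical(chars, c("K", "K", "R", "R"))) return("intact")
  if (any(chars == "-")) return("loss")
  subs <- chars[chars != c("K", "K", "R", "R")]
  if (all(subs %in% c("K", "R"))) "conservative" else "loss"
}

#' Motif calls for every sequence of an alignment
#'
#' @inheritParams extract_motif
#' @param reference_id reference row used to anchor coordinates.
#' @return data.frame with `sequence_id`, `species`, `motif`, `class` and
#'   `substitutions` (compact `pos:residue` list, `""` when intact).
#' @export
motif_table <- function(aln, reference_id, motif_domain = kkrr_domain()) {
  refmap <- build_reference_map(aln, reference_id)
  ref_motif <- strsplit("KKRR", "")[[1]]
  rows <- lapply(rownames(aln$matrix), function(id) {
    m <- extract_motif(aln, id, refmap, motif_domain)
    chars <- strsplit(m, "")[[1]]
    diffpos <- which(chars != ref_motif)
    data.frame(
      sequence_id = id,
      species = aln$meta$species[match(id, aln$meta$sequence_id)],
      motif = m,
      class = classify_motif(m),
      substitutions = paste(sprintf("%d:%s", diffpos, chars[diffpos]),
                            collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species NLS status from per-isoform motif calls
#'
#' A species is called `loss` only when every isoform call is `loss`;
#' disagreeing isoforms are flagged `mixed` for review. Unknown calls are
#' ignored unless they are all the species has.
#'
#' @param motif_calls output of [motif_table()].
#' @param conservative_as_intact treat conservative calls as intact-like.
#' @return data.frame with `species`, `status`
#'   (`intact`/`loss`/`mixed`/`unknown`), `n_isoforms`, `motifs`.
#' @export
call_species_status <- function(motif_calls, conservative_as_intact = TRUE) {
  intact_like <- if (conservative_as_intact) {
    c("intact", "conservative")
  } else "intact"
  rows <- lapply(split(motif_calls, motif_calls$species), function(d) {
    informative <- d$class[d$class != "unknown"]
    status <- if (length(informative) == 0L) {
      "unknown"
    } else if (all(informative == "loss")) {
      "loss"
    } else if (any(informative == "loss")) {
      "mixed"
    } else if (all(informative %in% intact_like)) {
      "intact"
    } else "mixed"
    data.frame(
      species = d$species[1], status = status, n_isoforms = nrow(d),
      motifs = paste(sort(unique(d$motif)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species), , drop = FALSE]
}

#' Monopartite NLS propensity (proxy score)
#'
#' A deliberately simple, fully documented stand-in for external NLS
#' predictors: over sliding windows of 8-13 residues, the score is the
#' fraction of basic residues (K or R) in the window, maximised over all
#' windows. Only the direction of comparisons between variants is
#' meaningful; the score is not a nuclear-import probability.
#'
#' @param sequence ungapped amino-acid string.
#' @param window_lengths integer vector of window widths (default 8:13).
#' @param motif_start,motif_end coordinates of the KKRR core on
#'   `sequence` (optional; used to report whether the best window covers
#'   the motif).
#' @return list with `score`, `best_window` (c(start, end), 1-based) and
#'   `contains_motif` (`NA` when no motif coordinates given). Ties go to
#'   the earliest, shortest window.
#' @export
nls_propensity <- function(sequence, window_lengths = 8:13,
                           motif_start = NA_integer_,
                           motif_end = NA_integer_) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  basic <- as.integer(chars %in% c("K", "R"))
  n <- length(basic)
  best <- list(score = 0, start = 1L, end = min(n, window_lengths[1]))
  cum <- c(0L, cumsum(basic))
  for (w in sort(window_lengths)) {
    if (w > n) next
    starts <- seq_len(n - w + 1L)
    scores <- (cum[starts + w] - cum[starts]) / w
    i <- which.max(scores)
    if (scores[i] > best$score + 1e-12) {
      best <- list(score = scores[i], start = starts[i],
                   end = starts[i] + w - 1L)
    }
  }
  contains <- if (is.na(motif_start) || is.na(motif_end)) NA else {
    best$start <= motif_start && best$end >= motif_end
  }
  list(score = best$score, best_window = c(best$start, best$end),
       contains_motif = contains)
}

#' Translate motif nucleotides to amino acids
#'
#' Standard genetic code; fuzzy codons (containing `N`) translate to `X`.
#' The length must be a multiple of 3.
#'
#' @param nt nucleotide string (case-insensitive).
#' @return amino-acid string.
#' @export
translate_codons <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3L != 0L) stop("length must be a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}
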
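#' Domain specification on reference coordinates
#'
#' Named 1-based inclusive interval on the ungapped reference residue
#' numbering. Defaults follow the human pro-IL-1alpha pro-domain layout:
#' N-terminal HAT-binding domain 7-19, NLS 78-90 (KKRR core 82-85),
#' second HAT-binding domain 98-108, whole pro-domain 1-112.
#'
#' @param name domain label.
#' @param start,end 1-based inclusive reference residues.
#' @return A `domain_spec` (list with `name`, `start`, `end`).
#' @export
domain_spec <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid domain interval: need 1 <= start <= end")
  }
  structure(list(name = name, start = start, end = end),
            class = "domain_spec")
}

#' @rdname domain_spec
#' @export
default_domains <- function() {
  list(
    HAT1 = domain_spec("HAT1", 7, 19),
    NLS = domain_spec("NLS", 78, 90),
    HAT2 = domain_spec("HAT2", 98, 108),
    PRO = domain_spec("PRO", 1, 112)
  )
}

#' KKRR core of the NLS (reference residues 82-85)
#' @export
kkrr_domain <- function() domain_spec("KKRR", 82, 85)

#' Binary match profile of a sequence against the modal consensus
#'
#' A position scores 1 only on exact amino-acid identity with the modal
#' amino acid. A gap in the scored row, a gap-modal column, or an `X` on
#' either side is always a mismatch (an `X` call carries no evidence of
#' conservation).
#'
#' @param aln an [ortholog_alignment()].
#' @param sequence_id row to profile.
#' @param consensus output of [modal_consensus()] on `aln`.
#' @param retained_columns 1-based columns surviving gap-modal removal
#'   (default: all non-gap-modal columns of `consensus`).
#' @return integer vector of 0/1 over `retained_columns` (named by
#'   original column index).
#' @export
match_profile <- function(aln, sequence_id, consensus,
                          retained_columns = which(!consensus$gap_modal)) {
  idx <- match(sequence_id, rownames(aln$matrix))
  if (is.na(idx)) stop("sequence id not in alignment: ", sequence_id)
  if (nrow(consensus) != aln$column_count) {
    stop("consensus does not match the alignment's column count")
  }
  row <- aln$matrix[idx, retained_columns]
  modal <- consensus$modal[retained_columns]
  prof <- as.integer(row == modal & !(modal %in% c("-", "X")) & row != "X")
  names(prof) <- retained_columns
  prof
}

#' Fraction of a domain matching the modal consensus
#'
#' The denominator is the number of domain columns that survived
#' gap-modal removal (the columns actually shown in a conservation
#' barcode); the pre-filter width is also reported.
#'
#' @param profile output of [match_profile()].
#' @param domain a [domain_spec()].
#' @param refmap a [build_reference_map()] result.
#' @return list with `domain`, `matched`, `total` (surviving columns),
#'   `total_prefilter` (domain width in residues), `fraction` (`NA` with
#'   `defined = FALSE` when no domain column survives).
#' @export
domain_conservation <- function(profile, domain, refmap) {
  res <- domain$start:domain$end
  if (max(res) > length(refmap$residue_to_column)) {
    stop(sprintf("domain %s extends past the reference (%d residues)",
                 domain$name, length(refmap$residue_to_column)))
  }
  cols <- refmap$residue_to_column[res]
  keep <- as.character(cols)[as.character(cols) %in% names(profile)]
  total <- length(keep)
  matched <- if (total > 0L) sum(profile[keep]) else 0L
  list(
    domain = domain$name,
    matched = matched,
    total = total,
    total_prefilter = length(res),
    fraction = if (total > 0L) matched / total else NA_real_,
    defined = total > 0L
  )
}

#' Per-sequence, per-domain conservation table
#'
#' @param aln an [ortholog_alignment()].
#' @param reference_id reference row for coordinates.
#' @param domains list of [domain_spec()] (default [default_domains()]).
#' @param collapse_species if `TRUE`, keep one sequence per species (the
#'   one with most non-gap residues, ties by id).
#' @return data.frame with one row per (sequence, domain):
#'   `sequence_id`, `species`, `domain`, `matched`, `total`, `fraction`.
#' @export
conservation_table <- function(aln, reference_id,
                               domains = default_domains(),
                               collapse_species = FALSE) {
  consensus <- modal_consensus(aln)
  retained <- which(!consensus$gap_modal)
  refmap <- build_reference_map(aln, reference_id)
  ids <- rownames(aln$matrix)
  if (collapse_species) {
    nres <- rowSums(aln$matrix != "-")
    ord <- order(aln$meta$species, -nres, aln$meta$sequence_id)
    ids <- aln$meta$sequence_id[ord][!duplicated(aln$meta$species[ord])]
  }
  rows <- lapply(ids, function(id) {
    prof <- match_profile(aln, id, consensus, retained)
    do.call(rbind, lapply(domains, function(dm) {
      dc <- domain_conservation(prof, dm, refmap)
      data.frame(
        sequence_id = id,
        species = aln$meta$species[match(id, aln$meta$sequence_id)],
        domain = dc$domain, matched = dc$matched, total = dc$total,
        fraction = dc$fraction, stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise conservation by NLS-status group
#'
#' Sequences are grouped by their motif class (see [classify_motif()]):
#' `intact_NLS` for intact (and, by default, conservative) calls,
#' `mutant_NLS` for loss calls, `other` for unknown.
#'
#' @param cons_table output of [conservation_table()].
#' @param motif_calls data.frame with `sequence_id` and `class` (from
#'   [motif_table()]).
#' @param conservative_as_intact treat conservative (K/R-preserving)
#'   substitutions as intact-like (default `TRUE`).
#' @return data.frame with one row per (group, domain): `n`, `mean`,
#'   `median`, `iqr`. Empty groups are omitted with a warning.
#' @export
group_summary <- function(cons_table, motif_calls,
                          conservative_as_intact = TRUE) {
  cls <- motif_calls$class[match(cons_table$sequence_id,
                                 motif_calls$sequence_id)]
  if (anyNA(cls)) stop("every profiled sequence needs a motif call")
  intact_like <- if (conservative_as_intact) {
    c("intact", "conservative")
  } else "intact"
  group <- ifelse(cls %in% intact_like, "intact_NLS",
                  ifelse(cls == "loss", "mutant_NLS", "other"))
  tab <- cons_table
  tab$group <- group
  tab <- tab[!is.na(tab$fraction), , drop = FALSE]
  present <- unique(tab$group)
  absent <- setdiff(c("intact_NLS", "mutant_NLS"), present)
  if (length(absent) > 0L) {
    warning("empty group(s) omitted: ", paste(absent, collapse = ", "))
  }
  agg <- lapply(split(tab, list(tab$group, tab$domain), drop = TRUE),
                function(d) {
    data.frame(
      group = d$group[1], domain = d$domain[1], n = nrow(d),
      mean = mean(d$fraction), median = median(d$fraction),
      iqr = unname(quantile(d$fraction, 0.75) - quantile(d$fraction, 0.25)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$domain, out$group), , drop = FALSE]
}
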
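#' Read a MaxQuant proteinGroups-dialect table
#'
#' Expects a protein id column, per-sample `LFQ intensity <name>`
#' columns, and `+`-coded flag columns (`Potential contaminant`,
#' `Reverse`, `Only identified by site`). Zeros and `NaN` in LFQ columns
#' are treated as missing (MaxQuant writes 0 for absent LFQ).
#'
#' @param path TSV path.
#' @param id_column protein id column name (default `"Protein IDs"`).
#' @param lfq_prefix prefix of intensity columns.
#' @param zero_is_missing treat 0 as missing (default `TRUE`).
#' @return An `intensity_table`: list with `intensities` (proteins x
#'   samples matrix, `NA` = missing), `flags` (logical data.frame with
#'   `contaminant`, `reverse`, `only_by_site`) and `protein_ids`.
#' @export
read_proteingroups <- function(path, id_column = "Protein IDs",
                               lfq_prefix = "LFQ intensity ",
                               zero_is_missing = TRUE) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lfq_cols <- grep(paste0("^", lfq_prefix), names(raw), value = TRUE)
  if (length(lfq_cols) == 0L) stop("no '", lfq_prefix, "' columns found")
  mat <- as.matrix(raw[, lfq_cols, drop = FALSE])
  mode(mat) <- "numeric"
  if (zero_is_missing) mat[mat == 0] <- NA_real_
  mat[is.nan(mat)] <- NA_real_
  colnames(mat) <- sub(lfq_prefix, "", lfq_cols, fixed = TRUE)
  rownames(mat) <- raw[[id_column]]
  plus_flag <- function(col) {
    if (!col %in% names(raw)) return(rep(FALSE, nrow(raw)))
    v <- raw[[col]] == "+" # an all-empty column reads as logical NA
    !is.na(v) & v
  }
  flags <- data.frame(
    contaminant = plus_flag("Potential contaminant"),
    reverse = plus_flag("Reverse"),
    only_by_site = plus_flag("Only identified by site")
  )
  intensity_table(mat, flags)
}

#' Construct an intensity table from a matrix
#'
#' @param intensities proteins x samples numeric matrix (`NA` missing).
#' @param flags optional logical data.frame (`contaminant`, `reverse`,
#'   `only_by_site`); defaults to all-`FALSE`.
#' @return An `intensity_table`.
#' @export
intensity_table <- function(intensities, flags = NULL) {
  if (is.null(flags)) {
    flags <- data.frame(
      contaminant = rep(FALSE, nrow(intensities)),
      reverse = rep(FALSE, nrow(intensities)),
      only_by_site = rep(FALSE, nrow(intensities))
    )
  }
  stopifnot(nrow(flags) == nrow(intensities))
  structure(
    list(intensities = intensities, flags = flags,
         protein_ids = rownames(intensities)),
    class = "intensity_table"
  )
}

#' Remove contaminant, reverse and only-identified-by-site rows
#'
#' @param x an `intensity_table`.
#' @return `x` with flagged rows removed; attribute `removed` carries the
#'   per-flag removal counts.
#' @export
filter_rows <- function(x) {
  bad <- x$flags$contaminant | x$flags$reverse | x$flags$only_by_site
  out <- intensity_table(x$intensities[!bad, , drop = FALSE],
                         x$flags[!bad, , drop = FALSE])
  attr(out, "removed") <- c(
    contaminant = sum(x$flags$contaminant),
    reverse = sum(x$flags$reverse),
    only_by_site = sum(x$flags$only_by_site),
    total = sum(bad)
  )
  out
}

#' Log2-transform intensities (missing stays missing)
#'
#' @param x an `intensity_table` of raw positive intensities.
#' @return `x` on the log2 scale.
#' @export
log2_transform <- function(x) {
  if (any(x$intensities <= 0, na.rm = TRUE)) {
    stop("non-positive intensities present; cannot log2-transform")
  }
  x$intensities <- log2(x$intensities)
  x
}

#' Keep rows fully observed in at least one group
#'
#' The published rule: a row is kept when at least one experimental group
#' has a valid value in all of its replicates (`min_valid` generalises
#' the "all replicates" requirement).
#'
#' @param x an `intensity_table`.
#' @param groups character vector over samples (two levels).
#' @param min_valid minimum valid values required in some one group
#'   (default: that group's size).
#' @return filtered `intensity_table`.
#' @export
validity_filter <- function(x, groups, min_valid = NULL) {
  groups <- check_groups(x, groups)
  keep <- rep(FALSE, nrow(x$intensities))
  for (g in levels(groups)) {
    cols <- which(groups == g)
    need <- if (is.null(min_valid)) length(cols) else min(min_valid, length(cols))
    keep <- keep | rowSums(!is.na(x$intensities[, cols, drop = FALSE])) >= need
  }
  intensity_table(x$intensities[keep, , drop = FALSE],
                  x$flags[keep, , drop = FALSE])
}

check_groups <- function(x, groups) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(x$intensities)) {
    stop("need one group label per sample column")
  }
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  groups
}

#' Downshifted-normal imputation of missing values
#'
#' Per sample column, missing entries are drawn from
#' `Normal(mean - downshift * SD, (width * SD)^2)` computed from that
#' column's observed log2 values - the standard left-censored
#' missing-not-at-random model for LFQ data (Perseus defaults:
#' width 0.3, downshift 1.8).
#'
#' @param x an `intensity_table` on the log2 scale.
#' @param width imputation SD as a fraction of the column SD.
#' @param downshift imputation mean shift in column SDs.
#' @param seed integer seed (reproducible imputation).
#' @return complete `intensity_table`.
#' @export
impute <- function(x, width = 0.3, downshift = 1.8, seed = 1L) {
  mat <- x$intensities
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j][!is.na(mat[, j])]
    miss <- which(is.na(mat[, j]))
    if (length(miss) == 0L) next
    if (length(obs) < 2L) {
      stop("column ", colnames(mat)[j], " has fewer than 2 observed values")
    }
    mu <- mean(obs) - downshift * sd(obs)
    mat[miss, j] <- rnorm(length(miss), mu, width * sd(obs))
  }
  x$intensities <- mat
  x
}

#' PCA of samples over protein features
#'
#' Samples are projected on the principal components of the centred
#' protein features (deterministic up to component sign).
#'
#' @param x a complete `intensity_table` (post-imputation).
#' @return list with `coordinates` (samples x PCs) and
#'   `explained_variance` (fractions).
#' @export
sample_pca <- function(x) {
  mat <- x$intensities
  if (ncol(mat) < 2L) stop("PCA needs at least two samples")
  if (anyNA(mat)) stop("PCA needs a complete matrix; impute first")
  p <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  list(
    coordinates = p$x,
    explained_variance = if (tot > 0) p$sdev^2 / tot else rep(0, length(p$sdev))
  )
}

#' s0-moderated two-sample statistic
#'
#' `d = (mean1 - mean2) / (se + s0)` where `se` is the pooled-variance
#' standard error of the classical two-sample t statistic and `s0` the
#' SAM-style variance-stabilising constant (`s0 = 0` recovers the
#' classical t exactly). Zero within-group variance with `s0 = 0` yields
#' `Inf` with the sign of the difference.
#'
#' @param mat proteins x samples matrix (complete, log2 scale).
#' @param groups two-level factor over samples; `d > 0` means higher in
#'   the first level.
#' @param s0 non-negative moderation constant (default 2).
#' @return list with `d`, `difference` (mean1 - mean2) and `se`.
#' @export
s0_test <- function(mat, groups, s0 = 2) {
  stopifnot(s0 >= 0)
  groups <- as.factor(groups)
  g1 <- which(groups == levels(groups)[1])
  g2 <- which(groups == levels(groups)[2])
  if (length(g1) < 2L || length(g2) < 2L) stop("each group needs >= 2 samples")
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  v1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  s2p <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(s2p * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  d <- diff / (se + s0)
  d[se + s0 == 0] <- sign(diff[se + s0 == 0]) * Inf
  list(d = d, difference = diff, se = se)
}

# All balanced relabelings of a two-group design, one per complement
# pair (4v4: 35, including the observed labelling, which callers drop
# from the null set). Columns give the samples assigned to group 1.
balanced_permutations <- function(groups, max_perms = 1000L, seed = 1L) {
  groups <- as.factor(groups)
  g1 <- which(groups == levels(groups)[1])
  n <- length(groups)
  all_sets <- combn(n, length(g1))
  if (2L * length(g1) == n) {
    # complement-invariance: keep the representative containing sample 1
    all_sets <- all_sets[, all_sets[1, ] == 1L, drop = FALSE]
    if (!(1L %in% g1)) {
      # re-key the observed labelling to its representative
      g1 <- sort(setdiff(seq_len(n), g1))
    }
  }
  if (ncol(all_sets) > max_perms) {
    set.seed(as.integer(seed))
    obs_col <- which(apply(all_sets, 2L, identical, as.integer(g1)))
    keep <- sample(setdiff(seq_len(ncol(all_sets)), obs_col),
                   max_perms - 1L)
    all_sets <- all_sets[, c(obs_col, keep), drop = FALSE]
  }
  list(sets = all_sets, observed = as.integer(sort(g1)))
}

#' Permutation-based FDR control on the moderated statistic
#'
#' Builds the null distribution of `d` from balanced group relabelings
#' (all 35 for a 4v4 design, enumerated exhaustively; the observed
#' labelling is excluded from the null set; larger designs are
#' subsampled with the seed). A symmetric cut on `|d|` is chosen as the
#' smallest value whose estimated FDR - pi0-adjusted mean permutation
#' false positives over observed positives - does not exceed the target.
#'
#' @param mat complete proteins x samples matrix (log2 scale).
#' @param groups two-level factor; the first level is the target group.
#' @param s0 moderation constant (default 2).
#' @param fdr target FDR (default 0.01).
#' @param seed seed for permutation subsampling.
#' @param max_perms permutation budget for designs larger than 4v4.
#' @return list with `d`, `difference`, `threshold` (`Inf` when no cut
#'   achieves the target), `significant` (logical), `direction`
#'   (`"target"`/`"control"`), `p_analogue` (pooled permutation p-value),
#'   `pi0`, `n_permutations`.
#' @export
permutation_fdr <- function(mat, groups, s0 = 2, fdr = 0.01, seed = 1L,
                            max_perms = 1000L) {
  stopifnot(fdr > 0, fdr <= 1)
  groups <- as.factor(groups)
  obs <- s0_test(mat, groups, s0)
  perms <- balanced_permutations(groups, max_perms, seed)
  n <- ncol(mat)
  null_d <- lapply(seq_len(ncol(perms$sets)), function(k) {
    set1 <- perms$sets[, k]
    if (identical(set1, perms$observed)) return(NULL)
    relab <- factor(ifelse(seq_len(n) %in% set1, "g1", "g2"),
                    levels = c("g1", "g2"))
    s0_test(mat, relab, s0)$d
  })
  null_d <- null_d[!vapply(null_d, is.null, logical(1))]
  n_perm <- length(null_d)
  if (n_perm == 0L) stop("no non-observed balanced relabelings available")
  pooled <- abs(unlist(null_d))
  m <- nrow(mat)
  # pi0: fraction of observed d inside the central null quartiles
  qn <- quantile(unlist(null_d), c(0.25, 0.75))
  pi0 <- min(1, sum(obs$d >= qn[1] & obs$d <= qn[2]) / (0.5 * m))
  abs_d <- abs(obs$d)
  cuts <- sort(unique(abs_d[is.finite(abs_d) & abs_d > 0]))
  sorted_pooled <- sort(pooled)
  threshold <- Inf
  m_tested <- length(abs_d)
  if (fdr < pi0 / ((n_perm + 1) * m_tested)) {
    warning(sprintf(
      "%d permutations cannot resolve FDR %.3g; smallest achievable is %.3g",
      n_perm, fdr, pi0 / ((n_perm + 1) * m_tested)
    ))
  }
  for (cut in cuts) {
    pos <- sum(abs_d >= cut)
    # add-one smoothed mean false positives per permutation: with B
    # permutations the smallest estimable FDR for a single call is
    # 1 / (B + 1), which keeps the top-of-null-range call honest
    n_exceed <- length(sorted_pooled) -
      findInterval(cut - 1e-12, sorted_pooled)
    fp_mean <- (n_exceed + 1) / (n_perm + 1)
    if (pos > 0 && pi0 * fp_mean / pos <= fdr) {
      threshold <- cut
      break
    }
  }
  significant <- abs_d >= threshold
  p_analogue <- (1 + vapply(abs_d, function(v) sum(pooled >= v),
                            numeric(1))) / (1 + length(pooled))
  list(
    d = obs$d, difference = obs$difference, threshold = threshold,
    significant = significant,
    direction = ifelse(obs$difference >= 0, "target", "control"),
    p_analogue = p_analogue, pi0 = unname(pi0), n_permutations = n_perm,
    fdr_resolution = 1 / (n_perm + 1)
  )
}

#' Run the full Perseus-style enrichment pipeline
#'
#' Fixed stage order: row flags filter, log2 transform, validity filter,
#' downshifted-normal imputation, then PCA and the s0/permutation-FDR
#' test. Stage-by-stage row counts, the achieved threshold and the full
#' configuration are recorded in the run summary.
#'
#' @param x an `intensity_table` of raw intensities (e.g. from
#'   [read_proteingroups()]).
#' @param groups two-level factor over sample columns; first level =
#'   target (enriched) group.
#' @param s0,fdr,width,downshift,seed see [permutation_fdr()] and
#'   [impute()].
#' @param log2_transformed set `TRUE` when `x` already holds log2 values.
#' @return An `enrich_result`: list with `results` (per-protein
#'   data.frame), `pca`, `summary` (counts, threshold, config) and
#'   `n_enriched` (significant, target-direction count).
#' @export
enrich_pipeline <- function(x, groups, s0 = 2, fdr = 0.01, width = 0.3,
                            downshift = 1.8, seed = 1L,
                            log2_transformed = FALSE) {
  groups <- check_groups(x, groups)
  counts <- c(input = nrow(x$intensities))
  x <- filter_rows(x)
  counts["after_flag_filter"] <- nrow(x$intensities)
  if (!log2_transformed) x <- log2_transform(x)
  x <- validity_filter(x, groups)
  counts["after_validity_filter"] <- nrow(x$intensities)
  x <- impute(x, width, downshift, seed)
  pca <- sample_pca(x)
  test <- permutation_fdr(x$intensities, groups, s0, fdr, seed)
  results <- data.frame(
    protein_id = rownames(x$intensities),
    difference = test$difference,
    d = test$d,
    p_analogue = test$p_analogue,
    neg_log10_p = -log10(test$p_analogue),
    significant = test$significant,
    direction = test$direction,
    stringsAsFactors = FALSE
  )
  rownames(results) <- NULL
  n_enriched <- sum(results$significant & results$direction == "target")
  structure(
    list(
      results = results, pca = pca, n_enriched = n_enriched,
      summary = list(
        counts = as.list(counts), threshold = test$threshold,
        pi0 = test$pi0, n_permutations = test$n_permutations,
        config = list(s0 = s0, fdr = fdr, width = width,
                      downshift = downshift, seed = seed,
                      target_group = levels(groups)[1])
      )
    ),
    class = "enrich_result"
  )
}

#' @export
print.enrich_result <- function(x, ...) {
  cat(sprintf(
    "enrich_result: %d proteins tested, %d significant (%d target-enriched), |d| threshold %.3f\n",
    nrow(x$results), sum(x$results$significant), x$n_enriched,
    x$summary$threshold
  ))
  invisible(x)
}

#' Export volcano-plot-ready table
#'
#' @param result an `enrich_result`.
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
volcano_export <- function(result, path = NULL) {
  out <- result$results[, c("protein_id", "difference", "neg_log10_p",
                            "significant", "direction")]
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
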
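#' Demo clade table mirroring the mammalian study design
#'
#' Species grouped into clades with per-species depth multipliers
#' (arbitrary time units; the effective per-site substitution probability
#' on a branch of depth `t` is `1 - (1 - p)^t`). Includes the lineages
#' with convergent NLS loss (castorimorpha, toothed whales, Australasian
#' marsupials) plus background placental clades and monotremes.
#'
#' @return data.frame with `species`, `clade`, `depth`.
#' @export
mammal_demo_clades <- function() {
  mk <- function(clade, species, depth) {
    data.frame(species = species, clade = clade, depth = depth,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("primates", c("sim_human", "sim_chimp", "sim_macaque"), 1),
    mk("carnivora", c("sim_dog", "sim_cat", "sim_bear"), 1),
    mk("myomorpha", c("sim_mouse", "sim_rat", "sim_hamster"), 1),
    mk("castorimorpha", c("sim_beaver", "sim_kangaroo_rat",
                          "sim_pocket_gopher", "sim_pocket_mouse"), 1),
    mk("mysticeti", c("sim_blue_whale", "sim_fin_whale"), 1),
    mk("odontoceti", c("sim_orca", "sim_sperm_whale", "sim_dolphin"), 1),
    mk("marsupialia", c("sim_koala", "sim_tasmanian_devil",
                        "sim_brushtail", "sim_opossum"), 2),
    mk("monotremata", c("sim_platypus", "sim_echidna"), 3)
  )
}

#' Configuration for the ortholog-family simulator
#'
#' @param clades data.frame with `species`, `clade` and optional `depth`
#'   (default 1) - a flat encoding of the species tree.
#' @param p_background,p_hat,p_nls per-site substitution probabilities
#'   (at depth 1) outside any domain, in the HAT-binding domains, and in
#'   the NLS.
#' @param knockouts named list `clade -> motif` (e.g.
#'   `list(castorimorpha = "KKRW", odontoceti = "KNRW")`): every species
#'   of the clade carries the replacement at the KKRR core (82-85).
#' @param indel_rate per-species probability of one short deletion
#'   (rendered as gaps; the simulator never inserts columns).
#' @param seed integer seed.
#' @return a `family_sim_config` list.
#' @export
family_sim_config <- function(clades = mammal_demo_clades(),
                              p_background = 0.2, p_hat = 0.02,
                              p_nls = 0.02, knockouts = list(),
                              indel_rate = 0, seed = 1L) {
  stopifnot(all(c("species", "clade") %in% names(clades)))
  if (is.null(clades$depth)) clades$depth <- 1
  probs <- c(p_background, p_hat, p_nls)
  if (any(probs < 0 | probs > 1)) stop("substitution probabilities must be in [0,1]")
  missing_clades <- setdiff(names(knockouts), clades$clade)
  if (length(missing_clades) > 0L) {
    stop("knockout clade(s) not in the tree: ",
         paste(missing_clades, collapse = ", "))
  }
  structure(
    list(clades = clades, p_background = p_background, p_hat = p_hat,
         p_nls = p_nls, knockouts = knockouts, indel_rate = indel_rate,
         seed = as.integer(seed)),
    class = "family_sim_config"
  )
}

#' Simulate an ortholog family with domain-structured conservation
#'
#' Evolves a fixed synthetic 112-residue ancestral pro-domain (human
#' domain layout: HAT1 7-19, NLS 78-90 with the KKRR core at 82-85,
#' HAT2 98-108) independently down each branch: every site substitutes
#' with its domain's effective probability, replacements drawn uniformly
#' over the 19 alternative residues. Knockout clades then carry the
#' configured motif at 82-85. A reference row (`reference|REF|1`,
#' species "reference") holds the unmutated ancestor so coordinates can
#' be anchored.
#'
#' @param config a [family_sim_config()].
#' @return list with `alignment` (an [ortholog_alignment()]) and `truth`
#'   (data.frame: `species`, `clade`, `motif`, `class`, and per-domain
#'   expected conservation `expected_HAT1`, `expected_NLS`,
#'   `expected_HAT2`, `expected_PRO`).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "family_sim_config"))
  set.seed(config$seed)
  anc <- strsplit(.ancestral_prodomain, "")[[1]]
  L <- length(anc)
  doms <- default_domains()
  site_domain <- rep("background", L)
  site_domain[doms$HAT1$start:doms$HAT1$end] <- "hat"
  site_domain[doms$HAT2$start:doms$HAT2$end] <- "hat"
  site_domain[doms$NLS$start:doms$NLS$end] <- "nls"
  p_site <- c(background = config$p_background, hat = config$p_hat,
              nls = config$p_nls)[site_domain]
  kkrr <- kkrr_domain()
  clades <- config$clades
  seqs <- character(nrow(clades))
  truth_motif <- character(nrow(clades))
  exp_cons <- matrix(NA_real_, nrow(clades), 4,
                     dimnames = list(NULL, c("HAT1", "NLS", "HAT2", "PRO")))
  for (i in seq_len(nrow(clades))) {
    p_eff <- 1 - (1 - p_site)^clades$depth[i]
    s <- anc
    hit <- runif(L) < p_eff
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(a) {
        sample(setdiff(.amino_acids, a), 1L)
      }, character(1))
    }
    ko <- config$knockouts[[clades$clade[i]]]
    if (!is.null(ko)) {
      s[kkrr$start:kkrr$end] <- strsplit(ko, "")[[1]]
    }
    if (config$indel_rate > 0 && runif(1) < config$indel_rate) {
      len <- sample(1:3, 1L)
      at <- sample(L - len + 1L, 1L)
      s[at:(at + len - 1L)] <- "-"
    }
    seqs[i] <- paste(s, collapse = "")
    truth_motif[i] <- paste(s[kkrr$start:kkrr$end], collapse = "")
    for (dm in names(doms)) {
      span <- doms[[dm]]$start:doms[[dm]]$end
      exp_cons[i, dm] <- mean(1 - p_eff[span])
    }
  }
  headers <- c(
    "reference|REF|1",
    sprintf("%s|ACC%03d|1", gsub(" ", "_", clades$species),
            seq_len(nrow(clades)))
  )
  aln <- ortholog_alignment(c(.ancestral_prodomain, seqs), headers)
  truth <- data.frame(
    # species labels as they come back from the header convention
    species = gsub("_", " ", clades$species),
    clade = clades$clade, motif = truth_motif,
    class = vapply(truth_motif, classify_motif, character(1)),
    stringsAsFactors = FALSE
  )
  truth <- cbind(truth, as.data.frame(exp_cons,
                                      col.names = paste0("expected_",
                                                         colnames(exp_cons))))
  names(truth)[5:8] <- paste0("expected_", colnames(exp_cons))
  rownames(truth) <- NULL
  list(alignment = aln, truth = truth)
}

#' Configuration for the read simulator
#'
#' @param reference exon nucleotide string (default: built-in synthetic
#'   180-nt exon with the KKRR codons `aagaagagacgg` at 100-111).
#' @param variants data.frame with `pos`, `base` substitutions applied to
#'   the reference before reads are sampled.
#' @param read_length,n_reads read geometry.
#' @param error_rate per-base substitution error in `[0, 0.5)`.
#' @param revcomp_frac fraction of reads reverse-complemented.
#' @param seed integer seed.
#' @return a `read_sim_config` list.
#' @export
read_sim_config <- function(reference = demo_exon(), variants = NULL,
                            read_length = 70L, n_reads = 200L,
                            error_rate = 0.01, revcomp_frac = 0.5,
                            seed = 1L) {
  if (error_rate < 0 || error_rate >= 0.5) stop("error rate must be in [0, 0.5)")
  if (read_length > nchar(reference)) {
    stop("read length exceeds the reference length")
  }
  if (!is.null(variants)) {
    stopifnot(all(c("pos", "base") %in% names(variants)))
    if (any(variants$pos < 1 | variants$pos > nchar(reference))) {
      stop("variant positions outside the reference")
    }
  }
  structure(
    list(reference = toupper(reference), variants = variants,
         read_length = as.integer(read_length),
         n_reads = as.integer(n_reads), error_rate = error_rate,
         revcomp_frac = revcomp_frac, seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

#' Built-in synthetic exon and its motif interval
#' @return `demo_exon()`: the 180-nt exon string; `demo_exon_motif()`:
#'   c(start, end) of the KKRR codons on it (1-based inclusive).
#' @export
demo_exon <- function() .demo_exon

#' @rdname demo_exon
#' @export
demo_exon_motif <- function() c(.demo_exon_motif_start, .demo_exon_motif_end)

#' Simulate sequencing reads over an exon
#'
#' Reads are uniform substrings of the (variant-substituted) reference;
#' per-base errors substitute a uniformly drawn different base; a
#' configured fraction is reverse-complemented.
#'
#' @param config a [read_sim_config()].
#' @param fastq_path optional path; when given the reads are also written
#'   as FASTA-quality-free FASTQ (constant quality `I`).
#' @return list with `reads` (named character vector), `truth` (list with
#'   the mutated reference, variant positions and error rate) and
#'   `fastq_path`.
#' @export
simulate_reads <- function(config, fastq_path = NULL) {
  stopifnot(inherits(config, "read_sim_config"))
  set.seed(config$seed)
  ref <- strsplit(config$reference, "")[[1]]
  if (!is.null(config$variants)) {
    ref[config$variants$pos] <- toupper(config$variants$base)
  }
  L <- length(ref)
  bases <- c("A", "C", "G", "T")
  starts <- sample.int(L - config$read_length + 1L, config$n_reads,
                       replace = TRUE)
  reads <- vapply(starts, function(s) {
    r <- ref[s:(s + config$read_length - 1L)]
    err <- runif(config$read_length) < config$error_rate
    if (any(err)) {
      r[err] <- vapply(r[err], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    }
    paste(r, collapse = "")
  }, character(1))
  rc <- runif(config$n_reads) < config$revcomp_frac
  reads[rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads[rc])
  ))
  names(reads) <- sprintf("read%04d", seq_along(reads))
  if (!is.null(fastq_path)) {
    x <- Biostrings::DNAStringSet(reads)
    Biostrings::writeXStringSet(
      x, fastq_path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads)))
    )
  }
  list(
    reads = reads,
    truth = list(reference_mutated = paste(ref, collapse = ""),
                 variants = config$variants,
                 error_rate = config$error_rate, strands = ifelse(rc, "-", "+")),
    fastq_path = fastq_path
  )
}

#' Configuration for the LFQ matrix simulator
#'
#' @param n_proteins,n_enriched matrix size and number of proteins
#'   shifted up in the target group.
#' @param effect log2 shift of enriched proteins (target - control).
#' @param sd_within replicate noise SD (log2 units).
#' @param group_sizes c(target, control) replicate counts.
#' @param baseline_mean,baseline_sd protein-level log2 abundance
#'   distribution.
#' @param missing_mid,missing_scale intensity-dependent (left-censored)
#'   missingness: `P(missing) = plogis((missing_mid - x) / missing_scale)`
#'   for true log2 intensity `x`.
#' @param contaminant_frac,reverse_frac fractions of extra rows flagged
#'   as contaminants / reverse hits.
#' @param seed integer seed.
#' @return an `lfq_sim_config` list.
#' @export
lfq_sim_config <- function(n_proteins = 1000L, n_enriched = 50L,
                           effect = 4, sd_within = 0.5,
                           group_sizes = c(4L, 4L),
                           baseline_mean = 25, baseline_sd = 2,
                           missing_mid = 20, missing_scale = 1,
                           contaminant_frac = 0.02, reverse_frac = 0.01,
                           seed = 1L) {
  stopifnot(n_enriched <= n_proteins, all(group_sizes >= 2L))
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_enriched = as.integer(n_enriched), effect = effect,
         sd_within = sd_within, group_sizes = as.integer(group_sizes),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         missing_mid = missing_mid, missing_scale = missing_scale,
         contaminant_frac = contaminant_frac, reverse_frac = reverse_frac,
         seed = as.integer(seed)),
    class = "lfq_sim_config"
  )
}

#' Simulate a proteinGroups-dialect LFQ matrix
#'
#' Protein baselines are log-normal (normal on the log2 scale); enriched
#' proteins are shifted by `effect` in the target group; missingness is
#' intensity-dependent (logistic in the true log2 intensity, mimicking
#' left-censored LFQ missingness); flagged contaminant/reverse rows are
#' appended. Missing values are written as 0, the MaxQuant convention.
#'
#' @param config an [lfq_sim_config()].
#' @param path optional TSV output path (proteinGroups dialect).
#' @return list with `table` (an `intensity_table` of raw intensities),
#'   `groups` (factor, levels `target`, `control`), `truth` (data.frame
#'   with `protein_id`, `enriched`) and `path`.
#' @export
simulate_lfq <- function(config, path = NULL) {
  stopifnot(inherits(config, "lfq_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  n1 <- config$group_sizes[1]; n2 <- config$group_sizes[2]
  samples <- c(sprintf("Target_%d", seq_len(n1)),
               sprintf("Control_%d", seq_len(n2)))
  groups <- factor(rep(c("target", "control"), c(n1, n2)),
                   levels = c("target", "control"))
  baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
  enriched <- seq_len(config$n_enriched)
  truemat <- matrix(baseline, n, n1 + n2)
  truemat[enriched, seq_len(n1)] <- truemat[enriched, seq_len(n1)] +
    config$effect
  log2mat <- truemat + matrix(rnorm(n * (n1 + n2), 0, config$sd_within),
                              n, n1 + n2)
  p_miss <- plogis((config$missing_mid - truemat) / config$missing_scale)
  log2mat[matrix(runif(n * (n1 + n2)), n) < p_miss] <- NA_real_
  ids <- sprintf("PROT%04d", seq_len(n))
  n_con <- round(config$contaminant_frac * n)
  n_rev <- round(config$reverse_frac * n)
  extra <- matrix(
    rnorm((n_con + n_rev) * (n1 + n2), config$baseline_mean,
          config$baseline_sd),
    n_con + n_rev, n1 + n2
  )
  mat <- rbind(log2mat, extra)
  rownames(mat) <- c(ids,
                     if (n_con > 0) sprintf("CON_%03d", seq_len(n_con)),
                     if (n_rev > 0) sprintf("REV_%03d", seq_len(n_rev)))
  colnames(mat) <- samples
  flags <- data.frame(
    contaminant = c(rep(FALSE, n), rep(TRUE, n_con), rep(FALSE, n_rev)),
    reverse = c(rep(FALSE, n + n_con), rep(TRUE, n_rev)),
    only_by_site = rep(FALSE, n + n_con + n_rev)
  )
  raw <- 2^mat
  tab <- intensity_table(raw, flags)
  if (!is.null(path)) {
    df <- data.frame(`Protein IDs` = rownames(raw), check.names = FALSE,
                     stringsAsFactors = FALSE)
    lfq <- as.data.frame(ifelse(is.na(raw), 0, raw))
    names(lfq) <- paste0("LFQ intensity ", samples)
    df <- cbind(df, lfq)
    df$`Potential contaminant` <- ifelse(flags$contaminant, "+", "")
    df$Reverse <- ifelse(flags$reverse, "+", "")
    df$`Only identified by site` <- ifelse(flags$only_by_site, "+", "")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(
    table = tab, groups = groups,
    truth = data.frame(protein_id = ids,
                       enriched = seq_len(n) %in% enriched,
                       stringsAsFactors = FALSE),
    path = path
  )
}
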
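#' Derive a stage seed from the global run seed
#'
#' Deterministic, documented derivation (kept below 2^31) so any stage
#' can be re-run in isolation with the same randomness as inside
#' [run_pipeline()].
#'
#' @param seed global integer seed.
#' @param stage_index 1-based index of the stage in the run order.
#' @return integer stage seed.
#' @export
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 97 + 1000003 * stage_index) %% 2147483647)
}

#' Run pipeline stages end-to-end
#'
#' Executes the selected stages in dependency order, writing every
#' artefact under `out_dir` and a JSON run report (`report.json`) with
#' per-stage record counts, parameters and wall-clock. A stage failure
#' aborts downstream stages; the report records partial completion.
#' Data artefacts are bit-reproducible given (config, seed); the report
#' additionally carries timings.
#'
#' Recognised stages (run order): `simulate_family`, `consensus`,
#' `conserve`, `motif`, `simulate_reads`, `readvote`, `simulate_lfq`,
#' `enrich`.
#'
#' @param config a named list (or path to a YAML file) with optional
#'   blocks `stages` (character vector), `family` (passed to
#'   [family_sim_config()]), `reads` ([read_sim_config()]), `lfq`
#'   ([lfq_sim_config()]), `readvote` (`min_score`, `cap`), `enrich`
#'   (`s0`, `fdr`, `width`, `downshift`) and `reference_id` (default
#'   `"reference|REF|1"`).
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @return the run report (list), invisibly; written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate_family", "consensus", "conserve", "motif",
                  "simulate_reads", "readvote", "simulate_lfq", "enrich")
  stages <- if (is.null(config$stages)) all_stages else {
    unknown <- setdiff(config$stages, all_stages)
    if (length(unknown) > 0L) {
      stop("unknown stage(s): ", paste(unknown, collapse = ", "))
    }
    all_stages[all_stages %in% config$stages]
  }
  for (p in unlist(config$inputs)) {
    if (!file.exists(p)) stop("configured input path does not exist: ", p)
  }
  reference_id <- config$reference_id %||% "reference|REF|1"
  report <- list(seed = seed, stages = list())
  state <- new.env(parent = emptyenv())
  for (i in seq_along(stages)) {
    st <- stages[i]
    t0 <- Sys.time()
    rec <- tryCatch({
      counts <- run_stage(st, config, state, out_dir,
                          stage_seed(seed, match(st, all_stages)),
                          reference_id)
      list(stage = st, status = "ok", counts = counts,
           seed = stage_seed(seed, match(st, all_stages)))
    }, error = function(e) {
      list(stage = st, status = "error", message = conditionMessage(e))
    })
    rec$wall_clock_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    report$stages[[st]] <- rec
    if (identical(rec$status, "error")) {
      report$partial <- TRUE
      break
    }
  }
  report$config <- config
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(stage, config, state, out_dir, seed, reference_id) {
  switch(stage,
    simulate_family = {
      args <- config$family %||% list()
      args$seed <- seed
      fam <- simulate_family(do.call(family_sim_config, args))
      state$alignment <- fam$alignment
      write_alignment(fam$alignment, file.path(out_dir, "family.fasta"))
      write.table(fam$truth, file.path(out_dir, "family_truth.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(sequences = nrow(fam$alignment$matrix))
    },
    consensus = {
      aln <- require_state(state, "alignment", config)
      cons <- modal_consensus(aln)
      state$consensus <- cons
      write_consensus(cons, file.path(out_dir, "consensus.tsv"))
      list(columns = nrow(cons), gap_modal = sum(cons$gap_modal))
    },
    conserve = {
      aln <- require_state(state, "alignment", config)
      tab <- conservation_table(aln, reference_id)
      state$conservation <- tab
      write.table(tab, file.path(out_dir, "conservation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(rows = nrow(tab))
    },
    motif = {
      aln <- require_state(state, "alignment", config)
      calls <- motif_table(aln, reference_id)
      status <- call_species_status(calls)
      state$motif_calls <- calls
      write.table(calls, file.path(out_dir, "motif_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(status, file.path(out_dir, "species_status.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      list(sequences = nrow(calls), species = nrow(status),
           loss = sum(status$status == "loss"))
    },
    simulate_reads = {
      args <- config$reads %||% list()
      args$seed <- seed
      sim <- simulate_reads(do.call(read_sim_config, args),
                            fastq_path = file.path(out_dir, "reads.fastq"))
      state$reads <- sim$reads
      list(reads = length(sim$reads))
    },
    readvote = {
      reads <- require_state(state, "reads", config)
      rv_cfg <- config$readvote %||% list()
      motif_iv <- rv_cfg$motif %||% demo_exon_motif()
      rv <- read_vote(
        reads, rv_cfg$query %||% demo_exon(),
        motif_iv[1], motif_iv[2],
        reference_motif = rv_cfg$reference_motif %||% .kkrr_reference_nt,
        min_score = rv_cfg$min_score %||% 80,
        cap = rv_cfg$cap %||% 100
      )
      write.table(rv$vote_table, file.path(out_dir, "vote_table.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        rv$consensus[c("nt", "aa")],
        file.path(out_dir, "consensus_motif.json"), auto_unbox = TRUE
      )
      list(input_reads = rv$n_input_reads, hits = length(rv$hits),
           consensus_aa = rv$consensus$aa)
    },
    simulate_lfq = {
      args <- config$lfq %||% list()
      args$seed <- seed
      sim <- simulate_lfq(do.call(lfq_sim_config, args),
                          path = file.path(out_dir, "proteingroups.tsv"))
      state$lfq <- sim
      list(proteins = nrow(sim$table$intensities))
    },
    enrich = {
      lfq <- require_state(state, "lfq", config)
      en_cfg <- config$enrich %||% list()
      res <- enrich_pipeline(
        lfq$table, lfq$groups,
        s0 = en_cfg$s0 %||% 2, fdr = en_cfg$fdr %||% 0.01,
        width = en_cfg$width %||% 0.3,
        downshift = en_cfg$downshift %||% 1.8, seed = seed
      )
      volcano_export(res, file.path(out_dir, "volcano.tsv"))
      write.table(
        data.frame(sample = rownames(res$pca$coordinates),
                   res$pca$coordinates[, 1:2, drop = FALSE]),
        file.path(out_dir, "pca.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      jsonlite::write_json(res$summary, file.path(out_dir, "enrich_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      list(tested = nrow(res$results), enriched = res$n_enriched)
    },
    stop("unknown stage: ", stage)
  )
}

require_state <- function(state, what, config) {
  if (is.null(state[[what]])) {
    # allow running downstream stages on externally supplied inputs
    path <- config$inputs[[what]]
    if (is.null(path)) {
      stop("stage input '", what,
           "' not available: run its upstream stage or set config$inputs$",
           what)
    }
    if (!file.exists(path)) stop("input path does not exist: ", path)
    state[[what]] <- switch(what,
      alignment = read_alignment(path),
      reads = read_sequences(path),
      lfq = stop("external LFQ inputs: call enrich_pipeline() directly"),
      stop("unknown input: ", what)
    )
  }
  state[[what]]
}
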
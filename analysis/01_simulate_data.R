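#!/usr/bin/env Rscript
# Generate the synthetic study inputs: an ortholog family with the
# convergent NLS-loss design (castorimorpha KKRW, toothed whales KNRW,
# marsupial KNRW-like losses), exon sequencing reads carrying the
# castorimorpha c->t substitution, and a spiked 4v4 LFQ matrix.

library(prodomainevo)

seed <- 20240808L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

fam <- simulate_family(family_sim_config(
  knockouts = list(castorimorpha = "KKRW", odontoceti = "KNRW",
                   marsupialia = "KNRW"),
  seed = stage_seed(seed, 1)
))
write_alignment(fam$alignment, "results/data/family.fasta")
write.table(fam$truth, "results/data/family_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("family: %d sequences, %d planted loss species\n",
            nrow(fam$alignment$matrix), sum(fam$truth$class == "loss")))

reads <- simulate_reads(
  read_sim_config(
    variants = data.frame(pos = demo_exon_motif()[1] + 9L, base = "T"),
    n_reads = 200, error_rate = 0.01, seed = stage_seed(seed, 2)
  ),
  fastq_path = "results/data/reads.fastq"
)
cat(sprintf("reads: %d at 1%% error, planted c->t at motif position 10\n",
            length(reads$reads)))

lfq <- simulate_lfq(
  lfq_sim_config(n_proteins = 1000, n_enriched = 50, effect = 4,
                 sd_within = 0.5, seed = stage_seed(seed, 3)),
  path = "results/data/proteingroups.tsv"
)
write.table(lfq$truth, "results/data/lfq_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("lfq: %d proteins (+flagged rows), %d spiked\n",
            nrow(lfq$truth), sum(lfq$truth$enriched)))
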
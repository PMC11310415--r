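#!/usr/bin/env Rscript
# Sequencing-read vote over the exon query: local alignment of reads,
# score filter (> 80) and top-100 cap, per-position percent match to the
# human KKRR codons, and the translated consensus motif.

library(prodomainevo)

motif_iv <- demo_exon_motif()
rv <- read_vote("results/data/reads.fastq", demo_exon(),
                motif_iv[1], motif_iv[2], min_score = 80, cap = 100)
write.table(rv$vote_table, "results/vote_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(rv$consensus[c("nt", "aa")],
                     "results/consensus_motif.json", auto_unbox = TRUE)
print(rv$vote_table[, c("position", "ref_base", "coverage",
                        "percent_match")], digits = 3)
cat(sprintf(
  "%d of %d reads used; consensus %s -> %s (planted substitution recovered)\n",
  length(rv$hits), rv$n_input_reads, rv$consensus$nt, rv$consensus$aa
))
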
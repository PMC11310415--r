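#!/usr/bin/env Rscript
# Modal-consensus conservation of the simulated ortholog family:
# per-column consensus, gap-modal column removal, per-domain
# conservation, and intact-vs-mutant NLS group summaries.

library(prodomainevo)

dir.create("results", showWarnings = FALSE)
aln <- read_alignment("results/data/family.fasta")
cons <- modal_consensus(aln)
write_consensus(cons, "results/consensus.tsv")
cat(sprintf("consensus over %d columns (%d gap-modal, removed)\n",
            nrow(cons), sum(cons$gap_modal)))

ct <- conservation_table(aln, "reference|REF|1")
write.table(ct, "results/conservation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mt <- motif_table(aln, "reference|REF|1")
gs <- group_summary(ct, mt)
write.table(gs, "results/conservation_by_group.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(gs, digits = 3)
nls <- gs[gs$domain == "NLS", ]
hat <- gs[gs$domain == "HAT1", ]
cat(sprintf(
  "NLS conservation drops in mutant-NLS species (%.2f vs %.2f) while HAT1 stays comparable (%.2f vs %.2f)\n",
  nls$mean[nls$group == "mutant_NLS"], nls$mean[nls$group == "intact_NLS"],
  hat$mean[hat$group == "mutant_NLS"], hat$mean[hat$group == "intact_NLS"]
))
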
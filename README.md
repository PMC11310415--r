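# prodomainevo

Convergent loss of the pro-interleukin-1α nuclear localisation signal
(NLS) across mammals, and the proximity-labelling proteomics that
motivates it, as a reusable R analysis workflow.

## The problem

The pro-domain of pro-IL-1α (residues 1–112 on the human sequence)
carries an NLS at residues 78–90 (`GKVLKKRRLSLSQ`, functional core
**KKRR** at 82–85) and two histone acetyltransferase (HAT)-binding
domains at 7–19 and 98–108. Several mammalian lineages — toothed
whales (KNRW), the rodent suborder castorimorpha (KKRW/KKRL), most
Australasian marsupials, and isolated species such as the naked
mole-rat — have independently substituted the KKRR core, abolishing
predicted nuclear import, while keeping the HAT-binding domains
conserved. The package implements:

- **Modal-consensus conservation** — per alignment column the most
  frequent symbol (gaps count; gap-modal columns are removed), and
  per-sequence, per-domain conservation as the fraction of surviving
  domain columns matching the modal residue, summarised by NLS-status
  group.
- **KKRR-motif classification** — `intact` (KKRR), `conservative`
  (substitutions to K/R only), `loss` (any non-basic substitution or
  gap), `unknown` (X); species status requires unanimous isoform
  agreement.
- **Sequencing-read base vote** — affine-gap Smith–Waterman local
  alignment of reads to an exon query on both strands (match +2,
  mismatch −3, gap open 5, extend 2), strict score filter (> 80), top
  100 hits, then per motif position the percentage of read bases
  matching the human KKRR codons (`aagaagagacgg`), and a translated
  majority consensus.
- **Perseus-style LFQ enrichment** — flag filtering, log2, one-group
  validity filter, per-column downshifted-normal imputation
  (mean − 1.8 SD, width 0.3 SD), PCA, and the SAM-style moderated
  statistic `d = (m₁ − m₂)/(se + s0)` with a permutation FDR: all 35
  balanced 4v4 relabelings enumerated, observed labelling excluded,
  symmetric cut on |d| at the smallest value whose π₀-adjusted,
  add-one-smoothed mean false-positive estimate stays under the target
  (defaults s0 = 2, FDR = 0.01).
- **Seeded simulators** for ortholog families on a clade table with
  domain-specific substitution rates and motif knockouts, reads with
  per-base errors, and LFQ matrices with intensity-dependent
  (left-censored) missingness — so everything above is testable with
  no downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on
simulated data (`Rscript analysis/01_simulate_data.R` … `05_enrichment.R`),
writing tables under `results/`. The core of it, interactively:

```r
library(prodomainevo)

fam <- simulate_family(family_sim_config(
  knockouts = list(castorimorpha = "KKRW", odontoceti = "KNRW",
                   marsupialia = "KNRW"),
  seed = stage_seed(20240808, 1)
))
aln <- fam$alignment
ct <- conservation_table(aln, "reference|REF|1")
mt <- motif_table(aln, "reference|REF|1")
group_summary(ct, mt)
```

```
       group domain  n  mean median    iqr
1 intact_NLS   HAT1 14 0.973  1.000 0.0000
2 mutant_NLS   HAT1 11 0.972  1.000 0.0385
3 intact_NLS   HAT2 14 0.968  1.000 0.0682
4 mutant_NLS   HAT2 11 0.950  1.000 0.0909
5 intact_NLS    NLS 14 0.978  1.000 0.0577
6 mutant_NLS    NLS 11 0.860  0.846 0.0385
7 intact_NLS    PRO 14 0.851  0.875 0.0603
8 mutant_NLS    PRO 11 0.808  0.812 0.0759
```

NLS conservation drops in the mutant-NLS group (0.86 vs 0.98) while
HAT-domain conservation is indistinguishable between groups (0.97 vs
0.97) — the signature of NLS-specific loss on a conserved pro-domain.

The read vote on 200 simulated reads (1% error) carrying the
castorimorpha c→t substitution:

```r
sim <- simulate_reads(read_sim_config(
  variants = data.frame(pos = demo_exon_motif()[1] + 9, base = "T"),
  n_reads = 200, error_rate = 0.01, seed = 31))
rv <- read_vote(sim$reads, demo_exon(), demo_exon_motif()[1],
                demo_exon_motif()[2])
rv$consensus[c("nt", "aa")]
#> $nt: "aagaagagatgg"   $aa: "KKRW"
```

Position 10 of the vote table shows ~0–2% match to the human base
(errors only); every other position sits at ~100%.

The enrichment pipeline on a simulated 4v4 TurboID design (1000
proteins, 50 spiked at 4 log2 units):

```r
lfq <- simulate_lfq(lfq_sim_config(seed = 11))
res <- enrich_pipeline(lfq$table, lfq$groups, s0 = 2, fdr = 0.01, seed = 11)
res
#> enrich_result: 966 proteins tested, 50 significant (50 target-enriched),
#> |d| threshold 1.286
```

All 50 spiked proteins are recovered with zero false calls; on pure-null
matrices the same settings call nothing.

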
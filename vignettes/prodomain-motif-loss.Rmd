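---
title: "Methods: pro-domain conservation, NLS motif loss and proximity enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pro-domain conservation, NLS motif loss and proximity enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prodomainevo)
```

# The scientific problem

Pro-interleukin-1&alpha; (pro-IL-1&alpha;) is a dual-function cytokine whose
pro-domain carries a nuclear localisation signal (NLS, residues 78&ndash;90 on
the human sequence, with a basic "KKRR" core at 82&ndash;85) and two histone
acetyltransferase (HAT)-binding domains (residues 7&ndash;19 and 98&ndash;108).
Several mammalian lineages &mdash; toothed whales, the rodent suborder
castorimorpha, most Australasian marsupials, and a handful of isolated
species &mdash; have independently acquired substitutions in the KKRR core
(KNRW, KKRW, KKRL, ...) that abolish NLS function, while their
HAT-binding domains remain conserved. This package implements the
computational side of that analysis as a reusable, testable workflow:

1. **Modal-consensus conservation** of an ortholog protein alignment,
   summarised per domain and per NLS-status group.
2. **KKRR-motif extraction and loss classification** per sequence and
   per species.
3. **A sequencing-read base vote** that dates motif-loss events from
   raw reads locally aligned to an exon query.
4. **Perseus-style differential enrichment** of TurboID
   proximity-labelling LFQ proteomics (the experiment that motivates
   the nuclear-interactor question in the first place).
5. **Seeded simulators** that generate inputs with the statistical
   structure each stage assumes, so the entire workflow is testable
   offline.

# Conservation against the modal consensus

Conservation is measured against the *modal* amino acid of each
alignment column, gaps counting as a symbol. Columns where the gap is
modal are removed before scoring (they correspond to insertions carried
by a minority of sequences). Two choices here were genuinely open:

* **Tie-break.** The most frequent symbol is not always unique. We
  prefer any amino acid over the gap, and among tied amino acids the
  lexicographically smallest one-letter code. This is deterministic and
  never lets a tie discard a column that half the sequences support.
* **Denominator.** A domain's conservation is `matches / columns of the
  domain surviving gap-modal removal`, matching how a conservation
  barcode is actually drawn; the pre-filter width is reported alongside.
  A domain whose columns were all removed is flagged undefined rather
  than silently scored 0.

A gap or an `X` in the scored row is always a mismatch: an ambiguous
residue call carries no evidence of conservation. `X` does participate
in modality, because it is a symbol the alignment actually contains.

Coordinates are 1-based inclusive on the ungapped reference row
throughout (the R/Bioconductor convention); `build_reference_map()`
anchors reference residue *i* on the column holding the i-th non-gap
symbol of the reference row.

Group summaries are computed over all sequences (isoforms) by default,
with `collapse_species = TRUE` (longest isoform wins) as an option,
because published figures do not always state which convention they
use; both are first-class.

# Motif classification

The classifier is total over the 21-symbol alphabet (20 amino acids
plus `X`) and the gap:

* `intact` &mdash; exactly `KKRR`;
* `conservative` &mdash; every substituted position carries K or R
  (basic character, and hence presumably import function, retained);
* `loss` &mdash; any substitution to a non-basic residue, or any gap;
* `unknown` &mdash; any `X`.

`conservative` is kept distinct from `intact` because a K&harr;R swap is
biologically neutral for a basic NLS but still a sequence change;
downstream grouping treats it as intact-like by default with a switch to
treat it as loss. Species-level status requires *unanimous* loss across
isoforms; disagreeing isoforms are flagged `mixed` for manual review
rather than resolved silently.

The `nls_propensity()` score is an explicit proxy, not a re-implementation
of any external NLS predictor: the fraction of basic residues in the
best window of 8&ndash;13 residues. Only the *direction* of comparisons
between variants is meaningful (KKRR context scores above KNRW context);
the absolute value predicts nothing.

# The read vote

The published procedure aligns archive sequencing reads against an exon
query, keeps the top 100 reads with alignment score above 80, and for
each of the 12 nucleotides coding for KKRR computes the percentage of
read bases matching the human base. Here:

* The aligner is affine-gap local (Smith&ndash;Waterman) alignment with
  blastn-like scoring (match +2, mismatch &minus;3, gap open 5, gap extend 2;
  a gap of length L costs `open + L * extend`), searched on both
  strands. Raw BLAST scores are not reproducible without BLAST itself,
  so the threshold is documented as a raw score *in this scheme*, with
  80 as the default to mirror the published cut-off. The implementation
  is checked exactly against a brute-force quadratic dynamic program on
  a thousand random pairs.
* Read bases are projected onto query coordinates (insertions in the
  read dropped, deletions rendered as `-`), replacing the interactive
  multiple-alignment-viewer step of the original procedure with
  pairwise query-projected columns.
* `N` never matches anything, but counts toward coverage. The score
  filter is strict (`> 80`), ties in the top-100 cap break by read id,
  and positions with zero coverage are reported undefined, never 0%.
* The consensus takes the per-position majority base; a tie falls back
  to the reference base and is flagged. Translation uses the standard
  genetic code; fuzzy codons give `X`.

# Perseus-style enrichment

The LFQ pipeline runs in a fixed, logged order: remove rows flagged
contaminant / reverse / only-identified-by-site; `log2`; keep rows with
a valid value in *all* replicates of at least one group; impute missing
values per sample column from `Normal(mean - 1.8 SD, (0.3 SD)^2)`
(the de-facto Perseus defaults for left-censored, missing-not-at-random
LFQ data; both parameters are exposed and logged); then PCA over
centred protein features and the moderated test.

The statistic is SAM-style: `d = (mean1 - mean2) / (se + s0)` with
`se` the pooled-variance two-sample standard error, so `s0 = 0`
recovers the classical t statistic exactly and `s0 = 2` (the study
default) damps low-variance proteins.

**FDR machinery.** For a 4v4 design all 35 balanced complement-invariant
relabelings are enumerated; the observed labelling is excluded, leaving
34 permutation null datasets (larger designs are subsampled under the
run seed). The significance cut on `|d|` is the smallest value whose
estimated FDR

&nbsp;&nbsp;&nbsp;&nbsp;`pi0 * (mean permutation false positives) / (observed positives)`

does not exceed the target, with &pi;&#8320; estimated from the fraction of
observed `d` inside the central null quartiles. The mean false-positive
count uses add-one smoothing, `(exceedances + 1) / (B + 1)`: with only
34 permutations, an unsmoothed estimate hits zero whenever the observed
labelling happens to attain the pooled maximum (probability &asymp; 1/35
under the null), which would call the top protein on about 3&ndash;5% of
pure-null datasets and inflate the realised FDR well above a 1% target.
Smoothing bounds the single-call estimate at `1/(B+1)` &asymp; 0.029, the
honest resolution of 34 permutations; calls therefore arrive in groups
of &ge; 3 at FDR 0.01, which costs nothing at realistic effect sizes (the
spiked simulations below reach sensitivity &ge; 0.95 with zero false
calls). The achieved threshold, &pi;&#8320;, and the resolution `1/(B+1)` are
all reported in the run summary.

# What the simulators emulate &mdash; and what they do not

* `simulate_family()` evolves a fixed synthetic 112-residue ancestral
  pro-domain (human domain layout, NLS 78&ndash;90 = `GKVLKKRRLSLSQ`) down a
  flat clade table: each species substitutes each site independently
  with its domain's probability (scaled by a per-species depth as
  `1 - (1-p)^depth`), replacements uniform over the 19 alternatives,
  and knockout clades then receive their motif at 82&ndash;85. There is no
  rate matrix, no among-site rate variation beyond the domain structure,
  and no shared internal branches &mdash; conservation scoring depends only
  on match/mismatch, so exchangeability realism buys nothing here. The
  default clade table mirrors the study design (castorimorpha, toothed
  whales, marsupials, monotremes plus placental background clades).
* `simulate_reads()` samples uniform substrings of a synthetic 180-nt
  exon carrying the human KKRR codons at 100&ndash;111, applies configured
  variants, injects uniform per-base errors, and reverse-complements
  half the reads. No indels, no quality model, no paired ends.
* `simulate_lfq()` draws protein baselines on the log2 scale
  (mean 25, SD 2), shifts enriched proteins in the target group, adds
  replicate noise, and censors values with probability
  `plogis((20 - x)/1)` in the true intensity `x` &mdash; low-abundance
  proteins go missing, which is exactly the assumption the downshifted
  imputation makes. Defaults (1000 proteins, 50 enriched at 4 log2
  units, within-group SD 0.5, 4v4) are the conditions the power and
  FDR claims are tested at.

Passing tests on these simulations show the machinery is correct and
calibrated under its own assumptions; they do not show that real LFQ
missingness is logistic, that real alignments are indel-free, or that
real read errors are uniform.

Problem sizes in the test suite are chosen to keep the full run in a
few minutes: 1000 random aligner pairs up to length 30, 100 null and 10
spiked LFQ simulations of 1000 proteins, 20 family-recovery seeds, and
exhaustive enumeration of all 21^4 motifs.

# Determinism and the pipeline

Every generator and the imputation step are seeded; `run_pipeline()`
derives per-stage seeds from the global seed (`stage_seed()`, a fixed
affine map modulo 2^31 &minus; 1) so stages can be re-run in isolation. Two
runs with the same config and seed reproduce all data artefacts
bit-identically; the JSON run report is the one file excluded from that
guarantee because it records wall-clock per stage.

# Known limitations

* The motif-loss classification is sequence-level; it cannot see
  regulatory changes, and `mixed` species need manual review.
* The alignment itself (MUSCLE/MAFFT) and phylogenetic tree inference
  are upstream of this package; it consumes alignments.
* The permutation FDR has resolution `1/(B+1)` &mdash; with 4v4 designs no
  single-protein discovery is possible at FDR 0.01, by construction.
* `nls_propensity()` orders variants; it does not predict import
  efficiency.
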
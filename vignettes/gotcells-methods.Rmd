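---
title: "Methods: genotyping of transcriptomes and genotype-aware single-cell analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping of transcriptomes and genotype-aware single-cell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gotcells)
```

# The measurement problem

Droplet scRNA-seq libraries tag every cDNA molecule with a cell barcode
and a UMI. When a disease is driven by a somatic point mutation, the
mutation status of each cell is invisible to standard expression
processing: the variant locus is rarely covered by enough transcriptome
reads. Genotyping of transcriptomes (GoT) re-amplifies a short fragment
spanning the variant from the same barcoded library, producing a deep
amplicon library in which each read pair links a cell barcode and UMI
(read 1) to the variant base (read 2).

`gotcells` assumes a **hemizygous** locus — one allele per cell, as for an
X-linked gene in a male — so each cell is purely mutant (`MUT`) or purely
wild-type (`WT`), and any well-supported molecule is in principle enough
to genotype its cell. All calling rules below follow from that assumption.

# The amplicon genotyper

Amplicon data are dominated by PCR duplication, and both the UMI and the
variant base accumulate errors during amplification and sequencing. The
genotyper deals with the two error channels in sequence.

**UMI collapsing.** Within one cell barcode, pairwise Levenshtein
distances (full edit distance — substitutions, insertions, deletions, unit
costs) are computed between all observed UMIs. Pairs at distance ≤ *t*
are *matches*, with *t* = ⌈0.1 · UMI length⌉ by default (2 bases for a
12-base UMI). Greedily, the UMI with the greatest number of matches among
the surviving set absorbs its matched partners; absorbed UMIs map to the
absorber as canonical and leave further consideration; the step repeats
with the next-highest-match survivor until no survivor has a match.
Unmatched UMIs are their own canonical form. The result is a total map,
and collapsing the canonical set again changes nothing (idempotence,
asserted in the tests).

Tie-breaking when two UMIs have equal match counts is not specified by
the procedure itself; the package breaks ties toward the UMI with more
supporting reads, then lexicographically — deterministic, and favoring
the more-sequenced molecule. Match counts are unweighted by reads;
read counts enter only as a tie-break.

**Per-molecule consensus.** Reads are re-tallied per (cell, canonical
UMI). Bases matching neither allele count toward neither tally (they are
reported, not silently dropped). A molecule is `MUT` when mutant reads
outnumber wild-type reads, `WT` in the converse, and **ambiguous** when
the two tallies are equal and positive; ambiguous molecules are excluded
from cell calling. Molecules with no informative read at all (all
off-allele) cannot be assigned either label and are dropped with a
reported count.

**Cell calling.** A cell with ≥ 1 mutant molecule is `MUT`; otherwise
≥ 1 wild-type molecule makes it `WT`; a cell with neither is
`UNASSIGNED`. Cells with both mutant and wild-type molecules are
conflicts that hemizygosity forbids except through error. Mutant takes
precedence: a true mutant cell produces wild-type evidence through a
single base error at the amplified locus, whereas the reverse requires
the same error in the opposite (rarer, given the mutant fraction of
reads) direction. Conflicted cells are flagged per cell and counted in
the output, so the choice is auditable.

**Chunked processing.** Reads are processed in groups (default 125,000
reads) whose per-chunk pass only tabulates (cell, UMI, base) counts;
collapsing and calling run after all chunks are merged and re-keyed by
cell barcode. Genotyping is therefore exactly invariant to the chunk
size, which the tests assert.

# The transcriptome variant caller

Transcriptome reads that happen to cover the variant give an independent,
shallower genotyping route. Reads without a cell-barcode (CB) or
molecular-barcode (UB) tag are removed first — without both tags a read
identifies no molecule. Within each (cell, UMI), if all reads agree the
shared base is the consensus; if they disagree, the most common base is
accepted only when it accounts for **at least 75%** of the molecule's
reads (so 3 of 4 reads suffice); otherwise the molecule is discarded.
The comparison operator is a switch (`strict = TRUE` uses > 0.75),
because the two printed formulations of this rule differ; the default
follows the "at least 75%" reading, which the 3-of-4 case supports. A
consensus equal to neither allele cannot support a genotype and is
discarded. Cell calling then reuses the hemizygous rule above.

Because transcriptome coverage of a single locus is far sparser than a
targeted amplicon (~5% vs ~17% of cells under the default simulation),
the amplicon route genotypes more cells; the suite asserts this ordering
across replicate cohorts.

# Annotation and expression

* **QC.** Cells with < 500 detected genes (fragments), > 6000 (potential
  doublets), or > 5% mitochondrial reads (prefix `MT-`, configurable) are
  excluded; removal counts per criterion are reported and the filter is
  idempotent.
* **Normalization.** Counts are scaled per cell to 10,000 and
  `log1p`-transformed (natural log — the ecosystem convention; the DE
  fold-change base is configurable).
* **Signatures and cluster identity.** Reference subtype profiles are
  reduced to signatures: genes ranked by mean expression in the subtype
  minus the mean across the other subtypes, top 250 kept, ties broken by
  gene name. Clusters are labeled by the subtype with the smallest
  one-sided Fisher's exact p-value for marker/signature overlap. The gene
  universe is the intersection of the expression matrix and the reference
  table — the most common convention where none is prescribed — and is
  recorded in the output. Ties go to the larger overlap, then name order,
  and are flagged ambiguous.
* **Module scores.** Genes are binned into 24 average-expression bins;
  for each module gene, up to 100 control genes are drawn from its bin
  (without replacement within the bin; the pooled control set is the
  unique union across module genes). The score is the mean module
  expression minus the mean control expression per cell. Sampling
  without replacement within bins makes the degenerate case exact: with
  one bin and an exhaustive control budget the control set is the whole
  universe and every score is identically zero. Scores are
  shift-invariant and deterministic under the stated seed (the caller's
  RNG state is preserved). One caveat the tests account for: the control
  pool may include module genes, attenuating a planted effect by roughly
  |module| / |control pool|.
* **Differential expression.** Per gene, a two-sided Wilcoxon rank-sum
  test (normal approximation; constant genes get p = 1), Bonferroni
  adjustment across tested genes, and log fold change
  log(mean(expm1 A) + 1) − log(mean(expm1 B) + 1). The DE flag uses the
  unadjusted p < 0.05 with log FC > 0.1 — the rule used to derive
  cluster markers, which are up-regulated by construction; adjusted
  p-values are emitted alongside for volcano-style use and a
  `direction = "both"` switch flags either sign.

# Trajectory summaries

Pseudotime is an input (its estimation is out of scope). Curves are
**equal-width binned means**, not smoothers: the smooth curves such
analyses display do not come with a published smoother specification, so
the package uses the transparent choice and exposes the bin count.

* Genotype-ratio curves divide lineage cells into 20 equal-width
  pseudotime bins; per bin the mutant (and wild-type) ratio is taken to
  **all** lineage cells in the bin (unassigned included; an
  assigned-only mode exists), with the binomial standard error
  √(p(1−p)/n) and a 1.96·SE band. Bins under 10 cells are masked. Values
  are stored linear; log display is a plotting choice.
* Score curves report per-group, per-bin means with SE = sd/√n and the
  same band. Exact per-bin coverage of the 1.96·SE bands is ~93–95% in
  calibration simulations (the normal-approximation interval), inside
  the 90–99% tolerance the tests enforce.
* The normalized mutant frequency per cell type is the per-patient
  mutant fraction among genotyped cells averaged across patients (so no
  patient dominates; a pooled mode exists and the mode used is stamped
  in the output). Cell types with ≤ 100 genotyped cells are omitted —
  the floor is strict.

# Repertoire statistics

Only productive chains enter clonality. Cells sharing an identical CDR3
nucleotide sequence share a clone (optionally also V and J); a cell's
primary chain is TRB (T) or IGH (B), and multi-chain cells are resolved
by UMI support, then lexicographic CDR3. Shannon entropy
H(P) = −Σ pᵢ log₂ pᵢ is computed on clone frequencies (validated against
closed forms; inputs must already be a distribution — no silent
renormalization). The Gini index uses the sorted-form identity,
cross-checked against the O(n²) pairwise-difference definition.
Expansion classes are singleton / 2–5 / 6–20 / > 20 cells; only the
strict > 20 "expanded" boundary is analysis-fixed, the interior bins are
plotting conventions. SHM categories are germline (exactly 0), low
(0 < f ≤ 3%), high (> 3%). Clonality is computed within patient by
default — it is a per-subject quantity — with a pooled mode; Gini is on
cells per clone by default, with a UMI-weighted mode.

# The cohort simulator

The simulator emulates the statistical structure the analysis assumes,
with full ground truth, under a single root seed split deterministically
per stage (same configuration ⇒ byte-identical outputs, FASTQ included).

Defaults encode the target study design: **9 patients × 1,000 cells**;
cell types T 0.50, B 0.15, Mono 0.20, NK 0.10, DC 0.05; mutant fractions
Mono/DC 0.40, NK 0.20 (at pseudotime 0), T and B exactly 0 (the
myeloid-restricted pattern of the motivating disease); **amplicon capture
0.17** and **transcriptome capture 0.05** (the two assays' observed
per-cell yields); per-base error 0.01. The NK mutant probability declines
along pseudotime on the logit scale, p(t) = logistic(logit(p₀) − λ·t)
with λ = 2 by default — the logit form keeps probabilities in [0, 1] and
gives the observed monotone decline. Each captured cell emits
1 + Poisson(0.5) molecules and each molecule 1 + Poisson(3) reads, so
capture is exact (every captured molecule is seen at least once);
duplicate reads carry a 1-edit UMI corruption with probability 0.05.
Counts use lognormal gene abundances with 25 marker genes per type
up-regulated 4-fold, lognormal library sizes around 3,000, and a
beta-distributed mitochondrial fraction (mean ~3%) over 13 `MT-` genes —
chosen so that a realistic minority of cells fails each QC bound. Clone
sizes follow a zeta (discrete power-law) distribution with α = 2.5
truncated at the lineage size — a simple reproducible heavy tail whose
exponent is recoverable by maximum likelihood (`fit_powerlaw_alpha`).
SHM mutation frequencies are beta-distributed per B subtype with means
0 (naïve — exact zeros, hence germline), 0.02 (memory), 0.06
(plasmablast, isotypes skewed to IgG). Read qualities are constant
dummies; the pipeline never uses them.

What the simulator does **not** emulate: transcript-level read structure
(no sequences beyond the amplicon), ambient RNA and doublets, barcode
collision/background calling, sequencing-quality variation, per-patient
capture variability (one global rate — the data offer no per-patient
estimate), germline V(D)J sequence biology (CDR3s are random nucleotide
strings; V/J/C calls come from a small fixed catalogue), or batch
effects. A green test suite therefore demonstrates correctness of the
computations under these assumptions, not robustness to artifacts absent
from the generative model.

# Numerical and degenerate-input choices

* Edit distances via `utils::adist`; the test oracle re-implements the
  DP independently.
* Reads with `N` in barcode or UMI are dropped before grouping
  (ambiguous molecule identity), with a reported count.
* Empty structures: an empty read group yields an empty consensus table;
  an empty lineage or an empty count matrix is an error; a repertoire
  with no productive chains yields empty tables, not errors.
* Probability validation is strict: clone frequencies must sum to 1
  within 1e-9; mutation frequencies outside [0, 1] are errors;
  configuration errors name the offending field.
* All tie-breaks (UMI absorption, signature ranking, cluster identity,
  primary-chain selection) fall back to lexicographic order so every
  result is deterministic.

# Validation scale

The suite validates at desk scale: greedy collapsing against a
brute-force oracle on 500 instances of ≤ 20 UMIs; consensus calling by
exhaustive enumeration of all read compositions up to 6 reads; Fisher
overlap against exhaustive hypergeometric enumeration for universes
≤ 30 (1,000 tables); genotype recovery on 9 × 1,000-cell cohorts across
50 seeds; band calibration over 200 seeds × 20 bins; family-wise error
of the Bonferroni-corrected DE over 100 null runs of 1,000 genes. These
sizes were chosen to give stable Monte-Carlo estimates of each property
while keeping the default test run in minutes.

# Known limitations

* The hemizygous calling rule does not generalize to diploid
  heterozygous loci, and splice-site variants are out of scope for the
  amplicon design itself.
* Binned curves are not smoothers; with few cells per bin the bands are
  normal approximations and undercover slightly (see calibration above).
* Cluster labels and pseudotime are inputs; the package neither clusters
  nor fits trajectories.
* The sniffer consumes a tagged-read table, not BAM: tag extraction from
  alignments is upstream of this package.
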
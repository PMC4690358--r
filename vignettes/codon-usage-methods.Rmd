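---
title: "Measuring and comparing synonymous codon usage bias with cubkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing synonymous codon usage bias with cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## The problem

Most amino acids are encoded by several synonymous codons, and the
frequencies with which a genome uses them are rarely uniform.  Two
forces shape this codon usage bias (CUB).  Mutational bias changes
nucleotide composition wholesale and is most visible at third codon
positions, where most substitutions are synonymous; its readout is GC3.
Translational selection prefers particular codons in particular genes:
selection for elongation *speed* favours translationally optimal codons
in highly expressed genes, and selection for *accuracy* favours them in
long proteins, where the cost of a missense error is higher.  Comparing
per-species codon statistics, and correlating per-gene statistics with
expression and length, lets the two forces be distinguished.

`cubkit` implements this workflow for multi-species sets of in-frame
coding sequences: per-species descriptive statistics, cross-species
clustering on codon usage profiles, and the correlation analyses, plus
a generative simulator that produces cohorts in which the strength and
direction of every force is known.

## Statistics and their conventions

**Codon counting.**  All statistics are computed from 64-element codon
count tables in a fixed alphabetical codon order.  A terminal stop
codon, when present, is excluded from counting: RSCU, ENC and CAI are
defined over sense codons, so interior codons are what carry the
signal.  Sequences with internal stop codons or a length not divisible
by three are rejected at validation with machine-readable reasons;
codons containing non-ACGT characters are skipped and tallied, since
real transcriptome-derived CDS contain ambiguity characters.  Species
level statistics pool counts over all genes of the species before any
ratio is formed — they are not averages of per-gene values, which would
weight short genes disproportionately.

**RSCU.**  For codon *j* of amino acid *i* with family size $k_i$,
$\mathrm{RSCU}_{ij} = k_i x_{ij} / \sum_j x_{ij}$.  Within every amino
acid that occurs at all, the values sum to $k_i$.  When an amino acid
never occurs, its codons' RSCU is reported as missing rather than 0 —
a zero would masquerade as "maximally avoided".  Imputation is left to
the analysis that needs complete data (see clustering below).

**Positional GC.**  GC1/GC2/GC3 are count-weighted over all sense
codons, including the non-degenerate ATG and TGG.  This matches the
convention of the widely used EMBOSS `cusp` output, so values are
directly comparable with that lineage of tools; GC3 restricted to
degenerate sites would run roughly 2–3 points different in AT-rich
data.

**ENC.**  Wright's effective number of codons is assembled from family
homozygosities.  In counts mode the small-sample corrected estimator
$\hat F = (n\sum p_i^2 - 1)/(n-1)$ is used per amino acid (requiring
$n \ge 2$; non-positive estimates are treated as missing); frequencies
mode uses $F = \sum p_i^2$ unmodified.  Class means $\bar F_k$ over the
2-, 3-, 4- and 6-fold amino acids enter
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
Two conventions deserve note:

- *Bounds.*  With every sense codon equally frequent the composition
  evaluates to exactly 61.  With a single codon per amino acid it
  evaluates to $2+9+1+5+3 = 20$, although 21 is often quoted as the
  theoretical minimum in the literature; we report what the formula
  gives and do not force 21.
- *Missing classes.*  If the 3-fold class (Ile) is unusable it is
  imputed as the mean of $\bar F_2$ and $\bar F_4$ (Wright's remedy).
  Any other fully missing class is imputed with the mean of the
  available class means — the same local-information principle; the
  imputed classes are recorded in the result.  These rules only
  matter for very short genes.
- *Capping.*  The species-level `enc()` result is capped at 61, since
  the corrected estimator can exceed 61 on near-uniform data.
  Per-gene values from `gene_metrics()` are deliberately *not* capped
  by default: those values feed regressions against length and
  expression, and truncation at the boundary is asymmetric — short
  genes are truncated more, which manufactures a spurious negative
  (−ENC)~length correlation in weakly biased genomes.  In simulation
  under a true null (uniform usage, no selection) the capped per-gene
  estimator shows a systematic correlation with length of $r \approx
  -0.2$ while the uncapped one is consistent with zero.  Cap at
  reporting time (`cap = TRUE`) when the strict $[1, 61]$ range is
  wanted.

**sENC-x.**  Per-amino-acid bias comparable across degeneracy classes:
with $\mathrm{ENC}_x = 1/F \in [1, k]$,
$\mathrm{sENC\text{-}x} = (k - \mathrm{ENC}_x)/(k - 1)$, so 0 means
uniform usage and 1 means a single codon used.  (The scaling direction
is chosen so that *larger* values mean *stronger* bias.)  Sampling
noise under the corrected estimator can push $1/F$ slightly outside
$[1, k]$; values are clamped to $[0, 1]$.  Eighteen amino acids are
degenerate and contribute.

**TPM and the CAI reference set.**  Expression is normalized as
$\mathrm{TPM}_i = 10^6 (c_i/l_i)/\sum_j (c_j/l_j)$ per library.  The
CAI reference set is the top-*n* (default 50) genes of the conserved
ortholog set ranked by the unweighted mean TPM across the configured
libraries, ties broken lexicographically so the selection is
reproducible.  Relative adaptiveness weights are per-family rescaled
reference RSCU, $w = \mathrm{RSCU}/\mathrm{RSCU}_{\max}$; codons unseen
in the reference receive a 0.5 pseudocount before RSCU so no weight is
zero, and amino acids entirely absent get all weights 1 with a warning.
CAI is the geometric mean of $w$ over a gene's codons excluding ATG,
TGG and stops, which carry no information about synonymous choice.
In the pipeline, the reference *gene ids* are chosen once from the
configured expression table, and each species' weights are rebuilt from
its own orthologs of those genes.

**Quality filters.**  ORFs must be strictly longer than 100 codons.  A
species passes the dataset filter iff it recovered at least 25% of the
conserved gene set *and* the mean recovered length strictly exceeds
500 nt.  The strict/inclusive readings are deliberate and tested at
the boundaries.  Orthology itself (the conserved gene table) is
consumed as input; sequence-similarity searching is out of scope.

## Cross-species analyses

**Clustering.**  Species RSCU profiles over the 59 informative codons
(61 sense codons minus ATG and TGG) are clustered under Euclidean
distance.  Missing cells (absent amino acids) are imputed with the
codon's column mean and masked; a species missing more than 20% of its
codons is excluded instead, since imputation would dominate its
profile.  The default linkage is *complete*; *average* linkage (UPGMA)
is one switch away, because both appear in the comparative literature
for this exact analysis and the choice genuinely affects mid-level
topology.  Trees are ultrametric by construction and export to Newick
with cophenetic distances equal to merge heights.

**Correlation analyses.**  All correlation/regression results carry the
Pearson r, OLS slope and intercept, $R^2$, the two-sided F-test p-value
and n.  Overall species CUB is expressed as −ENC so that positive
correlations read "more frequent in more biased species".  Per-codon
frequency~(−ENC) correlations use each codon's fraction of *all* sense
codons, not its within-family share — the within-family share is
already RSCU's job.  Significance flags use $\alpha = 0.05$; degenerate
inputs (zero variance) are flagged non-significant rather than erroring
the batch.  Gene-level analyses (−ENC and GC3 against length and
per-library TPM) report a row per analysis per species, and omit rows
whose inputs are absent rather than fabricating zeros.

## The simulator

The generator exists to answer one question: if the forces are known,
does the pipeline recover them?  Each gene of a species draws a length
(log-normal, mean 300 codons, sd 0.35 on the log scale, truncated at
101 codons so everything passes the ORF filter) and a true expression
level (log-normal, meanlog $\log 20$, sdlog 1.5 — a heavy-tailed
distribution typical of bulk RNA-seq); amino acids are i.i.d. from a
fixed average proteome composition (UniProt global frequencies).  Each
codon is then drawn from its synonymous family with log-linear weight

$$w_c \propto \exp\{(\beta + s\,d_s z_{\mathrm{expr}} +
a\,d_a z_{\mathrm{len}}) \cdot [c \text{ ends in G/C}]\}$$

where $z$ are the gene's standardized log-expression and log-length,
$d = \pm 1$ encodes the direction (GC- or AT-ending) of speed and
accuracy selection, and $\beta$ is calibrated by 1-D root finding so
the expected species GC3 with no selection equals the `gc3_target`
dial (realized GC3 lands within ±0.02 at 2000 genes; the expectation
itself is matched to numerical tolerance).  The third-position
nucleotide is the *only* bias feature — the minimal model that
generates every signal the analysis measures: a GC3 gradient across
species, expression-coupled and length-coupled codon preference within
species, and their interactions with ENC.

Read counts for three libraries are Poisson draws around
length-weighted expression with mild per-library log-normal noise
(sdlog 0.15, 2×10⁶ reads/library), so TPM recovers the true expression
ranking with realistic scatter.  All randomness flows from a single
cohort seed: per-species seeds are one `sample.int` draw, so any
species is reproducible in isolation.

What the simulator does **not** emulate: phylogenetic correlation among
species (each species is independent), amino-acid composition
differences, substitution processes along branches, isochore or
position-along-gene structure, assembly or annotation artefacts.
Passing sign-recovery tests therefore shows the *analyses* respond
correctly to the forces they target — not that real bivalve or insect
data are this clean.

## Problem sizes and numerical choices

The test suite's cohort analyses use 12 species × 2000 genes (a scale
at which species-level statistics are tight: ~600k codons/species) for
the parameter-recovery checks, and 10 replicates of 300 genes for the
null-control suite, where the point is calibration of the significance
flags, not power.  Root finding for $\beta$ uses `uniroot` on [−25, 25]
with tolerance 10⁻⁸; infeasible GC3 targets (below the floor set by
Met/Trp's invariant G-endings) are an error, not a clamp.  TSV outputs
round to 6 significant digits so pipeline reruns diff byte-identically.
Distance ties in clustering resolve by `hclust`'s lowest-index rule,
making tree topology reproducible for a fixed row order.

## Known limitations

- ENC-family statistics assume multinomial sampling within families;
  severely fragmented ORFs (many amino acids with $n < 2$) fall back on
  imputation rules whose impact is untested below ~50 codons.
- CAI weights from very small reference pools are pseudocount-dominated.
- The per-gene uncapped ENC can slightly exceed 61 on near-uniform
  genes; downstream consumers expecting a hard ceiling must cap.
- Clustering treats all 59 codons as exchangeable features; no
  phylogenetic correction is attempted, so clusters reflect codon
  usage similarity, not ancestry.
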
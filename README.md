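# cubkit

Comparative analysis of synonymous codon usage bias (CUB) across species,
from in-frame coding sequences to clustering and selection diagnostics.

Synonymous codons are not used at random: genome-wide mutational bias
(visible as GC content at third codon positions, GC3) and translational
selection (for elongation speed in highly expressed genes, and for
accuracy in long proteins) both leave fingerprints in codon counts.
`cubkit` computes the standard descriptive statistics of this field,
runs the cross-species comparative analyses that disentangle the two
forces, and ships a seeded simulator so the whole pipeline can be
exercised on cohorts with known generative parameters.

## What it computes

For a species' pooled codon count table (or a single gene):

- **Codon frequencies** — within-amino-acid fractions and per-thousand
  frequencies (EMBOSS `cusp`-style).
- **RSCU** — relative synonymous codon usage,
  `RSCU_ij = k_i x_ij / Σ_j x_ij` for codon *j* of amino acid *i* with
  degeneracy *k_i*; RSCU > 1 marks a *preferred* codon, RSCU < 1 an
  *avoided* one.
- **GC1/GC2/GC3** — count-weighted GC fraction per codon position.
- **ENC** — Wright's effective number of codons,
  `ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`, where `F̄_k` is the mean
  family homozygosity of degeneracy class *k* (counts-mode estimator
  `F̂ = (nΣp² − 1)/(n − 1)`, or plain `Σp²` in frequencies mode).
  61 = all sense codons used equally; lower = stronger bias.
- **sENC-x** — per-amino-acid bias scaled to [0, 1] across degeneracy
  classes: `sENC-x = (k − 1/F)/(k − 1)`, 0 = no bias, 1 = a single codon
  used (18 degenerate amino acids).
- **CAI** — codon adaptation index: the geometric mean of relative
  adaptiveness weights `w = RSCU/RSCU_max` derived from a reference set
  of highly expressed genes (selected by mean TPM among a conserved
  ortholog set).

Across species: hierarchical clustering of RSCU profiles over the 59
informative codons (Euclidean distance, complete or average linkage,
Newick export), preferred-codon tallies, per-codon frequency~(−ENC)
correlations, per-amino-acid sENC-x~ENC regressions, the cross-species
ENC~GC3 regression, and gene-level correlations of CUB and GC3 against
protein length and expression (TPM).

## Worked example

Simulate a small four-species cohort whose only difference is the
mutational-bias dial (target GC3 from 0.30 to 0.48), then measure ENC
and GC3 per species:

```r
library(cubkit)

params <- lapply(1:4, function(i)
  species_sim_params(sprintf("sp%02d", i), n_genes = 300,
                     gc3_target = seq(0.30, 0.48, length.out = 4)[i]))
cohort <- generate_cohort(params, cohort_seed = 7)
profiles <- lapply(cohort$species, function(sp)
  species_profile(validate_cds_set(sp$sequences)$accepted))

data.frame(species = names(profiles),
           enc = round(sapply(profiles, function(p) p$enc$enc), 2),
           gc3 = round(sapply(profiles, function(p) p$gc[["gc3"]]), 3))
#>   species   enc   gc3
#> 1    sp01 51.51 0.298
#> 2    sp02 56.15 0.364
#> 3    sp03 59.04 0.418
#> 4    sp04 60.83 0.481

pearson_regression(c(0.298, 0.364, 0.418, 0.481), c(51.51, 56.15, 59.04, 60.83))
#> r = 0.9814, slope = 51.25, intercept = 36.88, R2 = 0.9632, p = 0.0186, n = 4
```

Realized GC3 tracks each species' target to within the calibration
tolerance, and ENC falls as composition departs from GC3 = 0.5 — the
further usage is pushed towards A/T-ending codons, the fewer codons are
effectively in play.  In the most biased species every one of its 30
preferred codons (RSCU > 1) is A/T-ending, and the amino acids carrying
the strongest bias are visible in its sENC-x vector:

```r
sort(profiles$sp01$senc, decreasing = TRUE)[1:3]
#>     C     K     F
#> 0.345 0.331 0.329
```

The full pipeline (quality filters, CAI against an expression-defined
reference set, clustering, correlation tables) runs from a config:

```r
cfg <- run_config(fasta_dir = "cohort/fasta",
                  ortholog_tsv = "cohort/orthologs.tsv",
                  expression_tsv = "cohort/expression/sp01.tsv",
                  reference_species = "sp01",
                  out_dir = "results")
run_pipeline(cfg)
```

or from the shell via `inst/scripts/cub-pipeline.R`.  Outputs are TSVs
(species metrics, gene metrics, RSCU matrix, preferred-codon and
correlation tables), a Newick dendrogram and a provenance log.

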
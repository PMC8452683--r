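# mitoduo

Simulation and diagnostics for **doubly uniparental inheritance (DUI)** of
mitochondria in bivalves — species in which a female-transmitted (F-type)
and a male-transmitted (M-type) mitochondrial genome coexist. In the ocean
quahog *Arctica islandica* the two mitogenomes differ by ~5.5% at the
nucleotide level; some individuals carry the M-type as the *only* mitotype
of their somatic tissues, and those carriers lose roughly a third of the
capacity of respiratory complexes that are partly mitochondrially encoded.

`mitoduo` implements the computational toolkit for studying this system,
validated end-to-end on a seeded synthetic data generator:

* **synth** — annotated circular mitogenome pairs (17,428 bp, 12 CDS,
  22 tRNAs, 2 rRNAs, 2 non-coding regions) diverged at a calibrated rate
  with hotspot/conserved heterogeneity, a 127-bp M-lineage insertion in
  16S and a 10-amino-acid cox1 extension; sequencing reads from
  homoplasmic or heteroplasmic mixtures; qPCR plates with standard
  curves; phenotype tables; population screens.
* **scan** — fixed-difference columns between mitotype groups
  (set-disjointness per alignment column, gap as a fifth state),
  sliding-window divergence profiles (500 columns, step 1),
  pairwise-deletion p-distance with a column bootstrap, indel location,
  per-feature divergence tables.
* **assay** — in-silico multiplex PCR: primer-site search on circular
  genomes with a 3'-clamp rule, amplicon extraction, and size-based
  mitotype classification (F / M / HET / FAIL).
* **readtype** — diagnostic canonical k-mer indexes over type-specific
  regions, read assignment with matches per 100 bases, homoplasmy calls.
* **quant** — standard-curve fitting, `Concentration = Efficiency^ΔCt`
  quantification, geometric-mean housekeeping normalization, tissue-level
  mitotype calls with order-of-magnitude imbalance buckets, copy-number
  fold estimates with bootstrap CIs.
* **phenostats** — percent-reduction estimates with bootstrap CIs,
  Kruskal-Wallis across sex-by-mitotype groups, pairwise Wilcoxon post hoc
  with Holm adjustment, marginal mitotype and sex contrasts.

The core diagnostic rule: an alignment column is a **fixed difference**
between the mitotype groups when the observed state sets are disjoint,

    { s : s seen in M rows }  ∩  { s : s seen in F rows }  =  ∅ ,

with the gap character counted as a fifth nucleotide. p-distance is the
mismatch proportion over columns with no gap in either row; qPCR amounts
follow `amount = amount₀ · E^(Ct₀ − Ct)` with `E = 10^(−1/slope)` from the
standard curve; phenotype effects are reported as
`100 · (mean(ref) − mean(cmp)) / mean(ref)`.

## Worked example

```r
library(mitoduo)

cfg  <- synth_config(seed = 1)        # the canonical study conditions
pair <- generate_lineage_pair(cfg)
pair
#> <lineage_pair> F 17428 bp / M 17585 bp; 972 substitutions, 2 insertions (aligned length 17585)
realized_divergence(pair)
#> [1] 0.05577232

locate_indels(pair)
#> # A tibble: 2 × 4
#>   aln_start length carrier feature
#> 1      1537     30 M       cox1
#> 2      8537    127 M       16S
```

The realized divergence (5.58%) sits at the calibrated 5.5% target, and the
two M-lineage structural events are recovered from the true alignment: the
30-bp cox1 extension (10 codons) and the 127-bp 16S insertion.

```r
des <- design_assay_primers(pair)
run_multiplex(pair$genomeM, des$primers, des$def, "ind042")
#> <multiplex_call> ind042: M (2 bands)

idx <- build_diagnostic_index(pair)      # k = 31, top divergence windows
rs  <- simulate_reads(pair, synth_config(seed = 1, coverage = 10,
                                         mixture = 1, error_rate = 0))
assign_reads(rs, idx)$region_counts
#> # A tibble: 4 × 5
#>   region mitotype region_length matching_reads per_100_bases
#> 1 diag1  F                  173              0           0
#> 2 diag1  M                  300             34          11.3
#> 3 diag2  F                  300              0           0
#> 4 diag2  M                  300             24           8
```

A pure-M read set supports only M-diagnostic regions — zero reads
cross-assign to F-specific k-mers — so the sample is called
`homoplasmic_M`. Finally, the mitotype effect on respiration:

```r
ph  <- simulate_phenotypes(synth_config(seed = 7), n_per_group = 2000)
isF <- ph$mitotype == "F"
percent_reduction(ph$ETS[isF], ph$ETS[!isF], seed = 1)
#> ETS reduction: 30.9% (95% CI 30.0-31.8)
```

M-type carriers show a ~31% lower mean ETS (complexes I+III) activity than
F-type carriers, the configured effect.

See `vignettes/mitoduo-methods.Rmd` for the full model description,
parameter rationale and limitations.

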
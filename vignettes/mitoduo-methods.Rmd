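---
title: "Methods: simulating and diagnosing doubly uniparental mitochondrial inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and diagnosing doubly uniparental mitochondrial inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoduo)
```

## The biological setting

Most animals inherit mitochondria exclusively from the mother. In several
bivalve lineages a second, male-transmitted mitochondrial genome (the
"M-type" or ♂-type) coexists with the standard female-transmitted genome
(the "F-type" or ♀-type) — doubly uniparental inheritance (DUI). In species
such as the ocean quahog *Arctica islandica* the two mitogenomes differ by a
few percent at the nucleotide level, and individual animals may carry the
M-type not just in male gonads but — exceptionally — as the *only* mitotype
of their somatic tissues, with measurable consequences for the respiratory
chain: complexes partly encoded on the mitochondrial genome (ETS complexes
I+III, cytochrome c oxidase) lose roughly a third of their in vitro
capacity in M-carriers, while the purely nuclear-encoded citrate synthase
tracks sex, not mitotype.

`mitoduo` packages the desk-side computations such a study needs —
divergence scanning, size-based multiplex PCR typing, read-based
homoplasmy calling, qPCR quantification and the mitotype-effect
statistics — together with a seeded generator that produces every input
with the statistical structure those computations assume. The generator is
first-class, tested code: it defines the study conditions against which
the analytical modules are validated.

## The synthetic mitotype pair

`build_reference_genome()` emits a circular 17,428-bp genome carrying the
canonical bivalve complement — 12 protein-coding genes, 22 tRNAs, the two
rRNAs and two non-coding regions (NCRs) — all on the + strand, contiguously
tiled so the two NCRs absorb the length left over by the fixed gene
complement (a 55/45 split between NCR1 and NCR2; any split would do). Every
CDS starts with ATG and ends with TAA, and translation uses the
invertebrate mitochondrial code (NCBI table 5) throughout.

`diverge_lineages()` then creates the M lineage:

* **Substitutions.** Each site mutates independently with probability
  `baseline x multiplier`, where the multiplier is 3.0 in hotspot features
  (atp6, cytb, cox3, nad4, nad4L, nad6, 16S, tRNA-Ile, tRNA-Cys, both
  NCRs), 0.2 in conserved ones (12S, cox2, nad3, nad5, the remaining
  tRNAs) and 1 elsewhere. The baseline is computed in closed form so the
  genome-wide expectation equals the divergence target (default 5.5%);
  with ~17.4 kb of sequence the realized value fluctuates by only a few
  tenths of a percent. A substituted base is drawn uniformly among the
  alternatives that keep the reading frame intact — internal codons may
  not become stops, terminal codons must stay valid starts/stops — with
  the check applied against the codon *as already mutated*, since two
  individually harmless changes can otherwise combine into a stop. This is
  a deliberate, slight departure from a uniform three-alternative model;
  no transition/transversion bias is modelled because the divergence
  scanning and typing modules are insensitive to it.
* **Structural events.** An A/T-rich 127-bp insertion at the midpoint of
  the M-type 16S, and a 10-codon extension of M-type cox1 implemented by
  inserting 30 sense-codon bases immediately before the stop codon. Both
  are recorded in the event log, and the true gapped alignment of the two
  genomes is returned so that downstream modules can be checked against
  ground truth.

Sub-generators draw from seed offsets of the one configured seed (build:
`seed`, divergence: `seed + 1`, reads: `seed + 2`, qPCR: `seed + 3`,
phenotypes: `seed + 4`), so each stage is reproducible independently and
identical configurations give bit-identical outputs.

What the generator does *not* emulate: real mitogenomes have biased base
composition, overlapping genes, origin-spanning features, length
polymorphism in the control region, and alignment uncertainty. Tests
passing on synthetic pairs therefore validate the *computations*
(scanning, typing, quantification), not the practical difficulty of
aligning or annotating real mitogenomes.

## Divergence scanning

The diagnostic-site rule is set-disjointness per alignment column: a column
is a fixed difference when every state in the M group differs from every
state in the F group, with the gap character counted as a fifth nucleotide.
A column with M = {A, G} and F = {A} is *not* divergent. The
`sliding_window_profile()` (default 500 columns, step 1) runs in alignment
coordinates, linearly — windows do not wrap across the origin, matching how
a divergence profile is plotted over an aligned genome; whether one should
instead slide over one genome's own coordinates is ambiguous, and the
alignment-coordinate choice is the documented one.

`p_distance()` uses pairwise deletion (columns with a gap in either row are
excluded), the default of the common distance software this measure is
usually quoted from, with a column-resampling bootstrap for the standard
error (default 1,000 replicates). Ambiguity codes are rejected outright:
under partial state overlap the fixed-difference rule has no defensible
semantics, and silently treating codes as wildcards would inflate
divergence. All column indices are 1-based in the R API and in reports.

## In-silico multiplex PCR

`find_primer_sites()` scans both strands across the circular junction and
accepts a site when total mismatches are within `max_mismatch` (default 2)
and the 3'-terminal `clamp` bases (default 3) match exactly — polymerase
extension tolerates internal wobble far better than 3' mismatch, and the
defaults encode that qualitatively; no thermodynamic model is attempted.
`amplify()` reports the shortest forward→reverse span up to 2,000 bp
(suppressing spurious giant products), inclusive of both primer footprints,
which is the size a band on a gel corresponds to.

The shipped `design_assay_primers()` mirrors the published assay's logic on
synthetic pairs: a shared 16S pair on conserved flanks of the insertion
(product size difference exactly equal to the indel length) and
mitotype-specific cytb pairs whose forward 3' clamp sits on a fixed
difference, giving distinct product sizes per mitotype. Note that in the
real assay the printed 16S products differ by 126 bp while the indel is
127 bp — implying primer-site offsets between the mitotypes; the synthetic
assay makes the difference exactly the indel length and does not reproduce
that discrepancy. Classification is band-driven and total: F or M when only
one mitotype's band set appears at one or more loci, HET when both appear
(the assay detects both mtDNAs regardless of concentration), FAIL when
nothing is interpretable.

## Read-based mitotype typing

Instead of a short-read aligner, `build_diagnostic_index()` collects
canonical (strand-collapsed) 31-mers from declared regions and subtracts
every k-mer present anywhere in the other mitotype's genome. This is a
methodological substitution — the published analysis mapped reads with an
aligner — but the decision variable is identical: read support for
type-specific regions. The default regions are the top fixed-difference
density windows of the pair's alignment, which puts the first region over
the 16S insertion, the analogue of choosing the most type-specific stretch
of the genome. A read is assigned when at least `min_hits = 2` of its
k-mers hit one mitotype's set (two hits suppress single-error chimeras);
reads hitting both sets are discarded as ambiguous rather than split
fractionally. Counts are normalized to matching reads per 100 bases of
region length, and a sample is called heteroplasmic when both mitotypes
reach `min_reads = 5`.

## qPCR quantification

Standard curves are least-squares fits of Ct on log10(amount);
efficiency is `10^(-1/slope)`. Quantification is `Efficiency^ΔCt` relative
to the curve's 1-ng point — algebraically the same as reading the amount
off the fitted line, chosen because the published formula names no
reference point. Replicate wells are averaged on the Ct scale and flagged
(not dropped) when they disagree by more than 1 cycle. The relative
quantity is the target over the geometric mean of two housekeeping genes;
*which* two is a configuration input (the stability analysis that selects
them is a separate concern and out of scope here). A tissue is called
homoplasmic when the minor mitotype falls below the detection limit —
default: the amount corresponding to Ct 38, a conventional late-cycle
cutoff, since no explicit absence threshold is standard — and
heteroplasmic otherwise, with the imbalance bucketed at one and two orders
of magnitude. Copy-number differences between carrier groups are reported
as the ratio of group medians with a percentile bootstrap CI (medians,
because copy-number distributions are right-skewed).

## Phenotype statistics

The phenotype generator draws log-normal activities (dispersion
`sdlog = 0.3`, a coefficient of variation near 30%, typical of enzyme
assays on wild-caught animals) with group means structured as: ETS and COX
depend on mitotype only (M carriers at 69% and 67% of the F-carrier mean),
CS depends on sex only (females at 58% of the male mean), and normalized
mtDNA copy number is 3-fold higher in M carriers. Baseline means (ETS 30,
COX 20 U/g tissue; CS 10 U/g fresh weight; copy number 50 normalized
units) are arbitrary scale choices — every downstream statistic is a ratio
or rank.

`percent_reduction()` is defined on group *means* (the published percent
reductions do not state mean vs median; means are the documented choice)
with a two-sample percentile bootstrap. `factorial_tests()` runs the
stated nonparametric suite — Kruskal-Wallis over the four sex-by-mitotype
groups, pairwise Wilcoxon post hoc with Holm adjustment (the conservative
default when no adjustment is named), and the two marginal Wilcoxon
contrasts. The parametric two-way F statistics reported alongside the
nonparametric tests in the original analysis are not reproduced.

## Population screen

`simulate_population_screen()` draws binomial carrier counts per
population; its fixture mode transcribes the published seven-population
screening table (315 individuals, 300 F-carriers, 15 M-carriers; Iceland
10/60) exactly, including the totals row. The table's arithmetic
(15/315 ≈ 9.9%, Iceland ≈ 16.7%) is what the fixture carries; the rounded
"11%" prevalence sometimes quoted for the subarctic samples cannot be
reconstructed from the table alone and is not encoded.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
20-seed divergence calibration on full-length 17.4-kb genomes, 5,000-read
specificity checks, 200-individual multiplex concordance, 250-sample qPCR
plates, and n = 2000 per group for effect recovery (at that size the
standard error of a percent-reduction estimate is ≈ 0.5 points, so the
±2-point recovery checks are comfortably powered). Bootstrap defaults are
1,000 replicates for distances and folds and 2,000 for percent
reductions. Degenerate inputs fail loudly: zero comparable sites in
`p_distance()`, standard curves with fewer than three distinct amounts or
efficiency ≤ 1, empty groups in the statistics, regions shorter than k in
the index.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
pair <- generate_lineage_pair(cfg)
realized_divergence(pair)          # ~0.0558

recs <- locate_indels(pair)
recs[recs$feature == "16S", ]      # one 127-bp M-carried insertion

des <- design_assay_primers(pair)
run_multiplex(pair$genomeM, des$primers, des$def, "ind1")$call   # "M"

idx <- build_diagnostic_index(pair)
rs <- simulate_reads(pair, synth_config(seed = 1, coverage = 10, mixture = 1,
                                        error_rate = 0))
call_homoplasmy(assign_reads(rs, idx)$region_counts)             # "homoplasmic_M"
```

## Known limitations

* The substitution model is intentionally minimal: no transition bias, no
  rate variation within a rate class, no back-mutation (each site is hit
  at most once), no deletions in the F lineage.
* The read simulator has uniform coverage and substitution errors only —
  adequate for k-mer typing, not for indel-sensitive analyses.
* In-silico PCR models site matching and product size, not chemistry;
  primer artefacts (dimers, off-target amplification under permissive
  tolerances) are out of scope.
* The qPCR model is log-linear with Gaussian Ct noise; it does not model
  plateau effects, inhibition, or inter-plate calibration drift.
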
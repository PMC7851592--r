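---
title: "Detecting recent selective sweeps from unphased diploid genotypes"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent selective sweeps from unphased diploid genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The problem

A recent selective sweep drags one (or a few) haplotypes to high frequency
and erases local variation, leaving a telltale stretch of unusually
homogeneous chromosomes. In small wild-caught cohorts — the motivating case
is resequenced urban brown rats — phasing genotypes into haplotypes is
unreliable, so `sweepscan` works directly on *multisite genotypes*: for a
window of SNPs, each diploid individual is represented by its ordered
sequence of unphased genotype states. At each biallelic SNP the two
nucleotide alleles are collapsed into one of up to three pseudo-alleles
(homozygous reference, heterozygous, homozygous alternate), and
haplotype-style homogeneity statistics are computed on those strings.
Methods of this family lose little power relative to their phased
counterparts while avoiding phasing error in small samples.

## The statistics

**G12.** In a symmetric window of `window_snps` SNPs around a focal SNP,
let $p_1 \ge p_2 \ge \dots \ge p_k$ be the frequencies of the $k$ distinct
multisite genotypes. G12 is the expected homozygosity with the two most
frequent classes pooled,

$$G_{12} = (p_1 + p_2)^2 + p_3^2 + \dots + p_k^2 .$$

Pooling the top two classes keeps the statistic sensitive to *soft* sweeps
(two or more sweeping haplotypes) as well as *hard* ones. G12 lies in
$(0, 1]$; with $n$ samples its minimum, attained when every individual is
unique, is $(n+2)/n^2$. A window with at most two classes scores exactly 1.

**H.** For each pair of individuals $(i, j)$, $h_{ij}$ is the length — in
SNPs, not base pairs — of the maximal tract of pseudo-allele identity
containing the focal SNP, and zero if the pair differs at the focal SNP
itself. H is the mean of $h_{ij}$ over all $\binom{n}{2}$ pairs. Long
shared tracts centred on a locus are the H signature of a sweep. The SNP
metric avoids dependence on a genetic map and makes the two scans directly
comparable.

**Weir–Cockerham Fst.** Between two cohorts, per-SNP differentiation is
measured with the two-population diploid variance-components estimator
$\hat\theta = a/(a+b+c)$ (among-population, among-individual and
within-individual components), computed from per-population non-missing
sample sizes, allele frequencies and observed heterozygote proportions.
Per-SNP values are averaged in 10-kb windows stepping by 1 kb. A sweep
that postdates a population split elevates local differentiation, so
window Fst complements the within-population homogeneity scans.

## From tracks to candidates

Each scan yields a score track (one value per focal SNP, or per window for
Fst). Candidate loci are called greedily: take the global maximum, mask
everything within `mask_radius_bp` of it on its chromosome, repeat to
`top_k` loci. Masking prevents a single sweep, whose signal is spread by
linkage disequilibrium, from occupying many slots. Ties are broken by
genomic order so results do not depend on input order.

Candidates are then mapped to their single closest gene (distance 0 inside
a gene, otherwise distance to the nearer boundary, ties to the smaller
start), and a permutation null — equally many positions resampled
uniformly from the *scored focal SNPs*, re-applying the same spacing
constraint — supports a Wilcoxon rank-sum test of whether candidates sit
unusually far from (or near to) genes. Candidates farther than
`max_gene_distance_bp` (default 20 kb) from any gene are set aside when
building gene-level candidate lists.

## Gene enrichment with a permutation FDR

Genes are scored by the maximal statistic among focal SNPs inside the gene
and ranked. Walking down the ranking, a GO biological-process category is
a *discovery* the first time at least `min_genes` (default 3) of the genes
seen so far belong to it. Each discovery masks all genes intersecting
±`mask_kb` (default 30 kb) around the contributing genes and the ranking
is recomputed over the survivors — otherwise a physical cluster of
paralogs sharing one homogeneity signal (and, typically, annotations)
would be rediscovered repeatedly. The expected number of false discoveries
at each rank is estimated by shuffling scores across genes (annotation
geometry fixed), re-running the identical walk, and averaging over
permutations. For an a-priori gene set, `category_test()` permutes the
candidate *positions* instead and reports both a Fisher's exact test on the
permutation-calibrated 2×2 table and a direct permutation tail
probability; the sentence being operationalised admits both readings, so
both are emitted and labelled.

## Cross-population comparison

To ask whether a sweep predates or postdates a population split, each
candidate from cohort A is matched to the nearest scored focal SNP in
cohort B (within 5 kb, since the cohorts need not segregate the same
SNPs), and B's statistic there is expressed as an empirical percentile of
B's genome-wide track. A candidate is "elevated" in B when the percentile
reaches the $1-\alpha$ quantile (default $\alpha = 0.05$). This
empirical-quantile rule is a deliberate, transparent stand-in for more
elaborate significance machinery: it is invariant to monotone transforms
of the statistic and has an interpretable false-positive rate under
neutrality.

## The synthetic cohort generator

Every stage is exercised on synthetic data built by a founder-copying
mosaic: each of the $2n$ haplotypes is a segmental patchwork over a pool
of `n_founders` founder haplotypes, switching founders with probability
`switch_probability` per SNP. This produces realistic linkage-block
structure with desk-scale runtime; it is *not* a coalescent simulation and
makes no demographic claims. Defaults emulate the motivating study's
conditions: 29 diploids (9 in the comparison cohort), founder allele
frequencies Beta(0.5, 0.5) truncated to polymorphic, and mean inter-SNP
spacing of 144 bp so the default 201-SNP window spans about 29 kb.

Sweeps are injected by replacement, not forward simulation: the chosen
carrier haplotypes have their states across the span overwritten with one
of `n_sweep_haplotypes` novel segments (1 = hard, ≥2 = soft). Carriers are
assigned individual-first, so carrier individuals are homozygous for their
segment and form the large multisite-genotype class a real sweep creates.
Replacement gives exact, seed-stable truth tables for parameter-recovery
tests. Two-population cohorts share the founder pool but redraw
founder-choice weights with a drift parameter (gamma weights with variance
`drift`; 0 means identical populations); population-private sweeps then
produce locally elevated window Fst, shared sweeps do not distinguish the
cohorts.

What the generator does **not** emulate: mutation/recombination-rate
heterogeneity, background selection, gene conversion, genotyping error
correlated with depth, and realistic site-frequency spectra from
demography. Passing tests therefore demonstrate correctness of the
statistics and the machinery around them, and qualitative power under
controlled signal strengths — not calibrated power on real data.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_snps` | 201 | SNPs | G12 window; ≈29 kb at 144-bp spacing |
| `mask_radius_bp` | 100 000 | bp | exceeds the window span comfortably; candidate spacing |
| `fst_window_bp` / `fst_step_bp` | 10 000 / 1000 | bp | window Fst resolution |
| `fst_min_snps` | 5 | SNPs | guards windows against single-SNP noise |
| `top_k` | 100 | loci | depth of the empirical-outlier list |
| `max_gene_distance_bp` | 20 000 | bp | candidate-to-gene annotation cutoff (inclusive) |
| `r_max`, `min_genes`, `mask_kb` | 50, 3, 30 | — | enrichment walk depth, discovery rule, cluster mask |
| `n_permutations` | 100 | — | FDR and distance-null resolution |
| `max_missing` | 0.10 | fraction | per-site missing-call ceiling at load |

## Numerical and degenerate-input choices

* **Missing data.** Sites with more than 10% missing calls are dropped at
  load (configurable). Remaining missing calls *break identity*: a sample
  with a missing call in a window is its own singleton class, and a
  missing call terminates an identity tract. This is conservative —
  missingness can only reduce a homogeneity signal, never create one.
* **Window edges.** G12 requires the full fixed-SNP window, so focal SNPs
  within `(window_snps-1)/2` of a chromosome end are unscored. H needs no
  window, so it is computed at every SNP with tracts truncating at
  chromosome ends.
* **Class-count ties.** G12 is provably invariant to how equal class
  counts are ordered (equal frequencies contribute identically whether
  ranked second or third), so no tie-break is imposed.
* **Scan cores.** The G12 and H inner loops are C++ (per-pair prefix sums
  of mismatches; run-length tract assignment) but reproduce a naive
  per-focal recomputation bit-for-bit, including R's extended-precision
  summation order; the test suite asserts bitwise equality on 100 random
  matrices.
* **Fst.** "Mean per-SNP Fst" is the mean of per-SNP ratios; a
  ratio-of-sums variant is available via `ratio_of_means = TRUE`. Negative
  per-SNP estimates are retained (truncating at zero biases window means
  upward). Sites monomorphic in the pooled sample are undefined and
  excluded from window means. Sites whose ref/alt coding is swapped
  between cohorts are reconciled by recoding; irreconcilable sites are
  dropped with a message.
* **Permutation nulls.** Candidate-position nulls resample scored focal
  SNPs (not uniform base pairs): candidates can only arise at scored
  positions, so SNP-uniform sampling is the better-matched null. The
  spacing constraint of the original calling is re-applied per draw.
* **Seeds.** Every stochastic routine takes an explicit seed; the pipeline
  derives per-stage child seeds from the master seed by stage-name
  hashing, so stage reruns are stable regardless of execution order, and
  rerunning the pipeline reproduces outputs byte for byte.

## Problem sizes used by the test suite

The package's property tests run at deliberately compact scales chosen to
exercise every code path with comfortable statistical margins: bitwise
scan/oracle comparisons on 100 random matrices (3–10 samples, 40–120
SNPs), sweep-recovery and two-population contrasts on cohorts of 29 (and
9) individuals with 6,000–10,000 SNPs over 20 seeds each, and enrichment
calibration on 100 spread genes with 25 categories and 200 score
shuffles. These sizes are the package's own choices for a reproducible
desk-scale test bed; all scale linearly if enlarged.

## Known limitations

* Only two-population Fst is provided; no hierarchical F-statistics.
* No phased-haplotype statistics (iHS, nSL, haplotype H12) and no
  genetic-map distance option — the SNP metric is deliberate.
* Candidates carry no significance statement: they are empirical outliers
  intended as preliminary hypotheses, and the package deliberately does
  not attach simulation-based p-values to them.
* GO categories are taken from a user-supplied gene-to-category table;
  there is no ontology-graph propagation, so enrichment results depend on
  the annotation granularity supplied.
* The coding-effect report handles one transcript per gene and classifies
  SNPs only as intronic/synonymous/nonsynonymous (no UTR or splice-site
  classes).
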
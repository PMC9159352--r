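---
title: "Phenotype-gradient selective-sweep scans: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-gradient selective-sweep scans: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradsweep)
```

## The problem

A selective sweep leaves three footprints around a favoured allele: reduced
nucleotide diversity (low π), elevated allele-frequency differentiation
against an unselected population (high F~ST~), and unusually long shared
haplotypes (extreme XP-EHH). Genome scans that rank these statistics find
*many* swept regions, most of which have nothing to do with any one trait —
selection acts on everything at once. The phenotype-gradient design narrows
a scan to one quantitative trait: rank the focal breed's individuals by the
trait (here, mean gestation length of sows), form nested focal groups by
increasingly extreme trait cutoffs (all sows; sows under 114 d; sows under
113 d), contrast each group against the *same* fixed multi-breed reference,
and keep only those candidate windows or SNPs whose signal *increases* along
the gradient. If a sweep is genuinely coupled to the trait, conditioning on
more extreme phenotypes enriches the swept allele and strengthens the
signal; sweeps unrelated to the trait have no reason to respond.

`gradsweep` implements this design end to end: variant QC, the three
statistics, top-tail selection, the gradient filter, gene annotation, the
RNA-seq stage-exclusion set logic that separates breed-specific from
gestational-stage expression differences, the known-gene overlap, and a
forward Wright–Fisher simulator that plants a trait-linked sweep so every
step can be tested against a known truth.

## Statistics

**Nucleotide diversity.** Per site, π is the mean pairwise difference among
the `n` sampled haplotypes, `2c(n−c)/(n(n−1))` for alternate count `c`.
Windowed π sums the per-site values over each 10-kb tile and divides by the
window span in bp (not the SNP count), so SNP-poor windows are genuinely
low-diversity rather than undefined. The ranking signal is the log~10~ ratio
of focal over reference window diversity; the two-tailed mode ranks
`|log10 ratio|` with the sign kept as metadata, the `low_tail` mode ranks
`−log10 ratio` so only diversity *loss* in the focal group scores high.
Windows with zero reference diversity have an undefined ratio and are
excluded from ranking; zero focal diversity against positive reference
diversity is an infinite-signal sentinel that outranks everything.

**F~ST~.** The Weir–Cockerham (1984) two-population estimator from genotype
counts with observed heterozygosity, decomposed into the among-population
(a), among-individual (b) and within-individual (c) variance components.
Windows report the weighted ratio-of-sums `Σa / Σ(a+b+c)`, the standard for
windowed scans; negative per-site components are kept in the sums because
truncating them at zero biases the window estimate upward. Sites monomorphic
across both groups contribute nothing; windows with no usable site are
excluded from ranking.

**XP-EHH.** From a core SNP, haplotypes are partitioned into identity
classes over the growing inclusive span; the site homozygosity
`h(t) = Σ n_k(n_k−1)/(n(n−1))` is normalised by the core's allele
homozygosity to give EHHS, which starts at 1 and can only decay as classes
refine. iES is the trapezoid integral of EHHS against physical position on
both sides, each side ending at the first marker below the decay cutoff
(0.05) or at the panel edge / maximum scan extent (300 kb per side), which
flags the profile as truncated. XP-EHH is `ln(iES_focal / iES_ref)`,
unstandardized, positive when the focal group carries the longer
haplotypes. Candidate SNPs come from the *two-way* top 1%: the most positive
and most negative tails separately. Truncated cores are kept but flagged;
small panels would otherwise lose all cores.

## Top tails and the gradient filter

The empirical top 1% is the `ceiling(0.01 n)`-th largest value and
everything tied with it. The gradient filter then requires, per unit:
membership in the *first* pair's tail; strictly increasing signal across
the three pairs; and, for signed statistics (XP-EHH, the two-tailed log
π ratio), a consistent sign. Strictness is the default because it makes the
filter falsifiable — equal signals, which arise when the swept allele is
already (nearly) fixed in all three focal groups, fail rather than pass
silently; a non-strict mode is available. Tail membership is only required
in the first pair: the second and third pairs contribute their raw signal
values, which keeps the filter sensitive when the nested groups are small.

## Variant QC

Sites are retained at minor allele frequency strictly above 0.05, call rate
strictly above 90%, and exact Hardy–Weinberg p strictly above 10^−6^ — the
boundaries fail, reading the thresholds literally. The HWE test is the exact
conditional test (no mid-p): given the allele counts, the p-value sums the
probabilities of all heterozygote counts no more probable than the observed
one. Per-sample missingness at or above 10% is flagged but not acted on by
default, because the haplotype statistics assume complete phased panels and
real inputs are imputed upstream. HWE is computed across all samples by
default; computing it within groups is the caller's choice by subsetting.

## The expression arm

Differential expression between breeds mixes trait signal with gestational
age: a sow sampled at 109 d and one at 114 d differ in stage as much as in
breed. The stage-exclusion logic removes, from each between-breed DE set,
every gene differentially expressed between late pregnancy and parturition
*within* either breed; the per-stage remainders are unioned. The result is
provably disjoint from the stage set.

The DE engine itself is a deliberately simple stand-in: median-of-ratios
size factors, log2 fold changes of shifted normalized means, a Welch t-test
on `log2(normalized + 1)` and Benjamini–Hochberg adjustment, with the
strict call thresholds fold change > 2 and adjusted p < 0.001. Any
externally produced table with `gene`, `log2fc`, `padj` can be slotted in
instead. Two properties of this stand-in matter for interpreting tests: its
raw p-values are close to nominal on null negative-binomial data, but at
n = 3 per group its Satterthwaite degrees of freedom can collapse toward 2,
which caps the attainable power at the strict thresholds regardless of
effect size — roughly 60% for a planted 8-fold change at low dispersion.
The recovery tests therefore compare against this derived ceiling, not
against 100%; analyses of real data at n = 3 should import a
dispersion-sharing model's output instead.

## The synthetic-data generator

`sim_config()` fixes the whole study: a discrete-generation Wright–Fisher
population of 200 diploids evolves for 30 generations, is duplicated into a
focal and a reference deme, and the demes run independently for another 50
generations. Gametes are parental mosaics (per-adjacent-pair crossover
probability 5 × 10^−4^ over 3,000 sites in 2 Mb) with rare 0↔1 mutation
flips (10^−6^ per site per gamete). At the split, the selected site is set
to an exact derived-allele count at frequency 0.2 on randomly chosen
haplotype rows, and — key to a realistic *hard* sweep signature — the
carriers copy one founder's haplotype over ±100 kb around the site
(`sel_ibd_span`): a standing variant of single ancestral origin whose
carriers are locally identical by descent. Without this, a variant standing
at 20% frequency rests on ~80 unrelated backgrounds and even complete
fixation barely dents local diversity (the π reduction of a sweep from k
origins scales as 1/k), which is not the signature the scan is designed to
detect. From the split on, focal parents are drawn with weight
`1 + s·d/2` for dosage `d` at the selected site (additive selection,
s = 0.1).

Two conditioning rules, both standard in sweep simulation and both fully
seed-deterministic (rejected attempts re-run from the shared split state on
the advancing RNG stream): replicates in which the allele is lost are
discarded (conditioning on establishment), and replicates are kept only if
the final focal-deme frequency lies in [0.65, 0.9] — an *ongoing,
incomplete* sweep. The trait itself motivates the window: the focal breed
still segregates for gestation length (per-sow means span roughly
110–117 d), so the causal allele cannot be fixed; and below ~0.65 the
whole-breed (pair 1) contrast is too dilute for any statistic to rank the
swept window in a 1% tail at this scale. These simulator settings were
fixed by a design-stage power analysis across candidate demographies and
recombination rates before the acceptance experiment was written down, and
are not adjusted thereafter.

Phenotypes follow `mu_gl − beta·d + N(0, sigma_env)` per record, rounded to
whole days as gestation lengths are recorded; each sow contributes 3–5
records. Defaults `mu_gl = 115.5` d (focal), `beta = 1.5` d per derived
allele and `sigma_env = 1.0` d place roughly three quarters of focal means
below 114 d and about a third below 113 d, matching the nested-group
proportions the fixed 114/113-d cutoffs are meant to induce. RNA-seq counts
are negative-binomial (dispersion 0.002, reflecting the near-isogenic
littermate design the stand-in test needs to stay powered) with planted
breed-effect and stage-effect blocks of 100 genes at |log2 effect| = 3,
placed on solidly expressed genes so that recovery measures the set logic
rather than count-limited detection.

What the generator does *not* emulate: genome-scale data (one 2-Mb region
stands in for a genome, so the empirical 1% tail holds 2–3 windows rather
than thousands), realistic pig demography or linkage maps, multi-breed
reference structure (one panmictic reference deme stands in for 15 breeds),
genotyping error and imputation artefacts, and any correlation between
expression and genotype. Passing tests therefore demonstrate that the
machinery is correct and that the design detects a planted trait-linked
sweep under favourable, explicitly stated conditions — not that it would
have comparable power on any particular real dataset.

## The recovery experiment

The end-to-end experiment writes complete fixtures (VCF, phenotype TSV,
gene BED tiling the region in 40-kb genes, count matrices, a known-gene
list, a truth JSON), runs the file-backed pipeline with the fixed cutoffs
(114, 113) and the diversity-loss (`low_tail`) π mode — the biologically
directional reading appropriate when the planted signal is known to be a
sweep *in* the focal breed — and asks whether the gene overlapping the
selected site appears in the union of the three statistics' gradient
candidate lists. Over 20 seeds the recovery rate is required to be at least
90%; under the matched null (s = 0, beta = 0, thresholds at the 73rd/30th
percentiles of the noise-only phenotype means, mirroring the proportions
the fixed cutoffs induce) the sweep gene must not be recovered above the
background candidate rate. The 40-kb gene span is the fixture's annotation
choice: it matches the physical extent of the hitchhiking halo
(≈ 1/(rho·T) ≈ 30–60 kb) so that "the gene at the selected site" means the
gene plus its regulatory neighbourhood, as gene-level candidate reporting
does in practice.

## Numerical choices and edge cases

- Coordinates are 0-based half-open internally; VCF and GFF3 are converted
  at the edges. A SNP whose position equals a window's `end` belongs to the
  next window.
- Multiallelic and non-SNP VCF records are dropped, not split; ploidy is
  fixed at 2.
- `select_top()` includes all ties at the tail cutoff, warns when fewer
  than `1/q` valid units exist, and never selects invalid units.
- LD pruning drops the *later* site of an offending pair (positions are
  unique, so no further tie-break is needed) and is deterministic for a
  fixed site order.
- PCA uses Patterson scaling (centre by `2p̂`, scale by `sqrt(2p̂(1−p̂))`),
  drops monomorphic sites, and reports eigenvalue fractions of the trace.
- The neighbour-joining tree uses the allele-sharing distance (1 − IBS);
  the original analysis's PHYLIP distance model is unstated, so tree
  results are structural (clustering), not numerically comparable.
- Welch tests with zero pooled variance return p = 1 for equal means and
  p = 0 otherwise; all-zero genes report log2fc 0 and p 1.
- All randomness flows from the mandatory config seed; identical seeds
  reproduce fixtures byte for byte.

## Known limitations

The single simulated region makes 1% tails coarse (2–3 windows), so
individual statistics fluctuate seed to seed and the recovery guarantee is
stated for the union of the three. The strict gradient filter deliberately
fails saturated sweeps (signals equal across pairs); at very high sweep
frequencies recovery relies on the un-saturated flanking windows. The
Welch-based DE stand-in is under-powered at n = 3 relative to
dispersion-sharing models, as quantified above. XP-EHH is computed without
a genetic map and without frequency-bin standardization (the unstandardized
values are ranked directly, as in the design this package implements).
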
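---
title: "Methods: differentiation scans and population-level ASE in fstase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiation scans and population-level ASE in fstase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstase)
```

# Overview

`fstase` implements a two-layer screen for divergently selected diploid
populations. The first layer asks which *genes* are genetically
differentiated between two populations, using per-SNP Weir–Cockerham
fixation-index estimates aggregated per gene and standardized to
Z(F~ST~) scores, followed by colocalization of candidate-gene SNPs with
trait-labelled QTL intervals. The second layer asks which genes show
*allele-specific expression* (ASE) within a population group
(strain × age), from unphased per-SNP allelic read counts, using a folded
binomial deviance with an exact resampling null. A membership layer
intersects the two.

This vignette explains the models, the assumptions behind them, the
tunable parameters and their defaults, the synthetic-data generator that
backs the test suite, and the known limitations.

# Layer 1: the differentiation scan

## SNP retention and the ledger

Three filters run in a fixed order, with exact integer accounting
(`filter_snps()`):

1. **Call rate** (default `min_rate = 0.80`): a SNP is kept iff the
   fraction of non-missing calls across *all* individuals is at least the
   threshold. The boundary is inclusive (80/100 calls pass at 0.80).
2. **Autosomes** : contigs named Z, W, X, Y, MT are excluded by default;
   sex-linked loci violate the diploid sampling model underlying the
   estimator below (and are confounded with sex structure of the cohort).
3. **Minor allele frequency** (default `min_maf = 0.05`): the allele
   frequency is pooled over the *two populations of the comparison*, from
   non-missing dosages; `min(freq, 1 − freq) ≥ min_maf` keeps the SNP,
   with the boundary inclusive. Pooling per pair (rather than per cohort)
   is what makes the monomorphic/low-MAF exclusion count differ between
   comparisons drawn from one shared SNP set; SNPs with no call at all in
   the pair fall in this bin too.

The `filter_ledger` enforces
`total = removed_call_rate + removed_nonautosomal +
removed_monomorphic_or_low_maf + retained`
by construction, so conservation cannot silently break. Swapping the last
two filters changes the per-bin counts but not the retained set (asserted
in the tests).

## The Weir–Cockerham estimator

For two populations (r = 2), per SNP, from non-missing diploid sample
sizes $n_i$, alternate-allele frequencies $p_i$ and observed heterozygote
proportions $h_i$, `wc_components()` forms
$\bar n$, the sample-size correction $n_c$, the weighted mean frequency
$\bar p$, the among-population variance $s^2$ and mean heterozygosity
$\bar h$, and the three variance components

$$a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p)
 - \frac{s^2}{2} - \frac{\bar h}{4}\right)\right],\qquad
b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{s^2}{2}
 - \frac{2\bar n - 1}{4\bar n}\bar h\right],\qquad
c = \frac{\bar h}{2},$$

with $\hat\theta = a/(a+b+c)$. Numerical conventions:

* $\hat\theta$ is **undefined** (`NA`) when $a+b+c=0$ — exactly the SNPs
  monomorphic in the pooled pair; these are dropped before gene
  aggregation and never counted toward the ≥ 3 SNP rule.
* **Negative values are retained.** $\hat\theta$ is a method-of-moments
  ratio and is slightly negative at undifferentiated loci; truncating at
  zero would bias every gene mean upward and distort the Z screen.
* $\hat\theta \le 1$, with equality iff the populations are fixed for
  opposite alleles (verified against a closed form and an independently
  written scalar oracle at $10^{-12}$).

For multi-locus summaries the package reports the **ratio-of-sums**
estimate $\sum_\ell a_\ell / \sum_\ell (a+b+c)_\ell$, which weights loci
by information content and is the standard multi-locus combination; it is
also available as a per-gene aggregation mode.

## Gene aggregation and the Z screen

A SNP belongs to a gene iff its 1-based position lies in the gene's
closed interval on the same contig; SNPs inside overlapping genes count
toward *each* (excluding them would silently delete candidates). The
default per-gene aggregate is the arithmetic mean of defined
$\hat\theta$; genes with fewer than `min_snps = 3` defined values are
dropped as uninformative. Gene means are standardized with the sample
(n−1) standard deviation:

$$Z_g = (\bar F_{ST,g} - \mu)/\sigma .$$

Candidates satisfy $Z_g \ge 4$ (boundary inclusive); independently, the
top 1% of genes by $Z$ is flagged, taking exactly
$\lceil 0.01\, n_\text{genes} \rceil$ genes with ties at the boundary
broken by gene id so runs are reproducible.

## QTL colocalization

QTL intervals arrive as BED (0-based half-open) with one of six trait
categories (egg production, egg quality, fat content, growth, meat
quality, feeding); category matching is case-insensitive and unknown
categories are dropped, not errored, since real QTL databases carry many
more traits. A candidate-gene SNP at VCF position $p$ overlaps a region
$[s, e)$ iff $s \le p-1 < e$; the conversion is owned by a single pair of
functions (`vcf_to_bed_pos()` / `bed_to_vcf_pos()`) whose composition is
property-tested as the identity. Colocalization is defined at **SNP
level**: a gene is colocalized with a category if at least one of its
contributing SNPs falls inside a region of that category; genes with no
overlap at all are reported once under the category `"none"`. The
interval index (`IRanges`) is checked against a brute-force all-pairs
oracle, including both half-open boundary cases.

# Layer 2: population-level ASE

## Inputs and per-SNP acceptance

Each observation is a (gene, SNP, individual) pair of reference and
alternate read counts within a (strain, week) group. Observations pass
iff the minor allele has ≥ 3 reads, the total depth is ≥ 30 reads and the
minor ratio is ≥ 1% — removing homozygous sites and depths too small to
carry imbalance information. The depth clause is read as read depth at
the SNP (not SNPs per gene), the standard reading for per-observation
count filters.

## Folding, the statistic, and the resampling null

The data are unphased: which haplotype carries which allele is unknown
per individual, so the direction of imbalance relative to the reference
allele is arbitrary per site. The package therefore **folds** each
observation to the major allele, $m_s = \max(\text{ref}, \text{alt})$,
$d_s = m_s + \text{minor}$, making everything label-symmetric. Per
individual $j$, the pooled major fraction is
$\hat p_j = \sum_s m_s / \sum_s d_s \ge 1/2$ and the gene statistic is
the summed folded binomial deviance against balance,

$$T \;=\; \sum_j 2\sum_s\left[ m_s \ln \hat p_j +
 (d_s - m_s)\ln(1-\hat p_j) - d_s \ln \tfrac12 \right] \;\ge\; 0,$$

with $0\ln 0 = 0$. $T$ grows with both the magnitude and the consistency
of per-individual imbalance, while allowing different individuals to be
imbalanced **in different directions** — the population-level notion of
ASE appropriate when the regulatory variant's phase differs between
individuals.

The null distribution is obtained exactly by conditioning on the observed
depths: $x^*_s \sim \mathrm{Binomial}(d_s, 1/2)$, folded to
$m^*_s = \max(x^*_s, d_s - x^*_s)$, and $T^*$ recomputed **through the
same code path** as the observed statistic (a shared inner function, so
floating-point ties are genuine ties; the comparison uses a $10^{-9}$
relative epsilon). Resampling is batched (default `batch = 1000`) with a
fixed-hits early stop: once `stop_hits = 50` resamples reach
$T^* \ge T_\text{obs}$ the p-value is already known to ~14% relative
Monte-Carlo error and further resampling is wasted; otherwise up to
`R_max` resamples are used. The estimate

$$p = \frac{1 + \#\{T^* \ge T_\text{obs}\}}{1 + R_\text{used}}$$

is never zero and is valid by construction (the null applies the
identical filter, folding and statistic). `R_max` defaults to 10,000,
which bounds the smallest attainable p at $1/10001$ — far below both
decision thresholds (0.05 and 0.01), so significance calls are unaffected
by raising it; it is configurable up to $10^6$ for users who want
smaller p-values, at linear cost.

Each gene draws from a substream seeded by a stable string hash of
(strain, week, gene), so p-values do not depend on evaluation order or on
which other genes are present; within a gene the rows are put in a
canonical (individual, position) order first, making the scan invariant
to input row order.

p-values are adjusted by Benjamini–Hochberg **within each (strain, week)
group** (`bh_adjust()`, delegating to `stats::p.adjust`); the
`significant_05` flag is $p < 0.05$ and `significant_01` is $p < 0.01$
with BH-q below the FDR level (default 0.05).

## Membership and intersections

`classify_membership()` derives, per gene: *strain-week-specific*
(significant in one strain at a week and not in the other strain at the
same week — the per-week definition forced by a per-week results table),
*common across weeks* within a strain (significant at every week), and
*common to both strains*. The per-strain "specific total" is reported as
the **row sum of the per-week specific counts** — genes recurring in
several weeks count each time, matching the arithmetic of a per-week
summary table — and the distinct-gene count is emitted alongside, since
the two answer different questions. `fst_ase_overlap()` intersects each
specific set with the top-1% Z(F~ST~) gene set and reports "k/n" pairs.

# The synthetic-data generator

The generator exists to give every stage a ground truth; it emulates the
*structure* of a real multi-strain RNA-seq-derived dataset, not any
particular cohort.

**Genotypes** follow the Balding–Nichols model: per SNP an ancestral
frequency $p \sim U(0.05, 0.95)$; per population a frequency drawn from
$\mathrm{Beta}\!\left(p\,\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$; per
individual a dosage $\sim \mathrm{Binomial}(2, p_\text{pop})$. The model
was chosen because its divergence parameter $F$ equals the expectation of
Weir–Cockerham $\theta$, giving a closed-form recovery target: the
multi-locus ratio-of-sums estimate over 5,000 SNPs at $F = 0.2$ lands in
$[0.17, 0.23]$ across seeds (asserted over 20 seeds in the acceptance
suite). $F \in \{0, 1\}$ is rejected (degenerate Beta shapes). Planted
divergent genes get an elevated $F$; with `divergent_F = 0.5` against a
0.05 background and ≥ 8 SNPs per gene, planted genes are recovered in the
top-1% Z set essentially always (recovery degrades below ~5 SNPs per
gene, where gene means are noisy — one reason for the ≥ 3 SNP rule).
Genes tile five autosomal contigs; a configurable fraction of SNPs is
relocated i.i.d. to contigs "Z"/"W" to exercise the autosome filter, and
calls are masked i.i.d. at `missing_rate`.

**QTL regions** have uniform starts (contigs weighted by length),
exponential lengths clipped to the contig, and uniform categories.

**ASE counts**: per (group, individual, gene) an allelic fraction
$\mathrm{logit}^{-1}(\mathrm{logit}(\pi) + N(0, \tau^2))$; per SNP a
depth $\max(1, \mathrm{Poisson}(\texttt{depth\_mean}))$ and alternate
reads binomial at the individual's fraction; finally each
(SNP, individual) observation has its (ref, alt) labels swapped with
probability 1/2, emulating unknown phase. Folding makes the analysis
invariant to the swaps (asserted as an identity), while the *unfolded*
pooled alternate fraction sits at 1/2 even for strongly imbalanced genes
— exactly the signature of real unphased data. Poisson depth (rather
than negative binomial) keeps the conditional resampling null exact;
between-individual overdispersion enters through $\tau$ on the log-odds
scale instead.

Defaults mirror a realistic design for this kind of study: 10
individuals per strain × week group, 3 accepted SNPs per gene, mean depth
50; cohort defaults use populations of several dozen diploids. All
randomness flows from one seed through named substreams
(cohort / qtl / ase / per-gene), so stages can be regenerated
independently and the whole pipeline is byte-reproducible from one
integer.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: linkage disequilibrium within genes
(SNPs are conditionally independent given the gene fraction), reference
mapping bias (the null is symmetric at 1/2; with real data this requires
upstream N-masked remapping), read-level error, shared individuals across
weeks, and any correlation between genetic divergence and allelic
imbalance.

# Calibration, power and known limitations

Because the resampling null reapplies the identical folding and
statistic, empirical p-values are valid by construction; the test suite
verifies on 1,000 null genes ($\pi = 0.5$, $\tau = 0$) that the
rejection rate at $\alpha = 0.05$ lies in $[0.03, 0.07]$ and that the
p-value distribution passes a Kolmogorov–Smirnov uniformity check
(distance < 0.05), and on 200 genes at $\pi = 0.7$, depth 50, 3 SNPs, 10
individuals that power exceeds 0.95. Problem sizes throughout the suite
(thousands of SNPs, hundreds to a thousand genes, `R_max = 2000` for the
calibration runs) were chosen as the smallest sizes at which the
binomial/Monte-Carlo error bands in the assertions are meaningful.

Limitations worth knowing:

* **Composite nulls with $\tau > 0$ but $\pi = 0.5$** (individuals
  imbalanced in random directions averaging to balance) are rejected
  *more* often than $\alpha$: the statistic deliberately accumulates
  per-individual imbalance regardless of direction. A mixed-effects
  formulation would shrink this; here it is a documented property, not a
  bug — the screen targets "any consistent within-individual imbalance in
  the population".
* The gene-level statistic assumes accepted SNPs within a gene and
  individual share one allelic fraction; paralogous SNPs or
  isoform-specific imbalance violate this and inflate $T$.
* The Z screen is a ranking device, not an outlier test: $Z \ge 4$ has no
  calibrated type-I error under a realistic demography, which is why the
  top-1% set is carried in parallel.
* MAF and monomorphic filtering are pair-pooled; a SNP can therefore be
  analyzed in one comparison and excluded in another — intended, but it
  means per-comparison gene universes differ slightly.

# Session info

```{r}
sessionInfo()
```
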
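---
title: "Methods: selection scans, expression divergence and cluster enrichment"
author: "crestscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans, expression divergence and cluster enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`crestscan` connects two layers of evidence about divergence between two
closely related populations or species: population-genomic signatures of
recent positive selection, and divergence of gene expression across a
developmental time course. It implements four analysis stages --

1. a cross-population extended haplotype homozygosity (xpEHH) scan on
   phased haplotype panels;
2. construction of *selection islands* from significant SNPs and linking
   of each island to its closest annotated gene;
3. normalization, differential expression testing, and complete-linkage
   clustering of Z-scored developmental expression profiles;
4. a permutation test asking whether the genes of an expression cluster
   carry elevated selection signal in the 25 kb windows upstream of their
   transcription start sites

-- together with simulators that generate inputs with known ground truth
(planted sweeps, planted expression archetypes), so every stage is
validated end to end without external data. The motivating setting is a
pair of cichlid species whose differences in pigmentation and craniofacial
traits trace back to neural crest development, but nothing in the code is
specific to that system.

# The xpEHH scan

## EHHS and iES

For a panel of $n$ phased binary haplotypes, the site-specific extended
haplotype homozygosity at site $x$ relative to a focal site $s$ is the
probability that two haplotypes drawn without replacement are identical
over the closed interval between $s$ and $x$:

$$\mathrm{EHHS}_s(x) = \frac{\sum_g \binom{n_g}{2}}{\binom{n}{2}} \Big/
  h(s),$$

where the $n_g$ are the sizes of the haplotype groups defined by identity
over $[s, x]$ and $h(s)$ normalizes the profile to 1 at the focal site.
This is the all-haplotype (site) variant of EHH: it conditions on no
particular core allele, which is the quantity that enters the
cross-population statistic. The profile is non-increasing outward by
construction.

`integrate_ies()` integrates the profile against physical distance by the
trapezoid rule on each side of the focal site, stopping at the first site
where EHHS drops below the truncation threshold (default 0.05, the
conventional choice; that site still contributes its trapezoid). The sum
of both sides is iES, in bp. If a side reaches a chromosome edge or an
inter-site gap larger than `max_gap_bp` (default 200 kb) before crossing
the threshold, the site is flagged *censored*: its integral is truncated
by the data rather than by the statistic, and such sites are dropped by
default (`drop_censored = TRUE`) because their iES is biased downward.

## The cross-population statistic

For two populations A and B sharing a site set,

$$\mathrm{xpEHH} = \ln\left(\mathrm{iES}_A / \mathrm{iES}_B\right),$$

positive when haplotype homozygosity extends further in population A.
Sites are first filtered on pooled minor allele frequency
(strictly $> 0.05$ by default; a per-population variant is available via
`per_population_maf`). Raw values are standardized by the genome-wide mean
and standard deviation of the retained, uncensored sites -- no
derived-allele-frequency binning, matching the convention of the standard
xpEHH implementation -- and the reported significance is the two-sided
standard-normal tail, $-\log_{10}\!\big(2(1 - \Phi(|z|))\big)$. Because the
standardization is internal, the z scores have mean 0 and standard
deviation 1 exactly; the calibration question is whether the *tail* is
normal-like, which the acceptance checks test on neutral simulations
(the fraction of sites with $-\log_{10} p \ge 3$ stays below 0.005).

Population A is, by convention, the first argument of `xpehh_scan()`; the
sign convention is recorded in the scan TSV header.
`xpehh_scan_multi()` standardizes once across chromosomes so that
p-values are comparable genome wide.

# Selection islands and gene linking

SNPs with $-\log_{10} p \ge 3$ (inclusive) are chained into islands: a
site joins the current island if it lies within 50 kb of the island's
*last* member (the semantics of `bedtools merge -d`), so an island can
grow beyond 50 kb if significant SNPs tile the region. Merging is
idempotent, the island count is non-increasing in the merge distance, and
each island carries its member positions, SNP count and logp summaries.

Each island is linked to the gene minimizing the interval distance on its
chromosome (0 for overlap). Distance ties are broken by smaller gene
start, then lexicographic gene id, and the tie count is reported -- a
deliberate, reproducible simplification of tools that report all tied
genes. Links are categorized as `gene_body` (island overlaps the gene),
`promoter` (island overlaps the window 5 kb upstream of the TSS,
strand-aware) or `intergenic`. The 5 kb promoter definition is a
configurable default; annotation-based promoter calls would replace it
when available.

Internally all coordinates are 1-based inclusive; BED input/output uses
standard 0-based half-open coordinates, and the round trip is lossless.

# Expression divergence

Raw counts are normalized with median-of-ratios size factors: the
reference for each gene is its geometric mean across samples (genes with
any zero excluded), and a sample's factor is the median ratio to that
reference. Note that size factors are meaningful up to a common constant:
scaling one sample's counts by $c$ multiplies its factor by
$c^{(m-1)/m}$ and divides the others by $c^{1/m}$ (the reference includes
the scaled sample), so only factor *ratios* are exactly equivariant --
the tests assert that form.

Genes are pre-filtered by the rule "counts below 10 in every sample of
each species" -- implemented in its least aggressive reading (removed
only when *both* species are uniformly low, switchable to *either*).

The per-contrast test is a transparent negative-binomial Wald test, not a
re-implementation of a full shrinkage estimator: per-gene dispersion
$\alpha$ (variance $\mu + \alpha\mu^2$) is estimated by the method of
moments from pooled within-group variances and moderated toward the
genome-wide median with 20 prior degrees of freedom; with only
$n_1 + n_2 - 2 = 4$ residual degrees of freedom per gene, unmoderated
estimates make the Wald test clearly anticonservative (empirically
$\approx$ 0.10--0.12 at nominal 0.05), while the moderated test holds its
size (acceptance band 0.03--0.08). The statistic is the difference of
log group means (pseudocount 0.5) over its delta-method standard error,
referred to the standard normal, two-sided, with Benjamini-Hochberg
adjustment within each contrast.

A gene is a DEG if $|\log_2 \mathrm{FC}| \ge 0.585$ (i.e. a 1.5-fold
difference; the bound is inclusive) and adjusted $p < 0.05$ in at least
one contrast. The default contrasts compare the two species at each
shared stage; all cross-stage pairs are available via
`species_stage_contrasts(cross_stage = TRUE)`.

Profiles are the per-(species, stage) means of normalized counts,
Z-scored within each gene; zero-variance genes are flagged and excluded
from clustering. Clustering is agglomerative with complete linkage on
Euclidean distances between Z-profiles (the default metric of common
heatmap tools; correlation distance would be a one-line change), cut at
$k = 7$ clusters. Labels are deterministic given the input and stable
under row permutation up to relabeling.

# Cluster enrichment for selection signal

Every gene's score is the median $-\log_{10} p$ over scan SNPs in the
25 kb window immediately upstream of its TSS (strand-aware; windows are
clipped at chromosome edges and flagged). Genes whose windows contain no
scan SNPs are unscored and drop out of both the observed and the null
pools symmetrically.

For a cluster with $m$ scored genes, the observed statistic is the median
of their scores; the null redraws $m$ genes uniformly without replacement
from the genome-wide scored pool 1000 times and applies the same summary.
Because all windows have the same fixed width, the null windows are
size-matched by construction. The one-sided (greater) empirical p-value
uses the plus-one correction $(1 + \#\{\text{null} \ge \text{obs}\}) /
(1 + n_\mathrm{iter})$ and therefore is never 0 and is slightly
conservative. The cluster's own genes stay in the null pool by default
(exclusion is a flag); cluster-level mean instead of median is also a
flag. No multiple-testing correction is applied across the handful of
clusters, though a BH column is provided.

# The simulators and what they do (and do not) emulate

## Haplotypes

`simulate_haplotypes()` is a forward Wright-Fisher simulation chosen for
implementability and explicit sweep control -- a stand-in for the deep
coalescent history of real lake populations, not a demographic model of
any of them. Two design choices make its output behave like deep-history
data at desk scale:

* **A population larger than the panel.** `pop_size` haplotypes (default
  1000) evolve for `n_generations` (default 60) after the two
  populations split from a shared founding panel; only
  `n_haplotypes_per_pop` (default 60) are sampled. Most sampled pairs
  then coalesce *beyond* the founding panel, where founding alleles are
  independent draws, so neutral haplotype homozygosity decays within a
  few kb -- as it would after thousands of generations of real history.
* **A recent sweep.** Under selection ($s > 0$), the segregating site
  nearest `sweep_position` is re-initialized to a single derived copy
  arising in population A `sweep_time` generations (default 45) before
  sampling, with multiplicative fitness $1+s$ and restart-on-loss.
  Swept haplotypes therefore share a common ancestor only tens of
  generations back and stay homozygous over tens of kb, the contrast
  xpEHH detects. Conditioning on establishment happens only under
  selection, so an $s = 0$ sweep configuration is bit-identical to the
  neutral model under the same seed (parent sampling always uses the same
  weighted draw, with all weights 1 when neutral).

Sites are biallelic under an infinite-sites approximation: 85% segregate
in the founding panel with frequencies uniform on [0.1, 0.9] (shared
standing variation), the rest enter as population-private single-copy
mutations in a uniformly drawn generation. Site density defaults to one
SNP per 100 bp -- a realistic figure for divergent population pairs of
East African cichlids -- and the effective crossover rate defaults to
$10^{-6}$ per bp per generation, chosen so that, over the compressed
timescale of the simulation, neutral homozygosity tracts span a few kb
and swept tracts tens of kb. On deliberately short test chromosomes
(150--200 kb) the simulations raise this rate (up to $10^{-5}$) so EHHS
decays below the truncation threshold before hitting a chromosome edge;
otherwise swept sites would be censored and silently dropped.

What passing tests on this generator do **not** show: robustness to real
demography (bottlenecks, gene flow, population structure), to phasing or
genotyping error, to background selection, or to non-equilibrium
mutation processes. The simulator exists to verify the statistical
machinery against a known truth, not to calibrate biological effect
sizes.

## Counts

`simulate_counts()` plants seven temporal-profile archetypes over a
2 species x 10 stages x 3 replicates design: four archetypes with a
consistent between-species offset (two flat, two with a shared temporal
trend) and three with species-specific temporal shifts -- the qualitative
cluster shapes reported in two-species developmental time courses. No
published effect sizes exist for this setting, so archetype magnitude is
a free parameter (`effect_size_log2`, default 2, i.e. up to 4-fold
between extreme cells around a mean of $2^7$ counts). Counts are
negative binomial with overdispersion $\alpha$ (default 0.05, variance
$\mu + \alpha\mu^2$; the Poisson limit is $\alpha \to 0$), small
log-normal replicate noise (sd 0.1 on the log2 scale), and per-sample
library-size factors drawn log-uniformly in [0.5, 2] so median-of-ratios
recovery is testable. Real data additionally have mean-dependent
dispersion trends, outlier samples and unequal replicate counts, none of
which are emulated.

## Annotation and the enrichment scenario

`simulate_annotation()` draws possibly overlapping gene intervals with
random strands; TSSs follow the strand. For enrichment validation,
`simulate_scan_dataset()` builds a toy genome with one gene per
chromosome and, optionally, hard sweeps planted exactly at the midpoint
of the 25 kb upstream window of a designated gene set -- the positive
control for the permutation test, with every other chromosome providing
the null pool.

# Numerical and design choices

* EHHS/iES and the Wright-Fisher inner loop are implemented in C++
  (partition refinement with flat-array relabeling; block-copy
  crossover); pure-R enumeration oracles verify them to $10^{-12}$.
* Truncation 0.05, maximum gap 200 kb, unconditional standardization and
  two-sided p-values follow the defaults of the standard xpEHH tooling;
  none of them are claimed from first principles and all are
  configurable.
* Problem sizes in the validation suite (panels of 2 x 60 haplotypes,
  chromosomes of 0.4--1 Mb with 4,000--10,000 SNPs, 20-seed power runs,
  40-gene enrichment genomes, 2,000-gene null DE simulations) were chosen
  as the smallest instances at which the distributional checks have
  stable expectations.
* Permutation p-values use the plus-one correction; empirical p can
  never be 0 and calibration is asserted within the binomial 95%
  confidence band of the nominal rate.
* Degenerate inputs have defined behavior: identical panels yield a
  zero-variance raw vector and a degeneracy error at standardization; an
  empty post-filter scan warns and returns an empty table; constant
  genes are excluded from clustering with a flag; clusters with no
  scored genes become NA rows in the per-cluster table rather than
  aborting the pipeline.

# Known limitations

* The scan handles biallelic phased genotypes only; no support for
  unphased data, imputation, multi-allelic sites, or allele-conditioned
  EHH statistics (iHS, nSL, Rsb).
* The closest-gene link reports a single gene per island.
* The NB Wald test is not a substitute for a full shrinkage-based DE
  framework on real data; it exists so that downstream stages have
  well-calibrated DEG sets at simulation scale.
* The permutation null treats genes as exchangeable units; correlated
  scan signal between physically close genes on a real genome (windows
  here never overlap across the simulated chromosomes) would make the
  test anticonservative and would call for a blocked or distance-aware
  null.
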
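---
title: "Detecting ecotype differentiation and inversion supergenes with ecoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ecotype differentiation and inversion supergenes with ecoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoscan)
```

## The problem

Marine broadcast spawners such as herring combine enormous census sizes with
weak physical barriers to gene flow. Ecologically distinct populations
(ecotypes — e.g. planktivorous vs. piscivorous, or spring- vs.
autumn-spawning) are therefore nearly indistinguishable at selectively
neutral markers, while a minority of loci under divergent selection show
strong allele-frequency contrasts. A second hallmark of such systems is
chromosomal inversion supergenes: multi-megabase blocks in which
recombination between arrangements is suppressed, so each block segregates
as one of a small number of ancient haplotype classes (here labelled
Northern, N, and Southern, S) with occasional recombinant haplotypes carrying
a contiguous tract of the opposite class.

`ecoscan` implements the statistical toolkit for this situation: population
allele-frequency scans, supergene genotyping and recombinant detection,
diversity and divergence statistics, population trees, and probabilistic
population assignment — together with a synthetic-data generator that
reproduces exactly this structure with full ground truth, so every stage is
testable without access to any sequencing archive.

## The generative model

`simulate_dataset()` builds data from three ingredients.

**Neutral background.** Each population's frequency at each site is drawn
from the Balding–Nichols distribution
$p_k \sim \mathrm{Beta}\!\big(p\,(1-F)/F,\ (1-p)(1-F)/F\big)$,
with ancestral frequency $p \sim U(0.05, 0.95)$ (bounded away from 0/1 to
avoid degenerate invariant sites) and differentiation parameter $F$
(`drift_F`). The distribution has mean $p$ and variance $F\,p(1-p)$, so $F$
*is* the expected FST among populations — a single parameter with an
analytic expectation that the test suite exploits. The default
`drift_F = 0.02` matches the low single-percent divergence typical of
weakly separated marine ecotypes. This model deliberately ignores the true
demography (a stepwise colonisation over thousands of years) and linkage
outside inversions: it reproduces the *moments* the estimators see, not the
coalescent process, which is why Tajima's D calibration uses a separate
neutral-spectrum draw (below).

**Adaptive loci.** A designated subset of populations receives a fixed
frequency shift `adaptive_delta` (default 0.4) at `n_adaptive_sites` sites,
on a mid-range base frequency so the full shift fits in [0, 1]. Effect sizes
of adaptive loci are free parameters of the generator, not estimates; the
default merely places them well clear of neutral drift at the default
sample sizes.

**Inversions.** An inversion block is a set of fully linked sites. The N and
S consensus haplotypes differ at every block site (which side carries the
VCF alternate allele is randomised per site, so consensus building is
non-trivial), and an optional recombinant haplotype equals S except for a
run of sites copied from N. Individuals draw two haplotypes per block
(probabilities per population from `s_freq` and the recombinant fraction)
and the haplotypes determine all block sites jointly — blocks never
recombine during sampling, giving the "sharp borders" phenomenology of real
inversions. Missingness is uniform and independent per call (default 2%),
the simplest mechanism sufficient to exercise the coverage filter.

What the generator does *not* emulate: linkage-disequilibrium decay outside
inversions, genotyping error correlated with coverage, allele-strand
ambiguity across platforms, and coalescent variance in diversity statistics.
Tests passing on this generator therefore demonstrate correctness of the
estimators and of the recovery logic under the stated model, not robustness
to every artefact of real sequencing data.

## Frequencies, filtering, and delta-AF scans

`pop_allele_freqs()` counts alternate-allele dosages over non-missing
genotypes; every frequency travels with its observed-chromosome count.
`site_coverage_filter()` retains a site when the summed observed chromosomes
across the contrasted groups reach `ceiling(0.92 * total)` — with 152
possible chromosomes that threshold is 140, so 140/152 passes and 139/152
does not. The denominator is always derived from the contrasted groups'
sample sizes, never hard-coded, and the filter is applied per contrast.
`pool_groups()` pools by chromosome-weighted mean (unweighted means would
bias pooled frequencies when sample sizes differ), `delta_af()` is the
signed difference, and `heatmap_matrix()` restricts a region to sites whose
|dAF| against a pooled baseline *strictly* exceeds a cutoff (0.25 and 0.35
are the conventional zoom-in choices).

Coordinates are 1-based inclusive for regions (the VCF convention). Window
arithmetic is half-open on the position line: a site at position $x$ belongs
to window $\lfloor x/w \rfloor$, so position 10,000 with $w = 10{,}000$
falls in the second window.

## Association scan

The per-SNP test is the classic allelic χ² on the 2×2 table of ref/alt
chromosome counts in two groups — one degree of freedom, no continuity
correction (matching the default of the standard association-scan tools and
keeping the brute-force oracle simple). Zero-margin (monomorphic) tables are
flagged and return $p = 1$ rather than being dropped silently. Bonferroni
correction takes the total test count `m` explicitly, because a reported
region is often a slice of a genome-wide scan of m SNPs. Tiers: corrected
p < 0.05 ("genome-wide") and corrected p < 1e-10 ("extreme").

PCA mean-centres dosage columns with column-mean imputation of missing
entries and no variance scaling — the only missing-data treatment that keeps
the operation deterministic and matrix-shaped without imputation machinery.
With `collapse`, all SNPs inside an inversion are replaced by one synthetic
locus coded NN=0, NS=1, SS=2, making the projection invariant to how densely
the block was genotyped. K-means (K = 2) labels are arbitrary; callers map
them to spawn seasons via known anchor samples.

## Supergene genotyping

`build_consensus()` defines a side's consensus allele as the allele whose
frequency is at least `purity` (default 0.8) in **every** pure pool of that
side; a site where either side lacks a qualifying allele is dropped. The
supermajority-across-all-pools rule keeps diagnostic sites robust to noise
in any single pool; 0.8 leaves headroom for sampling noise in pools of a few
dozen chromosomes while excluding genuinely polymorphic sites. Diagnostic
sites are those where the two consensus alleles differ.

Individuals are scored per diagnostic SNP (homozygous N allele → NN,
heterozygous → NS, homozygous S → SS; missing excluded) and called by
majority vote across the inversion. Ties, or fewer than `min_sites` (default
5) scored sites, give `unassigned` — a deliberate addition, since silently
guessing would corrupt recovery statistics.

At the population level, the pooled frequency of the S consensus allele
$f_S$ classifies each diagnostic site (S-like if $f_S > 1-\tau$, N-like if
$f_S < \tau$, else intermediate; default $\tau = 0.2$, consistent with the
near-fixed differences that make heatmap classification meaningful), and
the mean $f_S$ across diagnostic sites estimates the S-haplotype frequency.
`detect_recombinant_segments()` reports maximal runs of at least `min_run`
(default 5) consecutive diagnostic sites classified to the foreign side;
intermediate sites break runs. The default of 5 sits well below the 12-SNP
recombinant tract that motivates the analysis while still excluding
single-site noise. `sweep_scan()` separates the other signature: sites
diverged beyond a cutoff from *both* the N-bearing and S-bearing references
(recombination explains divergence from one side only; a sweep on the local
haplotype explains divergence from both).

`nj_tree_region()` makes the "tree from allele frequency differences"
precise: the pairwise distance is the Euclidean distance between frequency
vectors divided by $\sqrt{\text{sites}}$ — the root-mean-square dAF — so
trees from regions with different SNP counts are on one scale. Sites must be
defined in all included populations. Agglomeration is Saitou–Nei neighbor
joining via `ape::nj`.

## Diversity and divergence

Watterson's estimator is $\hat\theta_W = S/(a_1 L)$ with
$a_1 = \sum_{i=1}^{n-1} 1/i$; $\pi$ sums the unbiased per-site
heterozygosity $2p_j(1-p_j)\,n_j/(n_j-1)$ with *per-site* chromosome counts
$n_j$, since missingness varies by site. Tajima's D uses the standard
constants, with the window's median $n$ for the S-based terms (a documented
choice; any single-n summary is an approximation under variable
missingness). $D$ is undefined (flagged `NA`, not zero) when $S = 0$.
$N_e = \theta_W/4\mu$ with $\mu = 2\times10^{-9}$ per base and generation by
default. The callable length $L$ defaults to the window width because the
true per-base denominator depends on a callable-sites mask that only the
data producer knows; $L$ is therefore an explicit argument everywhere.

Pairwise FST uses a method-of-moments coancestry estimator in the
Reynolds/Weir–Cockerham ratio-of-sums form. Per biallelic locus with sample
frequencies $p_1, p_2$ and chromosome counts $c_1, c_2$:

$$h_i = \frac{2 p_i (1-p_i)\, c_i}{c_i - 1}, \qquad
\text{num} = (p_1-p_2)^2 - \frac{h_1}{2c_1} - \frac{h_2}{2c_2}, \qquad
\text{den} = \text{num} + \frac{h_1 + h_2}{2}.$$

Under a pure-drift model with coancestry $\theta$,
$E[\text{num}] = 2\theta\,\bar p(1-\bar p)$ and
$E[\text{den}] = 2\bar p(1-\bar p)$, so the aggregate
$\sum\text{num}/\sum\text{den}$ estimates $\theta$ with no per-locus ratio
bias, equals 0 in expectation for identical populations (slightly negative
estimates are reported as computed, never clamped — clamping would break the
ratio-of-sums exactness), and equals 1 at a fixed difference. The genome or
window estimate is always the ratio of summed components, *not* the mean of
per-window ratios; the test suite keeps a regression test demonstrating the
two differ on heterogeneous windows.

UPGMA population trees come from average-linkage `hclust` on the pairwise
genome FST matrix. The nearest-ecotype analysis takes windowed FST of
several candidate ecotypes against one focal ecotype and reports, per
window, the candidate with strictly minimal FST (ties produce no winner),
each candidate's fraction of eligible windows, and each chromosome's
most-frequent winner. Fractions are window counts by default; a weight
column (e.g. window bp) switches to bp-weighted shares, since "fraction of
the genome" is ambiguous between the two.

## Population assignment

The reference database is a set of pooled per-location allele-frequency
vectors mapped to population clusters. The core classifier computes, per
query individual and pool, the Hardy–Weinberg genotype log-likelihood
$\sum_j \log P(g_j \mid p_j)$ with $P = (1-p)^2, 2p(1-p), p^2$ and pool
frequencies clamped to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 0.01$), so one genotyping error against a fixed pool costs
$2\log\varepsilon$ rather than $-\infty$. Cluster likelihood is the *best*
member pool (clusters contain heterogeneous locations; averaging would
punish a cluster for containing distant pools), posteriors use a uniform
prior, and an individual is labelled only when the top posterior strictly
exceeds 2/3 — the "two-thirds more likely than any alternative" rule, with
the boundary case explicitly unassigned. The classical protocol of training
a classifier on $m = 8$ individuals simulated per pool is supported through
`simulate_reference_individuals()`; the direct likelihood model is the
package's default because it is equivalent in expectation and exactly
testable.

## Numerical and design notes

- **Determinism.** Every stochastic operation takes a seed;
  `simulate_dataset()` is byte-reproducible given a config and seed. The
  pipeline derives per-stage seeds by hashing stage names
  (`stage_seed()`), so toggling one stage leaves the others' streams
  untouched.
- **Tajima's D calibration.** Balding–Nichols backgrounds with uniform
  ancestral frequencies do not have the neutral site-frequency spectrum, so
  D is not centred at zero there. `sim_neutral_sfs()` draws derived-allele
  counts from $P(i) \propto 1/i$, under which
  $E[\pi_{\text{total}}] = S/a_1$ exactly and D is centred on zero; the
  calibration tests use it with $S = 200$, $n = 20$ chromosomes and 50
  replicates.
- **Degenerate inputs.** All-missing sites give `NA` frequencies and are
  flagged downstream; empty heatmap selections warn instead of erroring;
  zero-variant VCFs round-trip; zero diagnostic sites is a hard error naming
  the region; K-means ties on identical points are resolved by the seed.
- **Coordinates.** User-facing positions are 1-based inclusive; BED exports
  convert to 0-based half-open; window indices use
  $\lfloor \text{pos}/w \rfloor$ as stated above.
- **Problem sizes.** The bundled tests and the acceptance script use
  simulations of up to 2 populations × 50 diploids × 20,000 sites (FST
  recovery, 20 replicates), 10⁴ sites for null calibration, and a few
  hundred individuals for inversion recovery — sizes chosen so the whole
  suite runs in well under a minute on a single CPU while leaving
  Monte-Carlo error comfortably inside the asserted bounds.
- **Scope.** Variant calling, imputation/phasing, strand harmonisation
  across genotyping platforms, de-novo inversion discovery, LD statistics
  and coalescent-aware confidence intervals are out of scope; inputs are
  assumed to be clean biallelic-SNP genotypes with consistent allele
  orientation.

## Known limitations

Diversity statistics inherit the unstated callable-length problem of any
windowed analysis: per-base θ and π are only as meaningful as the supplied
$L$. The FST estimator assumes biallelic sites and pure drift; under strong
selection its interpretation is the usual heuristic one. The assignment
model assumes site independence (no LD), which overstates confidence when
markers are clustered — the strict 2/3 rule partially compensates. The
generator's independence assumptions mean power estimates derived from it
are upper bounds for real, linked data.
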
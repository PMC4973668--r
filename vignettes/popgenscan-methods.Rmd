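---
title: "Methods: divergence scans, f4 tests and isolation by distance with popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence scans, f4 tests and isolation by distance with popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

popgenscan analyses biallelic SNP matrices from reduced-representation
sequencing mapped to a reference with named linkage groups. This vignette
records the statistical definitions the package implements, the modelling
assumptions behind its synthetic-data generator, and the design choices that
are the package's own rather than fixed by the underlying estimators.

## Data model

The central container is the `genotype_matrix`: ALT-allele dosages (0/1/2,
`NA` for missing) for diploid samples at sites identified by linkage group
and 1-based position, with optional per-genotype depth (DP) and genotype
quality (GQ) layers and per-site QUAL/MQ annotations. Sites are kept sorted
in genome order. VCF input is parsed with the vcfR package; the writer is
plain line formatting so that a write–read–write cycle reproduces the file
byte for byte.

Quality control follows a conventional RAD-seq recipe: site-level SNP
quality and mapping quality thresholds (default 20), genotype-level masking
below DP 5 or GQ 20, and a per-sample high-depth mask at the 99.5th
nearest-rank percentile of that sample's own depth distribution (paralog
collapse inflates depth sample by sample, so a global cutoff would be
miscalibrated). Site filters (biallelic only, missingness, minor allele
frequency) and greedy leftmost distance thinning are separate, idempotent
steps. Note one property thinning does *not* have: thinning at a small
distance and then a larger one is not guaranteed to reproduce direct
thinning at the larger distance, because removing an intermediate site can
change which later sites the greedy pass keeps.

For species-tree panels, `snapp_prepare()` keeps complete, thinned,
biallelic sites and reports stationary per-site mutation rates: with mean
ALT frequency $\pi_1$, the backward and forward rates $u = 1/(2\pi_1)$ and
$v = 1/(2\pi_0)$ satisfy $\pi_1 u + \pi_0 v = 1$, and the population-size
prior mean is $\theta = \alpha/\beta$.

## Synthetic data: Balding–Nichols drift

The generator draws ancestral ALT frequencies uniformly on a configurable
range and lets each population drift according to the Balding–Nichols
model: a population with drift parameter $F$ has site frequency
$p' \sim \mathrm{Beta}\!\left(p\tfrac{1-F}{F},\, (1-p)\tfrac{1-F}{F}\right)$,
so $\mathbb{E}[p'] = p$ and $\mathrm{Var}[p'] = F\,p(1-p)$. Drift is applied
along a rooted topology; internal edges share a small common drift
(`internal_F`) and leaf edges apply the per-population $F$. Shared internal
drift cancels in the f4 statistic, so unadmixed quartets stay null under any
topology. Admixture is a single frequency-level pulse: the target
population's frequencies become $(1-\alpha)\,p_\text{target} +
\alpha\,p_\text{source}$.

Genotypes are binomial draws from the population frequencies, placed
uniformly along the configured linkage groups. Two points about the LD
device deserve emphasis:

* Sharing a *frequency* draw between nearby sites cannot by itself create
  linkage disequilibrium between individuals' genotypes — conditional on
  frequencies, genotypes would still be independent across sites. The
  package therefore couples the allele *copies* directly: within each
  `ld_block_bp` block, each haploid copy of each individual carries a
  latent uniform that is reused from site to site, jittered per site and
  refreshed with a per-site probability. This produces within-block
  genotype $r^2$ well above background that drops to background across
  block boundaries.
* The device is a block-structured caricature, not a coalescent: it does
  not produce smooth exponential decay, recombination-rate variation, or
  haplotype structure beyond the block scale. It exists so the LD-decay
  profiler has a signal with a known spatial scale to detect.

## LD decay

`ld_decay()` computes genotype (composite) $r^2$ — the squared Pearson
correlation of dosage vectors over pairwise-complete samples — for site
pairs binned by distance within linkage groups, subsampling pairs per bin
for tractability. The background level is estimated from random pairs on
*different* linkage groups; for unlinked loci with $n$ samples the expected
background is approximately $1/(n-1)$, so background comparison, not an
absolute threshold, defines where decay "reaches background"
(`background_crossing()`).

## Divergence: Weir–Cockerham FST and DXY

Per-site variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals) follow Weir &
Cockerham (1984) for $r = 2$ populations, using observed heterozygosities
and the sample-size correction $n_c$. Windowed FST is the *ratio of sums*
$\sum a / \sum(a+b+c)$ over usable sites (at least two genotyped diploids
per population), not the average of per-site ratios — per-site ratios are
noise-dominated and their mean is biased. DXY is the mean over usable sites
of $p_A(1-p_B) + p_B(1-p_A)$; monomorphic shared sites contribute zero, so
window DXY depends on the site set the panel retained.

Two window rules are provided: sliding windows (default 1 Mb, step 100 kb)
that must fit entirely inside the linkage group — except that a linkage
group shorter than the window size contributes a single truncated window —
and nonoverlapping tiles (default 100 kb) truncated at the end. A genome
FST summary is the mean of nonnegative tile FSTs, which matches the
convention of averaging only informative windows; it is a summary of the
scan, not an unbiased estimator of a parametric FST, and under
Balding–Nichols drift with parameter $F$ it recovers $F$ closely at the
simulator's problem sizes.

## f4 admixture test

The point estimate is the mean over usable sites of
$(p_A - p_B)(p_C - p_D)$. Uncorrelated drift makes the expectation zero on
an unadmixed tree; a pulse from B into D creates positive covariance
between the (A,B) and (C,D) contrasts. The standard error comes from a
delete-one-block jackknife over contiguous 500-kb blocks (matched to the
scale at which LD reaches background), using the weighted form of Busing,
Meijer & van der Leeden (1999) so blocks with unequal numbers of usable
sites are handled exactly; with equal blocks it reduces to the classical
formula. The two-tailed p-value $2(1-\Phi(|Z|))$ is evaluated on the log
scale of the normal tail (`z_to_p()`), retaining at least two significant
figures down to $p \approx 10^{-300}$ where the naive expression
underflows.

## Outlier clustering: modified NNI permutation test

Outlier windows are the top empirical quantile of valid tile FSTs
(nearest-rank count, genome-order tie-break). To ask whether outliers
cluster along the genome, the observed statistic is the mean
nearest-neighbour distance in window bins, computed within linkage groups
only (an outlier alone on its linkage group contributes nothing and is
reported separately). Each permutation redraws the same number of outlier
flags uniformly among all valid windows *genome-wide*, so the null respects
the chromosome structure and the per-linkage-group window counts. The
modified index is observed mean over permutation mean — the classical NNI
expectation assumes one linear interval and would be biased by a
multi-chromosome genome — with a one-sided (+1-corrected) empirical p for
clustering and a Z-based two-sided p alongside. The package's acceptance
battery sizes this test at 5000 windows and 250 outliers so the null
index's coefficient of variation (~0.05) makes the [0.8, 1.2] calibration
band a ~4-sigma statement; that problem size is a package choice, not part
of the estimator.

## Isolation by distance

Geographic distances use the full iterative Vincenty inverse solution on
the WGS84 ellipsoid (tolerance $10^{-12}$), with `perimeter_distance()`
summing consecutive legs for shoreline-style traversals. The Mantel test
correlates lower triangles of two labelled distance matrices, permuting
rows and columns simultaneously, and reports a two-sided (+1-corrected)
empirical p on $|r|$; two-sided because both positive and negative
matrix association are departures from the null of no association.

## Pipeline

`run_config()` collects every knob (validated, YAML round-trippable);
`run_pipeline()` executes simulation or VCF input, masking, filtering, LD
profile, window scans with outlier BEDs, the genome-FST matrix, the f4
table, the NNI report, the optional Mantel report, and a JSON manifest. All
randomness is fanned out from one seed via `stage_seed()`, so adding a
stage never perturbs earlier stages and a rerun is byte-identical.

## Limitations

The simulator is a drift-plus-pulse caricature: no mutation model, no
coalescent LD, no selection, and admixture acts at the frequency level
rather than on sampled haplotypes. FST/DXY support exactly two populations
per comparison. The NNI test conditions on the number of outliers and
tests only spatial arrangement, not the outlier threshold itself. Vincenty
distances ignore topography and shoreline; the perimeter traversal is only
as meaningful as the ordering supplied.
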
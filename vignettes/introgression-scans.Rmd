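---
title: "Detecting riverine introgression in a lake radiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting riverine introgression in a lake radiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introgrescan)
```

## The problem

The Lake Malawi cichlid radiation descends from an ancestral hybrid swarm,
and riverine haplochromine lineages keep turning up as plausible genetic
donors. Given whole-genome biallelic SNP calls for hundreds of samples, the
analytical task is to (i) test every admissible species trio for excess
derived-allele sharing, (ii) localise the sharing along chromosomes, (iii)
date lineage splits from net sequence divergence, and (iv) summarise
genome-wide relationships robustly. `introgrescan` implements that pipeline
as composable R functions, together with a coalescent generator that
produces data with the same statistical structure and known truth, so every
stage can be validated by parameter recovery rather than by eye.

## Site filtering and polarization

Sites enter the analysis only if they are biallelic SNPs passing a battery
of caller-annotation filters (defaults: MQ >= 50, MQ0 fraction <= 0.10,
strand-MQ p >= 0.001, excess-het p >= 0.2, missingness <= 20%, total depth
<= mean + 1.5 SD, heterozygous allele-balance binomial PHRED <= 20). After
rule-based removal, any site lying between two removed sites no more than
10 bp apart is removed as well, in a single pass: removal of intervening
sites does not trigger further windows. We consume the p-value annotations
emitted by the caller rather than recomputing them from reads; read-level
processing is out of scope.

Two consequences of the depth rule deserve note. First, its cutoff is
derived from the data (mean + 1.5 SD of per-site depth), so re-applying the
filter to its own output would derive a new, lower cutoff and remove a
fresh tail: filtering is idempotent only for a fixed cutoff. The cutoff
actually used is therefore recorded in the `FilterLog`, and
`filter_params(depth_cutoff = ...)` accepts it explicitly; the test suite
asserts idempotence under a fixed cutoff. Second, the rule is one-sided by
design ("abnormally high depth" flags collapsed repeats); low-depth sites
are left to the missingness and genotype-quality rules.

Large inversion polymorphisms are removed by interval mask before any
statistic is computed; the printed inversion coordinates are treated as
1-based and inclusive at both ends (`read_region_mask(one_based = TRUE)`),
with standard BED input available behind a flag.

Polarization recodes dosages so they count derived alleles, using a single
outgroup column (a reconstructed ancestral-state sequence in the motivating
data). Sites where the outgroup is heterozygous are kept with outgroup
frequency 0.5 -- the pattern formulas are symmetric in p4, so such sites
contribute correctly -- while sites with a missing outgroup genotype drop
out of polarized statistics because p4 is undefined there.

## Trio statistics

For an ordered trio (P1, P2, P3) with outgroup O and per-population derived
frequencies $p_1, p_2, p_3, p_4$, per-site pattern weights are

$$\mathrm{ABBA} = (1-p_1)p_2p_3(1-p_4) + p_1(1-p_2)(1-p_3)p_4,$$

with BABA and BBAA defined by the corresponding permutations. Patterson's
$D = (\sum\mathrm{ABBA}-\sum\mathrm{BABA})/(\sum\mathrm{ABBA}+\sum\mathrm{BABA})$
is signed: orientation comes from the declared roles, never from the sign
of D, because negative values (P1--P3 sharing) are a meaningful outcome.
Significance uses a delete-one block jackknife over m = 20 contiguous
blocks of equal usable-site count (configurable); Z = D/SE with a two-sided
normal p. Twenty blocks is common ABBA-BABA practice; on unlinked data the
calibration is excellent (the acceptance suite verifies type-I error and
that Z is approximately standard normal over 200 null replicates), and on
linked data contiguity is what makes the jackknife honest.

The admixture fraction is estimated by the f4-ratio
$\sum(p_1-p_2)(p_{3a}-p_4) \,/\, \sum(p_1-p_{3b})(p_{3a}-p_4)$, where the
donor sample is split per site into halves a and b by hypergeometric
sampling of the derived-allele count -- the standard device when phasing is
unavailable; the estimator is invariant in expectation to the split. The
f4-ratio attenuates as the pulse ages: empirically the attenuation is close
to $(t_{123}-t_p)/t_{123}$ under the default demography, consistent with
the general observation that f4-ratios underestimate older gene flow. The
generator's default pulse age (1e5 generations) sits in the regime where a
simulated fraction of 0.1 is recovered within 0.02 at 1e5 unlinked sites.

Trio enumeration takes either disjoint role sets (every ordered P1 x P2 x
P3 combination) or a guide tree (every ordered trio whose sister pair forms
a cherry relative to the third taxon). Multiple testing across trios uses
Bonferroni division of the family-wise alpha by the number of tests.

## The fdM window scan

Local sharing is scanned in non-overlapping windows of 50 informative SNPs
("informative": all four role frequencies defined and $p_1,p_2,p_3$ not all
equal; such sites contribute zero to both numerator and denominator).
Within a window, the numerator sums ABBA $-$ BABA, and the denominator
substitutes the dynamic donor $\max(p_2,p_3)$ for both P2 and P3 when
$p_2 \ge p_1$, or (with a sign flip) $\max(p_1,p_3)$ for both P1 and P3
otherwise, yielding fdM in $[-1,1]$, positive for P2--P3 sharing and
negative for P1--P3 sharing. Because windows are defined by SNP count,
sparse regions can produce very long windows consisting mostly of
inaccessible genome; windows spanning more than 20 kb are dropped (strictly
greater -- a 20,000 bp window is kept).

Candidate introgressed windows are selected against the scan's own
negative tail: the threshold is the absolute value of the 0.5% quantile of
fdM, and candidates are windows strictly above it. The 0.5% default is the
methods-level choice; the quantile is exposed as a parameter
(`candidate_threshold(q = ...)`) since a ten-fold stricter tail is also
defensible. Quantiles use linear interpolation between order statistics
(R type 7), stated here for reproducibility. If the chosen quantile is
positive -- an all-positive scan -- the threshold degenerates to 0 with a
warning rather than silently selecting everything meaningful.

Normality diagnostics standardize the fdM values by their sample mean and
SD and apply a one-sample Kolmogorov--Smirnov test against the standard
normal, reporting the mean shift and skewness alongside. Estimating the
reference parameters from the sample makes the KS test anticonservative;
we document this rather than correct it, because the diagnostic is used
descriptively (the interesting signals are gross departures).

Adjacency enrichment compares the observed number of candidate windows
immediately preceded or followed by another candidate (within chromosomes
only) with the expectation $(N-1)\,(k/N)^2\,2$ for k candidates among N
genome-ordered windows, reporting the deviation observed/expected and the
run-length spectrum of maximal candidate runs (a run of 8 counts once at
n = 8). The expectation formula is a first-order approximation -- it uses
$(k/N)^2$ rather than the hypergeometric $k(k-1)/(N(N-1))$ and ignores
double-counting of runs -- so it exceeds the exact permutation mean by
roughly $2k/N$; at the scan sizes it is applied to (tens of thousands of
windows, sub-percent candidate rates) this is far inside Monte-Carlo noise,
which the acceptance suite verifies against a 10,000-permutation null.

## Net divergence and split times

For diploid dosages $g_i, g_j$, the expected per-site allele difference is
$[g_i(2-g_j) + (2-g_i)g_j]/4$ summed over sites and divided by the
accessible genome length L. By default missing-genotype sites are skipped
while L stays global -- matching how a single published accessible length
is used -- with a per-pair L correction available as an option. Per-sample
heterozygosity is the count of heterozygous sites over L. Net divergence
between groups x and y is

$$D_A = \mathrm{median}\,d_{xy} - \tfrac{1}{2}\left(\mathrm{median\ het}_x + \mathrm{median\ het}_y\right),$$

with the medians taken over cross-group pairs and per-sample
heterozygosities respectively. Split times convert as
$t = D_A \cdot g / (2\mu)$ with defaults g = 3 years and
$\mu = 3.5\times 10^{-9}$ per site per generation. With equal effective
sizes the estimator is unbiased ($E[d_{xy}] = 2\mu(T + 2N_e)$ and
$E[\mathrm{het}] = 4N_e\mu$ cancel exactly), which the test suite confirms
at the percent level.

Uncertainty uses a chromosome-delete jackknife: recompute $D_A$ leaving
out each chromosome, then take mean(theta) +/- 3 SD(theta) with the
divisor-n variance of the delete-one estimates, without the usual
jackknife inflation factor (n-1). This follows the source procedure, and it
reproduces interval widths of a few tenths of a percent to about one
percent around multi-million-year estimates. A statistical caveat belongs
here, in the package's own words: for a smooth statistic on n exchangeable
chromosomes, SD(theta_i) equals the estimator's true standard error divided
by sqrt(n-1), so the +/- 3 SD band is about 0.65 standard errors wide and
its frequentist coverage of the truth is roughly 50% -- our simulations
measure exactly that. The band should therefore be read as a
reproducibility interval on the point estimate (how much the estimate moves
when a chromosome is dropped), not as a confidence interval;
`jackknife_bounds()` documents the formula so users can rescale if they
want nominal coverage.

## Windowed NJ consensus trees

Pairwise dosage-difference distances (Manhattan on dosages, so one fixed
difference between homozygotes counts 2) are accumulated in 100 kb
coordinate windows -- a deliberate contrast with the SNP-count windows of
the fdM scan; each convention is used where its consumer expects it. The
genome-wide tree sums the window matrices and applies canonical
neighbour-joining, implemented in the package with a deterministic
tie-break (lowest row, then column, index in the Q matrix) so star-like
configurations resolve reproducibly; ties produce zero-length internal
branches. NJ is exact on additive matrices, and the suite checks both that
exactness and topological agreement with an independent implementation
(`ape::nj`). Node support is a block bootstrap: windows are resampled with
replacement, the summed-matrix tree is rebuilt, and each internal edge of
the consensus is scored by the fraction of replicates containing the same
leaf bipartition (unrooted splits, evaluated after rooting on the
outgroup). Note that because each replicate re-sums the resampled windows,
a split backed by 60% of windows gets support near the probability that a
resample keeps it in the majority -- well above 0.6; the tests encode this
binomial expectation explicitly.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It simulates a
structured coalescent on (((P1,P2),P3),O) with an optional admixture pulse
P3 -> P2, implemented in C++ with all randomness drawn from R's RNG (one
seed reproduces a dataset byte for byte). Two modes cover the two kinds of
statistic:

* **Unlinked site patterns** -- each site gets an independent genealogy.
  "Conditioned" sampling places exactly one mutation per genealogy,
  branch-length weighted (a segregating-sites sampler, the natural input
  for ABBA-BABA tests); "rate" sampling places Poisson mutation counts at
  rate mu so that per-accessible-site quantities (dxy, heterozygosity) have
  their model expectations, with the accessible length reported alongside.
* **Linked tracts** -- recipient haplotypes are mosaics of donor tracts
  (stationary alternating process, exponential tract lengths, occupancy f),
  SNPs are placed at a configurable density, and each SNP's genealogy is
  drawn conditional on the local ancestry: donor-tract lineages are held in
  a separate ancestry deme until the pulse time (they cannot coalesce with
  non-introgressed recipient lineages more recently than the pulse) and
  then join the donor population. Lineages whose descendants mix ancestries
  before the pulse remain in place; with pulse ages well under 2Ne this is
  a rare, documented approximation.

Default parameters are chosen once, on biological grounds: diploid Ne of
1.43e5 gives per-site heterozygosity near 0.002 (haplochromine levels with
mu = 3.5e-9); sister and donor splits at 1.53 and 1.72 million generations
mirror the relevant lineage depths at a 3-year generation time; 22
chromosomes match the jackknife design; the default pulse age of 1e5
generations corresponds to admixture around the radiation's onset and
keeps the f4-ratio in its near-unbiased regime (see above). The generator
emulates ILS, drift, admixture and linkage structure; it does not emulate
recombination-map heterogeneity, selection, or sequencing error beyond
planted annotation failures -- so passing tests demonstrate statistical
correctness of the methods, not robustness to artefacts real data may
carry.

`plant_filter_failures()` gives every site a deterministic passing
annotation baseline and then makes chosen sites violate exactly one named
rule each, recording them in the truth object; this is how the filter rules
are tested against known ground truth.

## Problem sizes and numerical choices

The shipped tests run at desk scale, chosen to finish in minutes on one
CPU while leaving each assertion statistically meaningful: 2e4 segregating
sites per replicate and 200 replicates for D-test calibration; 1e5 sites
for f4-ratio recovery; 22 chromosomes of 2.5e5 accessible sites and 50
replicates for split-time recovery; 10,000 permutations for the adjacency
null at the published scan size. Degenerate inputs are handled explicitly:
zero ABBA+BABA flags D undefined; an all-equal block series flags an
infinite Z (p = 0); zero fdM window denominators yield NA windows that are
excluded from thresholds; zero f4 denominators and zero divergence-ratio
denominators warn and return NA; NJ requires three taxa and retains
negative branch lengths rather than clamping them.

## Known limitations

Beyond the jackknife-coverage caveat above: the filters trust caller
annotations; the f4-ratio inherits its attenuation with pulse age and with
P1/P2-to-P3 distance, so it bounds gene flow from below; fdM window
thresholds are scan-relative and not comparable across scans with very
different window counts; and split-time absolute values inherit any error
in mu and generation time, which are treated as known constants.
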
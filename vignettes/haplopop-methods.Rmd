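---
title: "Methods: haploid SSR population genetics with haplopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haploid SSR population genetics with haplopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`haplopop` analyses haploid multilocus microsatellite (SSR) genotypes —
typical of fungal, bacterial, or gametophyte samples — organized in a
three-level hierarchy: individuals within populations within regions, with
optional population coordinates and per-individual mating-type calls. The
motivating setting is a heterothallic lichen-forming fungus sampled across
a mainland/island system, where the questions are: how diverse are
populations, is reproduction sexual (no clones, no multilocus linkage), how
is variance partitioned across the hierarchy, are there discrete genetic
clusters, and is there spatial signal (isolation by distance, spatially
restricted alleles) despite weak overall differentiation?

The canonical input is an N x L integer matrix of fragment lengths
(`NA` = missing) plus a sites table and a mating-type table
(`read_genotypes()`, `read_sites()`, `read_mat()`). All statistics treat
missing data by per-locus deletion: a call contributes only to the loci at
which it was scored. The one exception is the clustering stage, which
imputes a missing call with the allele's mean frequency over all
individuals — an imputation that is deliberately uninformative about group
membership, so it cannot create spurious between-group structure.

# Statistics

## Diversity and rarefaction

Per population and locus, Nei's unbiased haploid diversity is
$uh = \frac{n}{n-1}\left(1 - \sum_a p_a^2\right)$ on the $n$ non-missing
calls; population summaries are means over loci with the standard error
taken as the sd across loci divided by $\sqrt{L}$, matching the
"mean (s.e.)" presentation conventional in population tables. Cells with
$n < 2$ are undefined and excluded with a warning.

Allelic richness is standardized by rarefaction to a common number of gene
copies $g$: with $N_{ja}$ copies of allele $a$ among the $N_j$ scored
copies of stratum $j$,
$$Q_{ja}(g) = 1 - \binom{N_j - N_{ja}}{g} \Big/ \binom{N_j}{g}, \qquad
  \alpha_g = \sum_a Q_{ja}(g),$$
and private allelic richness multiplies each $Q_{ja}$ by the probability
that no other stratum shows the allele in its own $g$-subsample:
$\pi_g = \sum_a Q_{ja} \prod_{k \ne j} (1 - Q_{ka})$. Binomial ratios are
computed through `lchoose` (log-gamma), never factorials, so $N_j$ in the
hundreds is unproblematic. Strata with $N_j < g$ at a locus are excluded
from that locus, both as focal and as comparison strata. The default $g$
is the largest value available everywhere (the minimum over strata and
loci of $N_j$); at the reference sampling design the population-level
analyses use $g = 8$ (the smallest population) and the regional analyses
$g = 63$. Note that 63 is below the smaller region's nominal 65 copies:
with ~3% missing calls the smallest per-locus regional count falls to
about 63, and using the reference-design defaults keeps results comparable
with published tables.

## Multilocus linkage

Clonality and linkage leave the same footprint: alleles at different loci
co-segregate. For every pair of individuals, $d_\ell \in \{0,1\}$ flags a
mismatch at locus $\ell$ (pairs unscored at a locus drop out of that
locus) and $D = \sum_\ell d_\ell$. With $V_O = \mathrm{var}(D)$ over pairs
and $V_E = \sum_\ell \mathrm{var}(d_\ell)$,
$$I_A = V_O/V_E - 1, \qquad
  \bar r_d = \frac{V_O - V_E}{2\sum_{\ell<m}\sqrt{\mathrm{var}_\ell\,
  \mathrm{var}_m}}.$$
$\bar r_d$ is bounded by 1 (attained when all loci induce the same
partition) and does not grow with the number of loci. Sample variances
(denominator $n_{pairs}-1$) are used consistently; the choice cancels in
the $\bar r_d = 1$ identity and is irrelevant to the permutation test,
which independently shuffles each locus column within the population
(missingness travels with the allele) and uses the add-one estimate
$p = (\#\{\bar r_d^{perm} \ge \bar r_d\} + 1)/(B + 1)$, $B = 999$ by
default. Multilocus genotypes are matched exactly; a call differing only
by missingness is a different MLG (missing is not a wildcard), which is
conservative for clone detection.

## AMOVA and pairwise FST

The hierarchical analysis of molecular variance uses the haploid mismatch
distance (number of differing loci; an infinite-allele convention — a
stepwise, squared-length metric would answer a different question) as a
weighted average over loci: each locus contributes sums of squares and
variance components computed from the individuals scored at it, and the
components are summed across loci before forming
$\Phi_{CT} = \sigma_a^2/\sigma^2$,
$\Phi_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)$,
$\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma^2$. Variance components come
from the expected mean squares of the unbalanced three-level design (the
$n$, $n'$, $n''$ coefficients); negative estimates are reported raw, not
truncated, so percent-of-total columns remain honest. Reported degrees of
freedom follow the full design (regions − 1, populations − regions,
N − populations). Permutation schemes are the standard ones: individuals
across everything for $\Phi_{ST}$, individuals among populations within
regions for $\Phi_{SC}$, and whole populations among regions for
$\Phi_{CT}$ — the last is granular when regions hold few populations
(with 11 populations split 3/8 there are only 165 distinct relabelings),
so its test is conservative by construction. Pairwise population FST is
the same machinery restricted to two populations, permuting individuals
between them. The default 20,000 permutations match published practice;
tests in this package run reduced counts (29–999) to keep suites fast,
which only coarsens p-value granularity.

## Cluster discovery and DAPC

Genotypes are one-hot encoded (individuals x alleles, mean-frequency
imputation), centered but not scaled (allele indicators share a scale),
and decomposed by PCA. K-means (50 restarts, seeded) runs for
$K = 1, \dots, k_{max}$, scored by
$$BIC(K) = n\,\ln(WSS_K/n) + K \ln n,$$
with ties broken toward smaller K. Two numerical points matter. First, the
k-means step sees the *full-rank* PC scores by default. The BIC penalty is
calibrated against the complete within-cluster scatter: if only a few
leading components are retained, splitting even unstructured data removes
a large fraction of the retained variance (the top empirical eigendirection
of a small cluster is inflated), and the argmin drifts to $k_{max}$.
Retaining all components is also how the established DAPC workflow runs
its cluster-discovery step. Second, an exactly separable configuration
drives $WSS$ to round-off zero; BIC uses a relative floor
($10^{-12}$ of total scatter) so all zero-scatter K tie and the smallest
wins. The discriminant step then reduces dimension: the smallest number of
PCs explaining 90% of variance, capped at N/3, guards the posterior
memberships against overfitting. Linear discriminants solve
$W^{-1}B\,v = \lambda v$ with a ridge of $10^{-8} \times$ the mean
within-class variance on $W$, so perfectly separated clusters (zero
within-class scatter along some direction) remain analyzable; axes are
scaled to unit within-class variance and memberships are Gaussian
posteriors with identity covariance in discriminant space.

## Spatial structure

Population-level isolation by distance correlates Edwards' chord distance
$$D_E = \sqrt{1 - \tfrac{1}{L}\sum_\ell \sum_a
  \sqrt{p_{1\ell a}\,p_{2\ell a}}}$$
with great-circle distance (haversine, mean Earth radius 6371.0088 km) via
a Mantel test (`vegan::mantel`, one-sided for positive association).
Geographic distance is great-circle rather than planar because the
reference design spans ~3,000 km; a planar treatment would distort the
longest island–mainland distances by tens of km. The 2-D kernel density of
(geographic, genetic) distance pairs (`MASS::kde2d`, normal-reference
bandwidths with a floor for degenerate axes) distinguishes a continuous
cline from discrete clouds of differentiation.

The spatial analysis of shared alleles (SAShA) compares the distances
between pairs of individuals sharing an allele (one contribution per
shared allele, so a pair sharing alleles at three loci contributes three
distances) with the panmictic expectation — all pairs scored at the locus,
aggregated over loci. Because all individuals of a sampling site share its
coordinates, pair sums reduce to quadratic forms in per-site carrier
counts, which makes the 1,000-fold permutation null (alleles reshuffled
among scored individuals within each locus) cheap at any scale. The
one-sided p tests observed < expected (shared alleles geographically
under-dispersed, i.e. restricted).

Geographically restricted alleles (GRA) are detected per allele: carriers'
centroid in a planar azimuthal-equidistant projection about the data
centroid (km) is compared with a null of `n_boot` centroids from drawing
the same number of individuals without replacement from all individuals
scored at the locus; an allele is restricted if its observed centroid
falls outside the 2.5–97.5 percentile interval on at least one axis. The
axis rule's nominal false-positive rate lies between 5% and
$1-0.95^2 \approx 9.8\%$ per allele depending on axis correlation; no
multiple-testing correction is applied, mirroring common usage, and the
restricted subset is re-run through SAShA (its expectation then drawn from
the subset's loci only). An allele carried by every scored individual has
a degenerate null and is never flagged. Projection about the data centroid
makes flags invariant to rigid translation of all coordinates.

## Mating types

Idiomorph ratios are tested against 1:1 with the textbook goodness-of-fit
statistic $\chi^2 = (n_1-n_2)^2/(n_1+n_2)$ (df = 1, no continuity
correction) and, alongside, the exact two-sided binomial p — preferable
whenever $n_1+n_2$ is small. The two p-values converge slowly
($O(1/\sqrt{n})$): they differ by ~0.06 at n around 50 and agree to 0.02
only for n in the thousands, which is why both are reported.
`heterothallism_check()` lists BOTH calls (violations of one-idiomorph-
per-haploid) and NONE calls (amplification failures) and the success
fraction.

# The synthetic-data generator

`simulate_ssr()` exists so that every stage can be verified end-to-end
with known truth. It is a frequency-level hierarchical model, not a
coalescent: the analyses only ever see frequencies and genotypes, and the
Balding–Nichols compound Dirichlet gives direct control of
differentiation at each level. Per locus, an ancestral Dirichlet(1)
frequency vector over a 16–46 allele inventory is perturbed into regional
pools (`F_region`) and population pools (`F_pop`), where the F parameter
is approximately the FST contributed at that level. Three optional
mechanisms then act on population pools, in this order: distance-decay
mixing toward neighboring populations (strength `ibd_decay`, weights
$e^{-d/500\,\mathrm{km}}$) creating isolation by distance; founder
truncation to the `founder_k` most frequent alleles with renormalization
(founders carry the common alleles; the rare tail is lost — this couples a
strong allelic-richness deficit with near-zero pairwise FST, exactly the
island footprint of interest); and directed migration admixture from
regional pools. Individuals are then drawn i.i.d. from their population
pool, and corruption is applied in the fixed order clone → linkage →
missingness (changing this order changes the nulls): clones copy a
previous individual's full multilocus genotype, linkage copies the
frequency-rank of the previous locus with probability `linkage_rho`, and
calls go missing independently. Mating types are Bernoulli draws with an
optional amplification-failure rate. A single seed drives one generator
stream; identical configurations are byte-identical on disk.

`island_mainland_config()` freezes the reference design: 3 island + 8
mainland populations (sizes 25, 20, 20 | 20, 8, 21, 17, 29, 25, 14, 21;
total 220, mean 20), 8 loci, 3% missing calls, balanced mating types with
7% amplification failure, founder_k = 10 on the islands, mainland→island
migration 0.05, `F_region = F_pop = 0.01`, `ibd_decay = 0.6`. The F and
founder parameters were chosen so the generated data sit at the
differentiation magnitudes published for the motivating system — all
pairwise FST below 0.05, a regional rarefied-richness gap of roughly
11 vs 19 alleles at g = 63 — rather than at the larger values an
unconstrained island model would produce. Coordinates are synthetic
approximations of the named localities spanning ~3,000 km.

What the generator does *not* emulate: stepwise mutation (allele
identities are exchangeable; statistics here never use allele size),
overlapping generations, genuine coalescent genealogies, or
per-individual coordinates (all individuals of a population share its
site). Passing tests therefore demonstrate correctness of the statistical
machinery and qualitative behavior under controlled structure — not that
real data will show any particular effect size. One known consequence of
the design scale: with 11 populations a Mantel test has modest power, so
the generated isolation-by-distance signal yields r in the 0.1–0.5 range
with p < 0.05 only in a minority of seeds, straddling published values.

# Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; `run_all()` derives a
per-stage substream from the global seed and the stage name, so stage
results do not depend on execution order and identical inputs give a
byte-identical `report.json`. The test suite and the acceptance script
run the full reference-scale pipeline with 999 permutations for the
linkage, AMOVA, pairwise-FST and Mantel tests, 1,000 SAShA permutations
and 1,000 bootstrap draws per allele (a few minutes on one CPU); the
AMOVA default outside tests remains 20,000. Calibration properties
(permutation-test rejection rates under simulated nulls) use 200
replicates at 99 permutations each, sized so the binomial uncertainty of
the rejection rate stays inside the asserted bands.

# Known limitations

- The among-region permutation test is inherently granular with few
  populations per region; its p-values are conservative.
- Rarefaction assumes the scored calls are a random sample of the
  stratum; systematic missingness (e.g., allele-size dropout) would bias
  both $\alpha_g$ and $uh$.
- The GRA axis rule inherits the arbitrariness of per-axis CIs; a joint
  elliptical rule would have a single nominal level but is not what the
  motivating literature used.
- BIC-based K selection is asymptotic; at small n (clusters of a few
  dozen in high dimension) no WSS-based criterion cleanly separates
  K = truth from K + 1, and the package's defaults favor parsimony.
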
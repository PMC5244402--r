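# haplopop

Population genetics of haploid multilocus microsatellite (SSR) data in R.

`haplopop` targets haploid organisms — lichen-forming and other fungi,
bacteria, bryophyte gametophytes — genotyped at a handful of hypervariable
SSR loci across a hierarchical sampling design (individuals in populations
in regions), optionally with population coordinates and fungal mating-type
(MAT idiomorph) calls. It answers the standard questions of such surveys
in one coherent, seeded pipeline:

- **Diversity**: Nei's unbiased haploid diversity
  `uh = n/(n-1) (1 - Σ p²)`; rarefaction-standardized allelic richness
  `α_g = Σ_a [1 - C(N_j - N_ja, g)/C(N_j, g)]` and private allelic
  richness `π_g = Σ_a Q_ja Π_{k≠j}(1 - Q_ka)` at a common sample size g,
  per population and per region.
- **Reproductive mode**: multilocus genotype (MLG) accounting and the
  unbiased index of association `r̄_d = (V_O - V_E) / (2 Σ_{l<m} √(v_l v_m))`
  with a within-population column-permutation test; MAT idiomorph 1:1
  tests (χ² and exact binomial) and heterothallism consistency checks.
- **Differentiation**: hierarchical AMOVA on haploid mismatch distances as
  a weighted average over loci, with Φ_CT / Φ_SC / Φ_ST and the standard
  stratified permutation schemes; pairwise population F_ST matrices.
- **Structure**: DAPC — k-means cluster discovery on principal components
  with BIC model selection, then ridge-regularized linear discriminants
  and posterior membership probabilities.
- **Space**: Mantel isolation-by-distance on Edwards' chord distances,
  2-D kernel density of distance pairs, spatial analysis of shared
  alleles (SAShA) against the panmictic expectation, and geographically
  restricted alleles (GRA) by allele-centroid bootstrap.
- **Synthetic data**: a hierarchical Balding–Nichols simulator
  (`simulate_ssr()`) with founder truncation, directed migration,
  distance-decay mixing, clonality, linkage, and missingness — with a
  full latent-truth record so every stage is verifiable end-to-end.

## Worked example

Simulate a mainland/island survey at the reference design (11 populations
in 2 regions, 220 haploids, 8 loci) and run the full pipeline:

```r
library(haplopop)

sim <- simulate_ssr(island_mainland_config(seed = 1))
sim$data
#> Haploid multilocus genotype dataset
#>   220 individuals, 8 loci, 11 populations, 2 regions
#>   missing calls: 2.8%

res <- run_all(sim$data, mat = sim$mat, out_dir = "run1", seed = 1,
               g_pop = 8, g_region = 63,
               n_perm_amova = 999, n_perm_fst = 999,
               n_perm_linkage = 999, n_perm_mantel = 999,
               n_perm_sasha = 1000, n_boot_gra = 1000)

res$amova
#> Hierarchical AMOVA (haploid mismatch distance, summed over loci)
#>                           stratum  df      SS   sigma2      pct
#>                     among_regions   1   9.042 0.059540  1.60092
#>  among_populations_within_regions   9  33.406 0.002766  0.07437
#>                within_populations 209 741.463 3.656803 98.32471
#>                             total 219 783.912 3.719109       NA
#> phi_ct = 0.0160 (p = 0.007); phi_sc = 0.0008 (p = 0.420); phi_st = 0.0168 (p = 0.001)
```

The report collects every headline number. On this run: the island region
has rarefied allelic richness 11.1 vs 19.1 on the mainland (private
richness 1.0 vs 10.3) at g = 63 — the founder-effect signature; all 55
pairwise F_ST values are below 0.05 (max 0.032); no repeated multilocus
genotypes occur and mean rBarD is ~0.08 with only sporadic significance —
a sexually recombining system; the Mantel test gives r = 0.29; shared
alleles are significantly closer in space than the panmictic expectation
(1,033 vs 1,074 km, p = 0.002); and 42 of 186 observed alleles are flagged
geographically restricted. Stage CSVs (`diversity.csv`, `linkage.csv`,
`amova.csv`, `fst_matrix.csv`, `dapc_*.csv`, `ibd.csv`,
`sasha_summary.csv`, `gra.csv`) and a versioned `report.json` land in
`run1/`.

Individual stages are plain functions on the same objects —
`allele_frequencies()`, `diversity_table()`, `rbar_d()`, `amova()`,
`pairwise_fst()`, `dapc()`, `mantel_ibd()`, `sasha()`, `detect_gra()` —
see the methods vignette (`vignettes/haplopop-methods.Rmd`) for the
formulas, parameter meanings, and design rationale.

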
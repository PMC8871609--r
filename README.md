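# colpopgen

Population-genetic selection signatures at a collagen locus.

Type I collagen's alpha-1 chain (COL1A1) is under strong purifying selection
in its Gly-X-Y triple helix — glycine replacements there cause osteogenesis
imperfecta — yet its introns carry signals of more recent, population-level
evolution: frequency differentiation between African and non-African
ancestries, a conserved 5' intron block, and, in chimpanzees, two deep
haplogroups held together by unusually strong linkage disequilibrium.
`colpopgen` packages the statistical machinery needed to dissect such a
locus, for population geneticists working from phased VCFs, per-base
conservation tracks and clinical mutation catalogs:

- **Diversity**: Watterson's θ_W = S / (a_{n−1} L) with
  a_{n−1} = Σ_{i=1}^{n−1} 1/i; site-frequency-spectrum rare fractions.
- **Differentiation**: Hudson's per-SNP F_ST = 1 − H_w/H_b from unbiased
  within- and between-population heterozygosities, with an outlier scan whose
  null pools the allele copies and re-splits them into the original sample
  sizes.
- **Linkage disequilibrium**: pairwise r² = D²/(p_A(1−p_A) p_B(1−p_B)) with a
  strict MAF ≥ 5 % retention filter, plus distance-binned decay profiles.
- **Conservation contrasts**: length-weighted randomization test comparing
  mean phyloP-style scores between intron blocks, and rank-sum permutation
  tests for any two score or frequency distributions.
- **Haplogroup structure and age**: two-medoid haplogroup partitioning on
  Hamming distance, reciprocal fixed differences, a binomial/permutation test
  for their spatial clustering, neighbor-joining trees with outgroup-rooted
  monophyly checks, and the Thomson moment estimator
  t = Σᵢ xᵢ / (n μ), with μ calibrated from interspecies divergence as
  substitutions / 2T.
- **Protein-level contrasts**: codon-exact variant classification on the gene
  model, severity × domain and severity × glycine contingency tables with
  Fisher exact and Pearson χ² tests, and reading-frame analysis of exonic
  duplications (McDonald–Kreitman 2×2 included).

A synthetic-data module generates all inputs with the statistical structure
the analyses assume — a 51-exon/50-intron gene model whose first 21 introns
total 6700 bp and last 29 total 8900 bp, stem-and-star two-haplogroup
genealogies with exact truth bookkeeping, Balding–Nichols population pairs,
block-structured conservation tracks, and severity-stratified mutation
catalogs — so the whole battery runs and is tested without any downloads.

## Worked example

Forty phased chimpanzee-like haplotypes carrying two deep haplogroups,
partitioned, counted and dated:

```r
library(colpopgen)

sim <- simulate_two_haplogroup_locus(n_per_group = 20, locus_length = 15600,
                                     mu = 1e-9, t_split = 2.8e6,
                                     t_within = 2.8e5, seed = 42)
sim$haplotypes
#> Haplotype matrix: 40 haplotypes x 274 sites
#>   groups: g1=20 g2=20
#>   polarized sites: 274 / 274

part <- partition_core_haplogroups(sim$haplotypes)
fixed_differences(sim$haplotypes, part$assignment)$count
#> [1] 82

mu <- estimate_mu(156, 5e6, time_halfwidth = 1e6)   # subs / 2T
mu$mu
#> [1] 1.56e-05

x <- mutations_from_mrca(sim$haplotypes, sim$outgroup_alleles)$x
thomson_tmrca(x, mu$mu)
#> Thomson TMRCA: 2.94e+06 +/- 6.9e+04 years (n = 40, mu = 1.56e-05 /locus/yr)
```

The 40-haplotype sample recovers the simulated 2.8 My split within sampling
error. Are fixed differences clustered in the conserved 5' intron block? For
38 of 45 mutations falling in a block holding 6700 of 15600 intron bases,
the exact binomial tail is

```r
exact_spatial_tail(45, 6700 / 15600, 38)
#> [1] 1.159405e-08
```

i.e. far beyond any plausible uniform placement.

`run_full_analysis(out_dir, seed = 1)` chains all nine stages (annotation,
frequencies/SFS, conservation contrast, F_ST scan, LD, haplogroup partition,
fixed differences + spatial test, NJ tree + monophyly, TMRCA) on the default
synthetic profile and writes one TSV per stage plus `summary.json`.

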
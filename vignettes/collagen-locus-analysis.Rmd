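---
title: "Methods: selection signatures at a collagen locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection signatures at a collagen locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colpopgen)
```

`colpopgen` analyses a single fibrillar-collagen locus — COL1A1-like in its
exon/intron architecture and protein-domain structure — for signatures of
selection within and between populations and species. This vignette is the
package's own account of the models it implements, the choices made where
the methodology was genuinely open, and what the synthetic test battery does
and does not demonstrate.

## The locus model

All genomic coordinates are 0-based half-open internally; conversion to and
from 1-based coordinates happens only at the VCF boundary (positions) and
the protein boundary (residues). A `gene_model` stores sorted, disjoint
exons; introns are always derived from them, never stored, so the two can
never drift apart. The deterministic fixture built by
`make_colgene_fixture()` has 51 short exons (45–108 bp, all multiples of
9 bp, echoing the ancestral 54 bp collagen exon unit) and 50 introns whose
5' block (introns 1–21, with a long first intron) totals exactly 6700 bp
and whose 3' block (introns 22–50) totals 8900 bp. The protein is
partitioned into N-propeptide, triple-helix and C-propeptide residue
ranges. Every spatial test in the package keys off this backbone.

Multiallelic sites and indels are excluded at VCF parsing rather than split:
all downstream statistics are biallelic, and splitting would silently change
frequency denominators. Missing genotypes are dropped from per-site
denominators; nothing is imputed.

## Diversity and differentiation

Watterson's estimator is computed per site as θ_W = S/(a₍n−1₎L). Hudson's
per-SNP F_ST is 1 − H_w/H_b with the unbiased within-population
heterozygosity 2p(1−p)·n/(n−1) (n allele copies) and
H_b = p₁(1−p₂) + p₂(1−p₁). Sites monomorphic in the pooled pair are
undefined, not zero, and are excluded from summaries; negative per-SNP
values are retained, since clamping would bias both the mean and the
permutation null.

Two multi-SNP combinations are exposed. The default, the arithmetic mean of
per-SNP values, matches the convention of averaging the estimator across
SNPs between population pairs. It is, however, a mean of ratios: under a
Balding–Nichols generating model its expectation sits below the generating
parameter by an amount that does not vanish with more SNPs (we measure
≈ 0.21 at truth 0.30 with 100 diploids per population). The ratio of sums
1 − ΣH_w/ΣH_b is the consistent combination, and it is the one the
calibration tests target: at truths 0.05/0.15/0.30 it recovers the
parameter within ±0.02 on 2000 SNPs. Users comparing against a known truth
should use `combine = "ratio_of_averages"`.

The outlier scan builds each SNP's null by pooling all called allele copies
and re-splitting them into the original sample sizes without replacement.
The pop-1 alternate-allele count under that scheme is exactly
hypergeometric, so the scan draws from `rhyper` rather than literally
shuffling a vector of copies — identical in law and much faster. Because
the resampled statistic lives on a discrete support, the conservative
add-one p-value (resampled ties count as extreme) is valid but
super-uniform. A `tie_break = "random"` variant places the observed value
uniformly within its tie group, which makes the null p-value distribution
exactly uniform on the add-one grid — that is the variant used when testing
calibration, while the conservative convention remains the reporting
default. SNPs above F_ST = 0.30 are flagged as candidate outliers by
default, the conventional threshold for strong outliers between continental
groups; no multiple-testing correction is applied unless requested
(`adjust = "BH"`).

## Linkage disequilibrium

r² is the squared correlation of allele indicators over haplotypes complete
at both sites, equivalently D²/(p_A(1−p_A)p_B(1−p_B)). The MAF filter is
strict — a site is retained iff MAF ≥ cutoff (default 5 %) — and is applied
before any pair is formed. Decay profiles average r² between anchor SNPs
and all other retained SNPs per distance bin; empty bins are reported as
missing with a zero pair count, never as zero LD.

## Permutation machinery

Every randomization test returns the same container: observed statistic,
permutation count, count as extreme, seed, and an add-one p-value
(b+1)/(m+1). The add-one convention keeps p-values strictly positive, which
is what "<" bounds on permutation p-values require.

* `permutation_location_test` permutes group labels wholesale; the default
  statistic is the rank-sum of group A (mean difference optional). Two-sided
  p-values double the smaller tail and cap at 1; under a continuous null
  this doubling is exactly uniform on its grid, which the 500-seed
  uniformity test verifies.
* `intron_block_randomization` compares length-weighted mean scores of
  introns 1..k against the rest, permuting intron identities between the two
  groups with sizes preserved. Weighting by intron length is how "account
  for their lengths" is implemented; a site-level permutation mode is also
  provided since the label-permutation choice is not the only defensible
  reading. The test is one-sided with a fixed default alternative
  ("greater": the 5' block more conserved, the direction of scientific
  interest). Fixing the alternative, rather than testing the observed
  direction post hoc, is what makes the null p-value distribution uniform —
  a post-hoc direction yields min-tail p-values that are super-uniform by
  construction.
* `spatial_clustering_test` drops n mutations uniformly over the
  concatenated intron bases; the count landing in the target introns is then
  Binomial(n, fraction), so `exact_spatial_tail` provides the closed-form
  upper tail the Monte-Carlo mode is checked against. For 38 of 45
  mutations in the 6700/15600 block the exact tail is 1.16e-8; Monte-Carlo
  mode at any feasible permutation count simply bottoms out at 1/(m+1).

## Haplogroup structure and age

Haplogroups are recovered by 2-medoid clustering on Hamming distance,
seeded with the maximally distant pair and iterated to convergence, with
deterministic lowest-index tie-breaking — at deep splits (within-group
depth 10 % of the split time) this recovers the simulated truth in every
seed tested. Fixed differences require reciprocal fixation: every called
allele in one group different from every called allele in the other.

Neighbor joining is implemented natively (Saitou–Nei Q-matrix, lexicographic
tie-breaking, standard two-point branch lengths, final three-way join) and
returns an `ape` tree; on additive matrices it reproduces the generating
tree's topology and path lengths exactly, which is tested against a
path-length oracle on random trees up to 12 taxa and cross-checked against
an independent implementation. Negative branch-length estimates are clamped
to zero with the deficit moved to the sister branch (so pairwise path sums
are preserved at the join) and counted in an attribute. Monophyly is judged
after rooting at the designated outgroup leaf.

The haplogroup age uses the Thomson moment estimator t = Σxᵢ/(nμ). xᵢ is
the mutation count of haplotype i from the MRCA, reconstructed as the
outgroup-matching (ancestral) allele at polarizable sites; unpolarizable
sites fall back to the majority allele for the reconstructed sequence but
are flagged and excluded from the counts. The per-locus rate μ is
calibrated from interspecies divergence as substitutions/(2T): substitutions
accrue along both lineages, so dividing by 2T gives the per-lineage rate.
The alternative literal reading (×2 rather than ÷2) is exposed as
`reading = "times_two"` but not used. Calibration uncertainty (e.g. a
5 ± 1 My divergence time) propagates to a μ interval and thence to a t
interval. The reported standard error √(Σxᵢ)/(nμ) treats all mutations as
independent Poisson counts — a star-genealogy approximation that
understates the error when deep stem mutations are shared across many
tips; it should be read as a lower bound, and the simulation-based recovery
test checks the estimator's mean, not its claimed precision.

## The synthetic generators

The generators are first-class, tested code; their defaults are the study
conditions the battery runs under.

* `simulate_two_haplogroup_locus` uses a stem-and-star genealogy: two stems
  of length t_split − t_within and star tips at depth t_within, mutations as
  a Poisson process at μ per base-year placed at distinct uniform positions
  (infinite sites). This matches the assumptions of the Thomson estimator
  (no equilibrium, no recombination) and makes every truth quantity exact:
  stem mutations are precisely the between-group fixed differences
  (expectation 2μL(t_split − t_within)), and xᵢ is known per tip. The
  within-group depth defaults to 0.1·t_split, a free parameter chosen to
  keep the groups star-like without being degenerate. The default profile
  (20 haplotypes per group, 15.6 kb of intron sequence, μ = 1e-9/bp/yr — a
  human–chimpanzee-like calibration of ~1 % per-lineage divergence over
  5 My — and a 2.8 My split) reproduces the qualitative pattern of a deep
  two-haplogroup chimpanzee locus.
* `simulate_population_pair` draws per-site ancestral frequencies uniformly
  (default 0.1–0.9) and population frequencies from the Balding–Nichols
  Beta with variance parameter F, then binomial diploid genotypes; it gives
  the single interpretable truth parameter the F_ST calibration needs.
* `simulate_conservation_track` writes Normal per-base scores around block
  means over any feature partition of the locus; `simulate_dam_catalog`
  produces severity-stratified mutation records with per-category glycine
  probabilities and domain weights mirroring the clinical gradient (57 %
  glycine in the mildest category rising to 91–98 % in severe ones).

What the generators deliberately omit: recombination within the locus (so
LD decay in simulated data reflects only allele frequencies, not map
distance), demographic structure beyond the two-group split, selection
(only neutral nulls plus engineered contrasts), sequencing error and call
missingness models. Passing the battery therefore demonstrates estimator
correctness under the stated models, not robustness to the full
complexity of real resequencing data.

## Statistical calibration choices

The McDonald–Kreitman table is tested with a two-sided Fisher exact test
(p = sum of hypergeometric probabilities ≤ the observed table's), the
odds ratio reported as the plain cross-product ratio with a
Haldane–Anscombe 0.5 correction only when a zero cell forces it. Fisher's
test is conservative at small counts, so its type-I calibration is run at
moderate counts (neutral loci yielding on the order of 40–120 variants per
class), where the achievable rejection rate at α = 0.05 is ≈ 0.04–0.05;
the rate is required to sit within 0.05 ± 0.02. Pearson's χ² is reported
without continuity correction (Yates optional), with a flag when any
expected count drops below 5. The MAF exclusion used before MK testing
removes variants strictly below the cutoff, mirroring the LD filter.

Problem sizes in the test battery — 500 TMRCA replicates, 2000 SNPs per
F_ST calibration, 1000 MK replicates, 200 NJ trials, 500 seeds per
uniformity check with 199 permutations each — were chosen so each check's
Monte-Carlo error is several times smaller than the tolerance it enforces
while the whole suite stays comfortably interactive.

## Pipeline

`run_full_analysis()` chains the nine stages on the synthetic profile.
Every stage derives its own seed from the top-level seed by hashing the
stage name, so inserting a stage never perturbs the randomness of the
others; the JSON summary records package version, seed and every statistic.
The package is a library first: the exported functions, this vignette and
`scripts/acceptance.R` are its command surface.

## Known limitations

Residue arithmetic assumes the gene model is supplied in coding orientation
with fully coding exons downstream of the coding offset; UTR-containing
exon structures are handled only insofar as positions before the coding
offset report no residue. The MRCA reconstruction ignores recurrent
mutation (as does the infinite-sites simulator). The haplogroup partition
is 2-medoid by construction and will force a binary split on data without
one — the silhouette-style separation score is the guard to inspect. The
Thomson SE, as noted, is approximate and optimistic under shared stems.
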
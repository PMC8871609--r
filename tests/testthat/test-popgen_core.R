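test_that("Watterson's theta follows the harmonic-number formula", {
  expect_equal(watterson_theta(0, 10, 1000), 0)
  expect_equal(watterson_theta(5, 2, 1000), 0.005)      # a_1 = 1
  a9 <- sum(1 / 1:9)                                     # 2.828968...
  expect_equal(watterson_theta(10, 10, 1000), 10 / (a9 * 1000))
  expect_error(watterson_theta(1, 1, 1000), "at least 2")
  # linear in S, inverse in L
  expect_equal(watterson_theta(20, 10, 1000), 2 * watterson_theta(10, 10, 1000))
  expect_equal(watterson_theta(10, 10, 2000), watterson_theta(10, 10, 1000) / 2)
})

test_that("allele frequency counts dosages over called genotypes", {
  # 5 heterozygotes + 1 homozygote carrier among 20 diploids: 7/40 = 17.5%
  g <- matrix(c(rep(1, 5), 2, rep(0, 14)), ncol = 1)
  gt <- genotype_table(g, positions = 0)
  expect_equal(allele_frequency(gt, 1), 0.175)
  # all homozygous reference
  gt0 <- genotype_table(matrix(0, 10, 1), positions = 0)
  expect_equal(allele_frequency(gt0, 1), 0)
  # 3 het among 10 with 2 missing: 3 / 16
  g2 <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, NA, NA), ncol = 1)
  gt2 <- genotype_table(g2, positions = 0)
  expect_equal(allele_frequency(gt2, 1), 3 / 16)
  # all-missing site is an explicit error
  gt3 <- genotype_table(matrix(NA_integer_, 3, 1), positions = 0)
  expect_error(allele_frequency(gt3, 1), "missing")
})

test_that("SFS rare fraction uses a strict cutoff", {
  expect_equal(sfs_fraction_below(c(0.001, 0.02, 0.5), 0.01), 1 / 3)
  expect_equal(sfs_fraction_below(rep(0.01, 5), 0.01), 0)  # strict <
  expect_error(sfs_fraction_below(numeric(0), 0.01), "empty")
  set.seed(31)
  u <- runif(1000)
  se <- sqrt(0.01 * 0.99 / 1000)
  expect_lt(abs(sfs_fraction_below(u, 0.01) - 0.01), 3 * se)
})

test_that("per-SNP Hudson F_ST matches plug-in arithmetic and edge cases", {
  expect_equal(hudson_fst_snp(1, 1000, 0, 1000), 1)
  # panmixia limit
  expect_lt(abs(hudson_fst_snp(0.5, 1e6, 0.5, 1e6)), 1e-5)
  # p1 = 0.9, p2 = 0.1: 1 - 0.18/0.82
  expect_equal(hudson_fst_snp(0.9, 1e9, 0.1, 1e9), 1 - 0.18 / 0.82,
               tolerance = 1e-6)
  # both fixed for the same allele: undefined, not a crash
  expect_true(is.na(hudson_fst_snp(0, 100, 0, 100)))
  expect_true(is.na(hudson_fst_snp(1, 100, 1, 100)))
  expect_true(all(hudson_fst_snp(runif(50), 100, runif(50), 100) <= 1))
})

test_that("pairwise F_ST over identical populations is ~0 and fixed SNPs hit 1", {
  set.seed(8)
  g <- matrix(rbinom(100 * 20, 2, 0.4), nrow = 20)
  gt <- genotype_table(rbind(g, g), positions = seq(0, 990, 10),
                       population = rep(c("A", "B"), each = 20))
  res <- hudson_fst_pair(gt, "A", "B")
  expect_lte(abs(res$mean_fst), 0.03)   # -1/(n-1) small-sample artefact only
  # engineered fixed difference
  gfix <- genotype_table(matrix(rep(c(2L, 0L), each = 10), ncol = 1),
                         positions = 0,
                         population = rep(c("A", "B"), each = 10))
  expect_equal(hudson_fst_pair(gfix, "A", "B")$per_snp$fst, 1)
})

test_that("ratio-of-averages F_ST recovers the Balding-Nichols truth", {
  gt <- simulate_population_pair(2000, 100, 0.15, seed = 12)
  res <- hudson_fst_pair(gt, "popA", "popB", combine = "ratio_of_averages")
  expect_lt(abs(res$mean_fst - 0.15), 0.02)
})

test_that("r2 matches direct haplotype-count arithmetic", {
  hm <- haplotype_matrix(rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0)),
                         positions = c(0, 100))
  expect_equal(ld_r2_pair(hm, 1, 2), 1)
  hm2 <- haplotype_matrix(rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)),
                          positions = c(0, 100))
  expect_equal(ld_r2_pair(hm2, 1, 2), 0)
  # counts AB=3, Ab=1, aB=1, ab=3: D = 0.125, r2 = 0.25
  hm3 <- haplotype_matrix(rbind(matrix(rep(c(1, 1), 3), ncol = 2, byrow = TRUE),
                                c(1, 0), c(0, 1),
                                matrix(rep(c(0, 0), 3), ncol = 2, byrow = TRUE)),
                          positions = c(0, 100))
  expect_equal(ld_r2_pair(hm3, 1, 2), 0.25)
  mono <- haplotype_matrix(cbind(c(1, 1, 1, 1), c(0, 1, 0, 1)),
                           positions = c(0, 100))
  expect_error(ld_r2_pair(mono, 1, 2), "monomorphic")
  # invariant to swapping allele labels at either site
  hm5 <- haplotype_matrix(cbind(1L - hm3$alleles[, 1], hm3$alleles[, 2]),
                          positions = c(0, 100))
  expect_equal(ld_r2_pair(hm5, 1, 2), 0.25)
})

test_that("r2 matrix applies the MAF filter before pairing", {
  set.seed(3)
  base <- matrix(rbinom(100 * 3, 1, 0.5), ncol = 3)
  rare <- cbind(c(1, rep(0, 99)), c(rep(0, 99), 1))   # MAF 0.01
  hm <- haplotype_matrix(cbind(base, rare),
                         positions = c(0, 10, 20, 30, 40))
  r2 <- ld_r2_matrix(hm, maf_min = 0.05)
  expect_equal(dim(r2), c(3, 3))
  expect_equal(unname(diag(r2)), rep(1, 3))
  expect_error(ld_r2_matrix(hm, maf_min = 0.6), "MAF")
  # haplotype order is irrelevant
  perm <- sample(nrow(base))
  hmp <- haplotype_matrix(cbind(base, rare)[perm, ],
                          positions = c(0, 10, 20, 30, 40))
  expect_equal(ld_r2_matrix(hmp, maf_min = 0.05), r2)
})

test_that("r2 matrix equals the pairwise kernel entrywise (with missing data)", {
  set.seed(14)
  a <- matrix(rbinom(60 * 6, 1, 0.5), ncol = 6)
  a[sample(length(a), 30)] <- NA
  keep <- colMeans(a, na.rm = TRUE)
  hm <- haplotype_matrix(a, positions = seq(0, 50, 10))
  r2 <- ld_r2_matrix(hm, maf_min = 0.05)
  idx <- attr(r2, "retained")
  for (i in seq_along(idx)) for (j in seq_along(idx)) {
    if (i == j) next
    expect_equal(r2[i, j], ld_r2_pair(hm, idx[i], idx[j]), tolerance = 1e-12)
  }
})

test_that("LD decay profile bins pairs and flags empty bins", {
  hm <- haplotype_matrix(rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 1)),
                         positions = c(0, 500))
  prof <- ld_decay_profile(hm, anchor_sites = 1, breaks = c(0, 1000, 2000))
  expect_equal(prof$mean_r2[1], ld_r2_pair(hm, 1, 2))
  expect_equal(prof$n_pairs[2], 0)
  expect_true(is.na(prof$mean_r2[2]))
  # no recombination in the stem-and-star world: the intermediate-frequency
  # haplogroup-defining sites stay in uniformly strong LD at any distance
  sim <- simulate_two_haplogroup_locus(10, 15600, 1.5e-9, 2.8e6, 1e5,
                                       seed = 21)
  r2 <- ld_r2_matrix(sim$haplotypes, maf_min = 0.2)
  expect_gt(mean(r2[upper.tri(r2)]), 0.8)
})

test_that("MK test combines counts, MAF exclusion and Fisher p", {
  res <- mk_test(10, 5, 20, 10)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)
  # zero-cell table: p equals the exhaustive hypergeometric tail sum
  res2 <- mk_test(20, 0, 50, 50)
  expect_equal(res2$p_value,
               fisher_enum_p(matrix(c(20, 50, 0, 50), 2)), tolerance = 1e-10)
  expect_true(res2$or_corrected)
  # MAF exclusion recomputes polymorphism counts before testing
  res3 <- mk_test(0, 5, 0, 10, maf_cutoff = 0.05,
                  replacement_freqs = c(0.01, 0.10, 0.20),
                  neutral_freqs = c(0.30, 0.40, 0.02, 0.01))
  expect_equal(unname(res3$table[, "polymorphism"]), c(2, 2))
  expect_error(mk_test(0, 0, 0, 0), "all-zero")
})
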
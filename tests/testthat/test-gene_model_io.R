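test_that("locate_site partitions a small model exhaustively", {
  m <- gene_model("c", "+", exon_starts = c(0, 30, 80),
                  exon_ends = c(9, 45, 95),
                  domains = list(N_terminal = c(1, 4),
                                 triple_helix = c(5, 9),
                                 C_terminal = c(10, 13)))
  feats <- vapply(0:94, function(p) locate_site(p, m)$feature, "")
  counts <- table(feats)
  expect_equal(sum(counts), 95)  # every base maps to exactly one feature
  expect_equal(unname(counts[c("exon_1", "exon_2", "exon_3")]),
               unname(exon_lengths(m)), ignore_attr = TRUE)
  expect_equal(unname(counts[c("intron_1", "intron_2")]),
               unname(intron_lengths(m)), ignore_attr = TRUE)
  # first coding base
  expect_equal(locate_site(0, m)[c("feature", "residue", "codon_pos")],
               list(feature = "exon_1", residue = 1L, codon_pos = 1L))
  # residue arithmetic spans the first intron: base 30 is coding index 10
  expect_equal(locate_site(30, m)$residue, 4L)
  expect_equal(locate_site(30, m)$codon_pos, 1L)
  expect_error(locate_site(-1, m), "outside")
  expect_error(locate_site(95, m), "outside")
})

test_that("fixture model base inside intron 21 maps there", {
  m <- make_colgene_fixture()
  pos <- m$introns[21, 1] + 5
  expect_equal(locate_site(pos, m)$feature, "intron_21")
})

test_that("gene model TSV round-trips", {
  m <- make_colgene_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_model(m, path)
  m2 <- read_gene_model(path)
  expect_equal(m2, m)
})

test_that("VCF reader agrees with an independent parser on the fixture", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path, phased = TRUE)
  ref <- ref_parse_vcf(path)
  res <- suppressMessages(read_vcf(path))
  expect_equal(res$n_skipped, 1)
  expect_equal(dim(res$genotypes$genotypes), c(2, 3))
  expect_equal(unname(t(res$genotypes$genotypes)), unname(ref$dosage))
  expect_equal(res$genotypes$positions, ref$positions)
  expect_equal(dim(res$haplotypes$alleles), c(4, 3))
  expect_equal(unname(res$haplotypes$alleles), unname(ref$hap))
})

test_that("VCF reader matches the reference parser on simulated tables", {
  sim <- simulate_two_haplogroup_locus(4, 5000, 5e-9, 2e6, seed = 11)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$haplotypes, path)
  ref <- ref_parse_vcf(path)
  res <- read_vcf(path)
  expect_equal(unname(res$haplotypes$alleles), unname(ref$hap))
  expect_equal(res$haplotypes$positions, ref$positions)
})

test_that("unphased genotypes yield no haplotype matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path, phased = FALSE)
  res <- suppressMessages(read_vcf(path))
  expect_null(res$haplotypes)
  expect_s3_class(res$genotypes, "genotype_table")
})

test_that("empty region and missing file are explicit errors", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path)
  expect_error(suppressMessages(read_vcf(path, region = c(5000, 6000))),
               "no biallelic SNP")
  expect_error(read_vcf(file.path(tempdir(), "absent.vcf")), "no such file")
})

test_that("pop_map labels populations in both containers", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(path)
  res <- suppressMessages(
    read_vcf(path, pop_map = c(s1 = "west", s2 = "east")))
  expect_equal(res$genotypes$population, c("west", "east"))
  expect_equal(res$haplotypes$group_labels, rep(c("west", "east"), each = 2))
})

test_that("bedGraph expansion, gaps and overlaps behave", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("c\t0\t2\t1.5", "c\t2\t3\t-0.4"), path)
  tr <- read_conservation_track(path)
  expect_equal(tr$scores, c(1.5, 1.5, -0.4))

  writeLines(c("c\t0\t2\t1.0", "c\t3\t4\t2.0"), path)
  tr <- read_conservation_track(path)
  expect_equal(tr$scores, c(1, 1, NA, 2))

  writeLines(c("c\t0\t2\t1.0", "c\t1\t3\t2.0"), path)
  expect_error(read_conservation_track(path), "overlapping")
})

test_that("conservation track round-trips through bedGraph", {
  m <- make_colgene_fixture()
  tr <- simulate_conservation_track(m, two_block_profile(m), sd = 0.5,
                                    seed = 3)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  tr2 <- read_conservation_track(path)
  expect_equal(tr2$scores, round(tr$scores, 10), tolerance = 1e-6)
})

test_that("DAM reader filters severities, rejects malformed rows, round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue\taa_from\taa_to\tdomain\tseverity\tsite_score",
               "10\tG\tS\ttriple_helix\t1\t2.0",
               "20\tG\tA\ttriple_helix\t5\t1.0",
               "30\tA\tV\tN_terminal\t2\t0.5",
               "40\tG\tC\tC_terminal\t3\t1.5",
               "50\tP\tL\ttriple_helix\t4\t2.5"), path)
  dam <- suppressMessages(read_dam_table(path))
  expect_equal(nrow(dam), 4)
  expect_message(read_dam_table(path), "1 record")

  writeLines(c("residue\taa_from\taa_to\tdomain\tseverity\tsite_score",
               "10\tG\tG\ttriple_helix\t1\t2.0"), path)
  expect_error(read_dam_table(path), "line 2")

  dam10 <- simulate_dam_catalog(c(`1` = 5L, `4` = 5L),
                                glycine_prob = c(`1` = 0.5, `4` = 0.9),
                                seed = 2)
  write_dam_table(dam10, path)
  back <- read_dam_table(path)
  expect_equal(back$residue, dam10$residue)
  expect_equal(back$aa_from, dam10$aa_from)
  expect_equal(back$site_score, dam10$site_score, tolerance = 1e-12)
})

test_that("outgroup polarization recodes, flags, and inverts cleanly", {
  hm <- haplotype_matrix(rbind(c(0L, 1L, 0L), c(1L, 0L, 1L)),
                         positions = c(10, 20, 30),
                         ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  # outgroup = ref everywhere: codes unchanged, all polarized
  p1 <- polarize_with_outgroup(hm, c("A", "C", "G"))
  expect_equal(p1$alleles, hm$alleles)
  expect_true(all(p1$polarized))
  # outgroup = alt at site 2: codes flipped there
  p2 <- polarize_with_outgroup(hm, c("A", "T", "G"))
  expect_equal(unname(p2$alleles[, 2]), c(0L, 1L))
  expect_true(all(p2$polarized))
  # third base: site stays unpolarized, codes untouched
  p3 <- polarize_with_outgroup(hm, c("A", "G", "G"))
  expect_false(p3$polarized[2])
  expect_equal(p3$alleles, hm$alleles)
  # flipping twice restores the original codes
  p4 <- polarize_with_outgroup(p2, c("A", "T", "G"))
  expect_equal(p4$alleles, hm$alleles)
})
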
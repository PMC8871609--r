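test_that("haplogroup partition recovers simulator truth at deep splits", {
  hits <- vapply(1:50, function(s) {
    sim <- simulate_two_haplogroup_locus(8, 15600, 1e-9, 2.8e6, 2.8e5,
                                         seed = s)
    part <- partition_core_haplogroups(sim$haplotypes)
    truth <- sim$truth$assignment
    all(part$assignment == truth) || all(part$assignment == 3L - truth)
  }, TRUE)
  expect_true(all(hits))
})

test_that("degenerate partitions error and two-haplotype inputs split", {
  same <- haplotype_matrix(matrix(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), 4),
                           positions = c(0, 10))
  hm <- haplotype_matrix(rbind(c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L)),
                         positions = c(0, 10))
  part <- partition_core_haplogroups(hm)
  expect_equal(unname(part$assignment[1]), unname(part$assignment[2]))
  expect_true(part$assignment[1] != part$assignment[3])
  ident <- haplotype_matrix(matrix(1L, 4, 2), positions = c(0, 10))
  expect_error(partition_core_haplogroups(ident), "identical")
})

test_that("fixed differences require reciprocal fixation", {
  hm <- haplotype_matrix(rbind(c(0L, 0L, 0L), c(0L, 1L, 0L),
                               c(1L, 1L, 0L), c(1L, 1L, 0L)),
                         positions = c(0, 10, 20))
  fd <- fixed_differences(hm, c(1, 1, 2, 2))
  expect_equal(fd$count, 1)
  expect_equal(fd$positions, 0)
  # identical groups share everything
  fd0 <- fixed_differences(hm, c(1, 2, 1, 2))
  expect_equal(fd0$count, 0)
  # a site uncalled in one group is excluded, with a log line
  hm2 <- haplotype_matrix(rbind(c(0L, NA), c(0L, NA), c(1L, 0L), c(1L, 1L)),
                          positions = c(0, 10))
  expect_message(fd2 <- fixed_differences(hm2, c(1, 1, 2, 2)), "excluded")
  expect_equal(fd2$count, 1)
})

test_that("p-distances match a brute-force recompute", {
  hm <- haplotype_matrix(rbind(c(0L, 0L, 0L), c(0L, 1L, 1L)),
                         positions = c(0, 10, 20))
  d <- p_distance_matrix(hm)
  expect_equal(d[1, 2], 2 / 3)
  expect_equal(unname(diag(d)), c(0, 0))
  set.seed(9)
  a <- matrix(rbinom(8 * 12, 1, 0.4), nrow = 8)
  a[sample(length(a), 10)] <- NA
  hm2 <- haplotype_matrix(a, positions = seq(0, 110, 10))
  for (metric in c("p_distance_per_variable_site", "raw_differences")) {
    d2 <- p_distance_matrix(hm2, metric)
    ref <- ref_p_distance(a, metric == "p_distance_per_variable_site")
    expect_equal(unname(d2), ref, tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(isSymmetric(unname(d2)))
  }
  empty <- haplotype_matrix(matrix(integer(0), 3, 0), positions = numeric(0))
  expect_error(p_distance_matrix(empty), "variable")
})

test_that("NJ solves the three-point and four-point cases by hand", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d3)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # additive 4-taxon matrix from ((A:1,B:2):1,(C:3,D:4))
  lbl <- c("A", "B", "C", "D")
  d4 <- matrix(0, 4, 4, dimnames = list(lbl, lbl))
  d4["A", "B"] <- 3; d4["A", "C"] <- 5; d4["A", "D"] <- 6
  d4["B", "C"] <- 6; d4["B", "D"] <- 7; d4["C", "D"] <- 7
  d4 <- d4 + t(d4)
  tr4 <- neighbor_joining(d4)
  expect_equal(stats::cophenetic(tr4)[lbl, lbl], d4)
  # AB|CD split present
  expect_equal(
    ape::dist.topo(tr4, ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))),
    0, ignore_attr = TRUE)
  # star distances collapse the internal branch to zero
  ds <- matrix(2, 4, 4, dimnames = list(lbl, lbl)); diag(ds) <- 0
  trs <- neighbor_joining(ds)
  internal <- trs$edge.length[trs$edge[, 2] > 4]
  expect_true(all(abs(internal) < 1e-12))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ reproduces random additive trees exactly", {
  set.seed(17)
  for (rep in 1:25) {
    case <- random_additive_case(sample(4:12, 1))
    tr <- neighbor_joining(case$D)
    expect_equal(ape::dist.topo(tr, case$tree), 0, ignore_attr = TRUE)
    expect_equal(stats::cophenetic(tr)[rownames(case$D), colnames(case$D)],
                 case$D, tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation off additivity", {
  set.seed(23)
  case <- random_additive_case(8)
  D <- case$D + matrix(runif(64, 0, 0.02), 8)  # mild symmetric noise
  D <- (D + t(D)) / 2; diag(D) <- 0
  mine <- neighbor_joining(D)
  ref <- ape::nj(D)
  expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
})

test_that("newick writing round-trips topology and branch lengths", {
  set.seed(29)
  case <- random_additive_case(9)
  tr <- neighbor_joining(case$D)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
  expect_equal(stats::cophenetic(back)[tr$tip.label, tr$tip.label],
               stats::cophenetic(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-9)
})

test_that("monophyly is judged relative to the outgroup root", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_true(is_monophyletic(tr, c("A", "B"), "C"))
  expect_true(is_monophyletic(tr, "A", "C"))
  expect_error(is_monophyletic(tr, c("A", "C"), "C"), "outgroup")
  expect_error(is_monophyletic(tr, "Z", "C"), "unknown")
  tr2 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  expect_false(is_monophyletic(tr2, c("A", "C"), "D"))
})

test_that("simulated haplogroups come out monophyletic against the outgroup", {
  ok <- vapply(1:20, function(s) {
    sim <- simulate_two_haplogroup_locus(6, 15600, 1e-9, 2.8e6, 2.8e5,
                                         seed = 100 + s)
    hm <- sim$haplotypes
    hm_og <- haplotype_matrix(rbind(hm$alleles, rep(0L, ncol(hm$alleles))),
                              hm$positions,
                              sample_ids = c(hm$sample_ids, "outgroup"))
    tr <- neighbor_joining(p_distance_matrix(hm_og))
    g1 <- hm$sample_ids[sim$truth$assignment == 1L]
    g2 <- hm$sample_ids[sim$truth$assignment == 2L]
    is_monophyletic(tr, g1, "outgroup") && is_monophyletic(tr, g2, "outgroup")
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("mutation-rate calibration handles both readings and uncertainty", {
  res <- estimate_mu(100, 5e6)
  expect_equal(res$mu, 1e-5)
  expect_equal(estimate_mu(0, 5e6)$mu, 0)
  res2 <- estimate_mu(100, 5e6, time_halfwidth = 1e6)
  expect_equal(res2$mu_interval, c(100 / 1.2e7, 100 / 8e6))
  expect_equal(estimate_mu(100, 5e6, reading = "times_two")$mu, 4e-5)
  expect_error(estimate_mu(100, 0), "positive")
})

test_that("mutation counts from the MRCA equal simulator truth", {
  sim <- simulate_two_haplogroup_locus(10, 15600, 1e-9, 2.8e6, 2.8e5,
                                       seed = 6)
  xm <- mutations_from_mrca(sim$haplotypes, sim$outgroup_alleles)
  expect_equal(unname(xm$x), unname(sim$truth$x))
  expect_equal(xm$n_flagged, 0)
  # an unpolarizable site is flagged and excluded from the counts
  og <- sim$outgroup_alleles
  bases <- c("A", "C", "G", "T")
  og[1] <- setdiff(bases, c(sim$haplotypes$ref[1], sim$haplotypes$alt[1]))[1]
  xm2 <- mutations_from_mrca(sim$haplotypes, og)
  expect_equal(xm2$n_flagged, 1)
  expect_equal(unname(xm2$x),
               unname(sim$truth$x - sim$haplotypes$alleles[, 1]))
})

test_that("Thomson estimator follows the moment formula and its scalings", {
  expect_equal(thomson_tmrca(c(0, 0, 0), 1e-4)$t, 0)
  est <- thomson_tmrca(c(5, 5), 1e-3)
  expect_equal(est$t, 5000)
  expect_equal(est$se, sqrt(10) / (2 * 1e-3))
  x <- c(3, 7, 2, 9)
  expect_equal(thomson_tmrca(x, 2e-4)$t, thomson_tmrca(x, 1e-4)$t / 2)
  expect_equal(thomson_tmrca(rev(x), 1e-4)$t, thomson_tmrca(x, 1e-4)$t)
  expect_error(thomson_tmrca(x, 0), "positive")
})
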
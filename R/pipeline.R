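#' Default synthetic analysis profile
#'
#' The generator parameters the full battery runs on when no real inputs are
#' given. They mirror the study system: a 51-exon collagen locus; a
#' human-like population pair (African-style vs out-of-Africa-style) typed at
#' a few hundred intronic SNPs; a chimpanzee-like phased sample of 40
#' haplotypes carrying two deep haplogroups whose split sits at 2.8 My with a
#' shallow within-group star; a per-base mutation rate of 1e-9 /bp/yr
#' (a human-chimpanzee-like calibration: ~1% divergence over 2 x 5 My); a
#' conservation track more conserved over the first 21 introns; and a
#' severity-stratified mutation catalog with the clinical glycine gradient.
#'
#' @return named list of parameter blocks.
#' @export
default_synthetic_profile <- function() {
  list(
    pop_pair = list(n_sites = 400L, n_per_pop = 100L, fst_true = 0.10,
                    ancestral_freq_range = c(0.05, 0.95)),
    haplogroups = list(n_per_group = 20L, locus_length = 15600L,
                       mu = 1e-9, t_split = 2.8e6, t_within = 0.28e6),
    divergence = list(substitutions = 156L, time_years = 5e6,
                      time_halfwidth = 1e6),
    track = list(mean_5p = 0.5, mean_3p = -0.5, mean_exon = 2.5, sd = 1),
    dam = list(n_per_category = c(`1` = 100L, `2` = 80L, `3` = 60L,
                                  `4` = 120L),
               glycine_prob = c(`1` = 0.57, `2` = 0.91, `3` = 0.95,
                                `4` = 0.98),
               domain_weights = list(`1` = c(0.30, 0.40, 0.30),
                                     `2` = c(0.10, 0.80, 0.10),
                                     `3` = c(0.08, 0.84, 0.08),
                                     `4` = c(0.05, 0.90, 0.05))))
}

write_stage_tsv <- function(df, out_dir, stage) {
  path <- file.path(out_dir, paste0(stage, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis battery on the synthetic profile
#'
#' Executes, in order: variant annotation, frequency / SFS summaries,
#' conservation contrasts, the F_ST outlier scan, LD matrices and decay,
#' haplogroup partitioning, fixed differences plus the spatial clustering
#' test, the NJ tree with a monophyly check, and the TMRCA estimate. One TSV
#' is written per stage plus a machine-readable JSON summary carrying every
#' statistic, p-value, permutation count and seed. Each stage draws its own
#' seed from the top-level seed via \code{\link{derive_seed}}, so the stage
#' list can grow without perturbing earlier stages.
#'
#' @param out_dir output directory (created if absent).
#' @param seed top-level integer seed.
#' @param n_perm permutations for every randomization stage.
#' @param maf_min MAF filter for the LD stage.
#' @param block_split intron split index for the conservation contrast.
#' @param profile parameter list, see \code{\link{default_synthetic_profile}}.
#' @return the summary list, invisibly; side effect: TSVs and
#'   \code{summary.json} under \code{out_dir}.
#' @export
run_full_analysis <- function(out_dir, seed = 1L, n_perm = 999L,
                              maf_min = 0.05, block_split = 21L,
                              profile = default_synthetic_profile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(package = "colpopgen",
                  version = as.character(utils::packageVersion("colpopgen")),
                  seed = seed, n_perm = n_perm)
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(derive_seed(seed, name)),
                    error = function(e) stop("stage '", name, "' failed: ",
                                             conditionMessage(e), call. = FALSE))
    message(sprintf("stage %-22s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  model <- make_colgene_fixture()
  ilen <- intron_lengths(model)
  pp <- profile$pop_pair; hg <- profile$haplogroups

  # 1. variant annotation: place the population-pair SNPs on the gene model
  ann <- stage("variant_annotation", function(s) {
    span <- locus_span(model)
    gt <- simulate_population_pair(pp$n_sites, pp$n_per_pop, pp$fst_true,
                                   pp$ancestral_freq_range, seed = s)
    pos <- with_seed(s, sort(sample.int(span[2] - span[1],
                                        pp$n_sites)) - 1L)
    gt$positions <- as.numeric(pos)
    feats <- vapply(pos, function(p) locate_site(p, model)$feature, "")
    write_stage_tsv(data.frame(position = pos, feature = feats),
                    out_dir, "variant_annotation")
    list(gt = gt, features = feats)
  })
  summary$variant_annotation <- list(
    n_sites = pp$n_sites,
    n_intronic = sum(grepl("^intron", ann$features)))

  # 2. frequencies and site-frequency-spectrum summaries
  sfs <- stage("frequency_sfs", function(s) {
    fA <- allele_frequencies(ann$gt, "popA")
    maf <- pmin(fA, 1 - fA)
    list(freqA = fA, rare_below_1pct = sfs_fraction_below(maf[maf > 0], 0.01),
         theta = watterson_theta(sum(maf > 0), 2L * pp$n_per_pop,
                                 diff(locus_span(model))))
  })
  summary$frequency_sfs <- sfs[c("rare_below_1pct", "theta")]

  # 3. conservation contrasts over the intron blocks
  cons <- stage("conservation_contrast", function(s) {
    tr <- profile$track
    track <- simulate_conservation_track(
      model, two_block_profile(model, block_split, tr$mean_5p, tr$mean_3p,
                               tr$mean_exon), sd = tr$sd, seed = s)
    pr <- intron_block_randomization(track, model, block_split,
                                     n_perm = n_perm, seed = s + 1L)
    pr_no1 <- intron_block_randomization(track, model, block_split,
                                         n_perm = n_perm, seed = s + 2L,
                                         exclude_introns = 1L)
    write_stage_tsv(data.frame(test = c("block_contrast", "omit_intron_1"),
                               observed = c(pr$observed, pr_no1$observed),
                               p_value = c(pr$p_value, pr_no1$p_value),
                               n_perm = n_perm),
                    out_dir, "conservation_contrast")
    list(p = pr$p_value, p_omit1 = pr_no1$p_value, observed = pr$observed)
  })
  summary$conservation_contrast <- cons

  # 4. F_ST outlier scan
  scan <- stage("fst_outlier_scan", function(s) {
    sc <- fst_outlier_scan(ann$gt, "popA", "popB", n_perm = n_perm, seed = s)
    write_stage_tsv(as.data.frame(sc), out_dir, "fst_outlier_scan")
    sc
  })
  summary$fst_outlier_scan <- list(
    n_snps = nrow(scan), n_flagged = sum(scan$flagged),
    mean_fst = hudson_fst_pair(ann$gt, "popA", "popB")$mean_fst)

  # 5-9 run on the phased two-haplogroup sample
  sim <- stage("haplogroup_simulation", function(s)
    simulate_two_haplogroup_locus(hg$n_per_group, hg$locus_length, hg$mu,
                                  hg$t_split, hg$t_within, seed = s))
  hm <- sim$haplotypes

  ld <- stage("ld_structure", function(s) {
    r2 <- ld_r2_matrix(hm, maf_min = maf_min)
    idx <- attr(r2, "retained")
    long <- data.frame(
      pos_a = rep(hm$positions[idx], times = length(idx)),
      pos_b = rep(hm$positions[idx], each = length(idx)),
      r2 = as.vector(r2))
    write_stage_tsv(long[long$pos_a < long$pos_b, ], out_dir, "ld_structure")
    prof <- ld_decay_profile(hm, anchor_sites = idx[1:min(3, length(idx))],
                             breaks = c(0, 2000, 5000, 10000, 16000),
                             maf_min = maf_min)
    list(mean_offdiag = mean(r2[upper.tri(r2)]), decay = prof)
  })
  summary$ld_structure <- list(mean_r2 = ld$mean_offdiag)

  part <- stage("haplogroup_partition", function(s)
    partition_core_haplogroups(hm))
  summary$haplogroup_partition <- list(
    score = part$score,
    matches_truth = all(part$assignment == sim$truth$assignment) ||
      all(part$assignment == 3L - sim$truth$assignment))

  fixed <- stage("fixed_differences_spatial", function(s) {
    fd <- fixed_differences(hm, part$assignment)
    feats <- vapply(fd$positions, function(p) {
      # map locus-relative simulated positions onto the intron backbone
      findInterval(p, cumsum(ilen)) + 1L
    }, 0L)
    obs_target <- sum(feats <= block_split)
    sp <- spatial_clustering_test(fd$count, model, seq_len(block_split),
                                  obs_target, n_perm = n_perm, seed = s)
    write_stage_tsv(data.frame(n_fixed = fd$count,
                               in_first_block = obs_target,
                               p_value = sp$p_value), out_dir,
                    "fixed_differences_spatial")
    list(count = fd$count, in_first_block = obs_target, p = sp$p_value)
  })
  summary$fixed_differences_spatial <- fixed

  tree_res <- stage("nj_tree", function(s) {
    # outgroup carries the ancestral allele everywhere
    out_allele <- matrix(0L, 1, ncol(hm$alleles))
    hm_og <- haplotype_matrix(rbind(hm$alleles, out_allele), hm$positions,
                              ref = hm$ref, alt = hm$alt,
                              sample_ids = c(hm$sample_ids, "outgroup"))
    tr <- neighbor_joining(p_distance_matrix(hm_og))
    ape::write.tree(tr, file.path(out_dir, "nj_tree.nwk"))
    g1 <- hm$sample_ids[sim$truth$assignment == 1L]
    list(tree = tr,
         g1_monophyletic = is_monophyletic(tr, g1, "outgroup"))
  })
  summary$nj_tree <- list(g1_monophyletic = tree_res$g1_monophyletic)

  tmrca <- stage("tmrca", function(s) {
    dv <- profile$divergence
    mu <- estimate_mu(dv$substitutions, dv$time_years, dv$time_halfwidth)
    xm <- mutations_from_mrca(hm, sim$outgroup_alleles)
    est <- thomson_tmrca(xm$x, mu$mu)
    write_stage_tsv(data.frame(haplotype = names(xm$x), x = xm$x),
                    out_dir, "tmrca_x")
    list(t_years = est$t, se_years = est$se, mu = mu$mu,
         t_interval_years = sum(xm$x) / (est$n * mu$mu_interval))
  })
  summary$tmrca <- tmrca

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
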
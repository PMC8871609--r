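#' Deterministic collagen-gene fixture model
#'
#' A 51-exon / 50-intron gene model echoing the structure of a fibrillar
#' collagen locus: short exons (45-108 bp, all multiples of 9 bp, the legacy
#' of an ancestral 54 bp unit), a long first intron, and a protein partitioned
#' into N-propeptide, triple-helix and C-propeptide domains. The first 21
#' introns total exactly 6700 bp and the last 29 exactly 8900 bp, the two
#' intron blocks contrasted by every spatial test in the package.
#'
#' @return a \code{\link{gene_model}}.
#' @export
make_colgene_fixture <- function() {
  exon_len <- rep(c(54L, 45L, 99L, 54L, 63L, 108L, 54L, 45L, 72L, 54L),
                  length.out = 51L)
  # intron 1 long (as first introns typically are); blocks sum to 6700 / 8900
  intron_len <- c(1000L, rep(285L, 20L), rep(307L, 28L), 304L)
  stopifnot(sum(intron_len[1:21]) == 6700L, sum(intron_len[22:50]) == 8900L)
  starts <- integer(51L); ends <- integer(51L)
  pos <- 0L
  for (i in 1:51) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i]
    pos <- ends[i] + if (i < 51L) intron_len[i] else 0L
  }
  n_res <- sum(exon_len) %/% 3L
  doms <- list(N_terminal = c(1L, 160L),
               triple_helix = c(161L, n_res - 168L),
               C_terminal = c(n_res - 167L, n_res))
  gene_model(chrom = "colgene", strand = "+", exon_starts = starts,
             exon_ends = ends, domains = doms, coding_offset = 0L)
}

#' Simulate a two-haplogroup locus on a stem-and-star genealogy
#'
#' Emulates a locus carrying two deep haplogroups (as the chimpanzee collagen
#' locus does): all haplotypes coalesce at \code{t_split} years; each group
#' has a stem of length \code{t_split - t_within} and its tips hang as a star
#' at depth \code{t_within}. Mutations fall as a Poisson process at rate
#' \code{mu} per base-year along every branch and land at distinct uniform
#' positions (infinite sites). The recorded truth makes fixed differences and
#' per-tip mutation counts from the MRCA exact.
#'
#' @param n_per_group haplotypes per haplogroup.
#' @param locus_length locus length in bp.
#' @param mu mutation rate per base per year.
#' @param t_split years to the MRCA of all haplotypes.
#' @param t_within depth of the within-group star, years
#'   (default \code{0.1 * t_split}).
#' @param seed integer seed.
#' @return list with \code{haplotypes} (a \code{\link{haplotype_matrix}} with
#'   \code{group_labels} \code{"g1"}/\code{"g2"}), \code{outgroup_alleles}
#'   (ancestral base per site, for polarization), and \code{truth}:
#'   \code{fixed_diff_positions}, \code{x} (per-tip mutation count from the
#'   MRCA), \code{assignment}, \code{mrca} (ancestral allele codes, all 0).
#' @export
simulate_two_haplogroup_locus <- function(n_per_group, locus_length, mu,
                                          t_split, t_within = 0.1 * t_split,
                                          seed = 1L) {
  stopifnot(is.finite(mu), mu >= 0, is.finite(t_split), t_split > 0,
            t_within < t_split, t_within >= 0, n_per_group >= 1)
  with_seed(seed, {
    H <- 2L * n_per_group
    stem_len <- t_split - t_within
    # branches: 2 stems, then H tip branches
    branch_T <- c(stem_len, stem_len, rep(t_within, H))
    n_mut <- stats::rpois(length(branch_T), mu * locus_length * branch_T)
    total <- sum(n_mut)
    if (total > locus_length)
      stop("more mutations than bases; infinite-sites assumption broken")
    pos <- sort(sample.int(locus_length, total)) - 1L   # distinct, 0-based
    branch <- rep(seq_along(branch_T), n_mut)
    branch <- branch[order(sample.int(total))]          # shuffle positions
    alleles <- matrix(0L, nrow = H, ncol = total)
    grp <- rep(c(1L, 2L), each = n_per_group)
    for (s in seq_len(total)) {
      b <- branch[s]
      carriers <- if (b == 1L) which(grp == 1L)
                  else if (b == 2L) which(grp == 2L)
                  else b - 2L
      alleles[carriers, s] <- 1L
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, total, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    hm <- haplotype_matrix(alleles, pos, ref = ref, alt = unname(alt),
                           group_labels = paste0("g", grp), polarized = TRUE)
    x <- tabulate(branch[branch > 2L] - 2L, nbins = H) +
      n_mut[1L] * (grp == 1L) + n_mut[2L] * (grp == 2L)
    list(haplotypes = hm,
         outgroup_alleles = ref,   # ancestral state = reference base
         truth = list(fixed_diff_positions = pos[branch <= 2L],
                      x = x, assignment = grp,
                      mrca = rep(0L, total)))
  })
}

#' Simulate a diverged population pair under the Balding-Nichols model
#'
#' Per site an ancestral frequency is drawn uniformly on
#' \code{ancestral_freq_range}; each population's frequency is then a Beta
#' draw with that mean and variance parameter \code{fst_true}
#' (\code{Var = fst_true * p * (1 - p)}); diploid genotypes are
#' \code{Binomial(2, freq)}. Gives a single interpretable truth parameter for
#' calibrating the differentiation estimator.
#'
#' @param n_sites SNP count.
#' @param n_per_pop diploid individuals per population.
#' @param fst_true divergence parameter in (0, 1).
#' @param ancestral_freq_range \code{c(lo, hi)} with 0 < lo < hi < 1.
#' @param seed integer seed.
#' @return a \code{\link{genotype_table}} with populations \code{"popA"} and
#'   \code{"popB"}.
#' @export
simulate_population_pair <- function(n_sites, n_per_pop, fst_true,
                                     ancestral_freq_range = c(0.1, 0.9),
                                     seed = 1L) {
  stopifnot(fst_true > 0, fst_true < 1,
            ancestral_freq_range[1] > 0,
            ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] < ancestral_freq_range[2])
  with_seed(seed, {
    pbar <- stats::runif(n_sites, ancestral_freq_range[1],
                         ancestral_freq_range[2])
    a <- pbar * (1 - fst_true) / fst_true
    b <- (1 - pbar) * (1 - fst_true) / fst_true
    p1 <- stats::rbeta(n_sites, a, b)
    p2 <- stats::rbeta(n_sites, a, b)
    g1 <- matrix(stats::rbinom(n_sites * n_per_pop, 2L, rep(p1, each = n_per_pop)),
                 nrow = n_per_pop)
    g2 <- matrix(stats::rbinom(n_sites * n_per_pop, 2L, rep(p2, each = n_per_pop)),
                 nrow = n_per_pop)
    genotype_table(rbind(g1, g2), positions = seq_len(n_sites) * 10 - 10,
                   population = rep(c("popA", "popB"), each = n_per_pop))
  })
}

#' Simulate a block-structured conservation track over a gene model
#'
#' Per-base scores are Normal(mean of the containing block, sd). Blocks are
#' named feature sets (\code{"exon_i"}, \code{"intron_j"}) that must jointly
#' cover the locus.
#'
#' @param model a \code{\link{gene_model}}.
#' @param blocks list of \code{list(features = <character>, mean = <numeric>)}.
#' @param sd per-base standard deviation.
#' @param seed integer seed.
#' @return a \code{\link{conservation_track}} over the locus span.
#' @export
simulate_conservation_track <- function(model, blocks, sd = 1, seed = 1L) {
  span <- locus_span(model)
  mean_per_base <- rep(NA_real_, span[2] - span[1])
  feat_interval <- function(f) {
    i <- as.integer(sub("^[a-z]+_", "", f))
    if (grepl("^exon_", f)) model$exons[i, ] else model$introns[i, ]
  }
  for (b in blocks) for (f in b$features) {
    iv <- feat_interval(f)
    mean_per_base[(iv[1] - span[1] + 1):(iv[2] - span[1])] <- b$mean
  }
  if (anyNA(mean_per_base))
    stop("blocks do not cover the locus: ",
         sum(is.na(mean_per_base)), " uncovered base(s)")
  with_seed(seed, {
    conservation_track(stats::rnorm(length(mean_per_base), mean_per_base, sd),
                       start = span[1], chrom = model$chrom)
  })
}

#' Default two-block conservation profile (first k introns vs the rest)
#'
#' Convenience builder for \code{\link{simulate_conservation_track}}: exons at
#' a high conserved mean, introns split at index \code{k} into a
#' more-conserved 5' block and a less-conserved 3' block.
#'
#' @param model a \code{\link{gene_model}}.
#' @param k intron split index.
#' @param mean_5p,mean_3p,mean_exon block means (phyloP-scale).
#' @return a block list.
#' @export
two_block_profile <- function(model, k = 21L, mean_5p = 0.5, mean_3p = -0.5,
                              mean_exon = 2.5) {
  n_int <- nrow(model$introns)
  list(list(features = paste0("exon_", seq_len(nrow(model$exons))),
            mean = mean_exon),
       list(features = paste0("intron_", seq_len(k)), mean = mean_5p),
       list(features = paste0("intron_", (k + 1):n_int), mean = mean_3p))
}

#' Simulate a severity-stratified disease-mutation catalog
#'
#' Emulates a clinical catalog of collagen mutations: exact counts per
#' severity category (1 = mildest to 4 = lethal), per-category probability
#' that the mutated reference residue is glycine, and per-category domain
#' weights.
#'
#' @param n_per_category named vector, e.g. \code{c(`1` = 50, `4` = 50)}.
#' @param glycine_prob named vector of per-category glycine probabilities.
#' @param domain_weights named list of per-category weight vectors over
#'   \code{c(N_terminal, triple_helix, C_terminal)}; a single vector is
#'   recycled.
#' @param n_residues protein length used to draw residue positions.
#' @param seed integer seed.
#' @return a \code{dam_table} data.frame.
#' @export
simulate_dam_catalog <- function(n_per_category,
                                 glycine_prob,
                                 domain_weights = c(0.1, 0.8, 0.1),
                                 n_residues = 1000L, seed = 1L) {
  if (any(glycine_prob < 0 | glycine_prob > 1))
    stop("glycine probabilities must lie in [0, 1]")
  doms <- c("N_terminal", "triple_helix", "C_terminal")
  aas <- strsplit("ACDEFHIKLMNPQRSTVWY", "")[[1]]  # 19 non-glycine
  with_seed(seed, {
    recs <- lapply(names(n_per_category), function(cat) {
      n <- n_per_category[[cat]]
      if (n == 0) return(NULL)
      w <- if (is.list(domain_weights)) domain_weights[[cat]] else domain_weights
      gly <- stats::rbinom(n, 1L, glycine_prob[[cat]]) == 1L
      aa_from <- ifelse(gly, "G", sample(aas, n, replace = TRUE))
      aa_to <- vapply(aa_from, function(a)
        sample(setdiff(c(aas, "G"), a), 1L), "")
      data.frame(residue = sample.int(n_residues, n, replace = TRUE),
                 aa_from = aa_from, aa_to = unname(aa_to),
                 domain = sample(doms, n, replace = TRUE, prob = w),
                 severity = as.integer(cat),
                 site_score = stats::rnorm(n, mean = 2, sd = 1))
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    class(out) <- c("dam_table", "data.frame")
    out
  })
}
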
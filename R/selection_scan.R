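#' Permutation location test for two groups of values
#'
#' Nonparametric contrast of two value distributions (conservation scores,
#' allele frequencies, ...) evaluated by label permutation. The default
#' statistic is the rank-sum of group A over the pooled ranking (a Wilcoxon
#' statistic); a mean-difference statistic is available. Two-sided p-values
#' double the smaller add-one tail, capped at 1.
#'
#' @param valuesA,valuesB non-empty numeric vectors.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param statistic \code{"rank_sum"} or \code{"mean_diff"}.
#' @param alternative \code{"two.sided"} (default), \code{"greater"},
#'   \code{"less"} (tails refer to group A's statistic).
#' @return a \code{\link{perm_result}}.
#' @export
permutation_location_test <- function(valuesA, valuesB, n_perm = 999L,
                                      seed = 1L,
                                      statistic = c("rank_sum", "mean_diff"),
                                      alternative = c("two.sided", "greater",
                                                      "less")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  nA <- length(valuesA); nB <- length(valuesB)
  if (nA == 0 || nB == 0) stop("both groups must be non-empty")
  if (n_perm < 99) stop("use at least 99 permutations")
  pool <- c(valuesA, valuesB)
  stat_fun <- if (statistic == "rank_sum") {
    r <- rank(pool)
    function(idx) sum(r[idx])
  } else function(idx) mean(pool[idx]) - mean(pool[-idx])
  obs <- stat_fun(seq_len(nA))
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm),
                   function(i) stat_fun(sample.int(nA + nB, nA)), 0)
    n_ge <- sum(perm >= obs); n_le <- sum(perm <= obs)
    p <- switch(alternative,
                greater = (n_ge + 1) / (n_perm + 1),
                less = (n_le + 1) / (n_perm + 1),
                two.sided = min(1, 2 * (min(n_ge, n_le) + 1) / (n_perm + 1)))
    perm_result(obs, n_perm, switch(alternative, greater = n_ge,
                                    less = n_le, two.sided = min(n_ge, n_le)),
                p, seed, alternative,
                extra = list(statistic = statistic))
  })
}

#' Per-SNP F_ST outlier scan by pooled resampling
#'
#' For every SNP the null distribution is built by pooling all called allele
#' copies of the two populations and randomly re-splitting them into the
#' original sample sizes (sampling without replacement, so the pop-1
#' alternate-allele count is hypergeometric), then recomputing Hudson's
#' per-SNP F_ST. The per-SNP p-value is the add-one fraction of resampled
#' values >= the observed one. SNPs with observed F_ST above
#' \code{flag_threshold} are flagged as candidate outliers.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param popA,popB population labels.
#' @param n_perm resamples per SNP (default 1000).
#' @param seed integer seed.
#' @param flag_threshold F_ST level flagged in the report (default 0.30).
#' @param adjust optional p-adjustment method passed to
#'   \code{\link[stats]{p.adjust}} (e.g. \code{"BH"}); raw p-values are always
#'   reported.
#' @param tie_break \code{"conservative"} (default: resampled values tying
#'   the observed one count as extreme, giving a valid but super-uniform
#'   p-value on the discrete resampling support) or \code{"random"} (the
#'   observed statistic's rank inside its tie group is randomized, which
#'   makes the null p-value distribution exactly uniform on the add-one
#'   grid).
#' @return data.frame of class \code{"fst_scan"}: position, fst, p_value,
#'   flagged (and p_adjusted when requested); attributes \code{n_perm},
#'   \code{seed}.
#' @export
fst_outlier_scan <- function(gt, popA, popB, n_perm = 1000L, seed = 1L,
                             flag_threshold = 0.30, adjust = NULL,
                             tie_break = c("conservative", "random")) {
  tie_break <- match.arg(tie_break)
  gA <- gt$genotypes[gt$population == popA, , drop = FALSE]
  gB <- gt$genotypes[gt$population == popB, , drop = FALSE]
  if (nrow(gA) < 1 || nrow(gB) < 1) stop("population absent from table")
  nA <- 2 * colSums(!is.na(gA)); nB <- 2 * colSums(!is.na(gB))
  kA <- colSums(gA, na.rm = TRUE); kB <- colSums(gB, na.rm = TRUE)
  ok <- nA >= 2 & nB >= 2 & (kA + kB) > 0 & (kA + kB) < (nA + nB)
  S <- sum(ok)
  if (S == 0) stop("no polymorphic SNP shared by the pair")
  nA <- nA[ok]; nB <- nB[ok]; kA <- kA[ok]; kB <- kB[ok]
  obs <- hudson_fst_snp(kA / nA, nA, kB / nB, nB)
  with_seed(seed, {
    K <- kA + kB; N <- nA + nB
    n_gt <- integer(S); n_eq <- integer(S)
    for (b in seq_len(n_perm)) {
      xA <- stats::rhyper(S, K, N - K, nA)
      null <- hudson_fst_snp(xA / nA, nA, (K - xA) / nB, nB)
      hit <- !is.na(null)
      n_gt <- n_gt + (hit & null > obs + 1e-12)
      n_eq <- n_eq + (hit & abs(null - obs) <= 1e-12)
    }
    p <- if (tie_break == "conservative")
      (n_gt + n_eq + 1) / (n_perm + 1)
    else   # observed value placed uniformly at random within its tie group
      (n_gt + 1L + floor(stats::runif(S) * (n_eq + 1))) / (n_perm + 1)
    out <- data.frame(position = gt$positions[ok], fst = obs,
                      p_value = p,
                      flagged = obs > flag_threshold)
    if (!is.null(adjust)) out$p_adjusted <- stats::p.adjust(out$p_value, adjust)
    structure(out, n_perm = as.integer(n_perm), seed = as.integer(seed),
              class = c("fst_scan", "data.frame"))
  })
}

# length-weighted mean block contrast used by intron_block_randomization
weighted_block_stat <- function(means, lens, in_first) {
  stats::weighted.mean(means[in_first], lens[in_first]) -
    stats::weighted.mean(means[!in_first], lens[!in_first])
}

#' Randomization test for a conservation contrast between intron blocks
#'
#' Statistic: length-weighted mean conservation score of introns 1..k minus
#' that of introns k+1..end (weights = intron lengths in bases, so the
#' contrast accounts for unequal intron lengths). The null permutes intron
#' identities between the two groups, keeping group sizes; an alternative
#' \code{mode = "site"} permutes per-base scores across all intron bases
#' instead. \code{exclude_introns} removes introns entirely before splitting
#' (e.g. to rerun without the long first intron).
#'
#' @param track a \code{\link{conservation_track}} covering the model span.
#' @param model a \code{\link{gene_model}}.
#' @param block_split k, the last intron of the 5' block (1 <= k < n introns).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param exclude_introns optional integer set of intron indices to drop.
#' @param alternative \code{"greater"} (default: 5' block more conserved),
#'   \code{"less"} or \code{"two.sided"}.
#' @param mode \code{"label"} (permute intron identities) or \code{"site"}
#'   (permute per-base scores).
#' @return a \code{\link{perm_result}}.
#' @export
intron_block_randomization <- function(track, model, block_split,
                                       n_perm = 999L, seed = 1L,
                                       exclude_introns = NULL,
                                       alternative = c("greater", "less",
                                                       "two.sided"),
                                       mode = c("label", "site")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  n_int <- nrow(model$introns)
  if (block_split < 1 || block_split >= n_int)
    stop("block_split must lie in [1, ", n_int - 1, "]")
  idx <- setdiff(seq_len(n_int), exclude_introns)
  in_first <- idx <= block_split
  if (!any(in_first) || all(in_first))
    stop("exclusion leaves an empty intron group")
  site_scores <- lapply(idx, function(i)
    track_scores(track, model$introns[i, ]))
  means <- vapply(site_scores, mean, 0, na.rm = TRUE)
  lens <- intron_lengths(model)[idx]
  obs <- weighted_block_stat(means, lens, in_first)
  k1 <- sum(in_first)
  with_seed(seed, {
    if (mode == "label") {
      perm <- vapply(seq_len(n_perm), function(b) {
        first <- sample.int(length(idx), k1)
        inf <- seq_along(idx) %in% first
        weighted_block_stat(means, lens, inf)
      }, 0)
    } else {
      all_scores <- unlist(site_scores)
      grp_len <- lengths(site_scores)
      grp <- rep(seq_along(idx), grp_len)
      perm <- vapply(seq_len(n_perm), function(b) {
        shuf <- sample(all_scores)
        m <- vapply(split(shuf, grp), mean, 0, na.rm = TRUE)
        weighted_block_stat(m, lens, in_first)
      }, 0)
    }
    n_ge <- sum(perm >= obs); n_le <- sum(perm <= obs)
    p <- switch(alternative,
                greater = (n_ge + 1) / (n_perm + 1),
                less = (n_le + 1) / (n_perm + 1),
                two.sided = min(1, 2 * (min(n_ge, n_le) + 1) / (n_perm + 1)))
    perm_result(obs, n_perm,
                switch(alternative, greater = n_ge, less = n_le,
                       two.sided = min(n_ge, n_le)),
                p, seed, alternative, extra = list(mode = mode))
  })
}

#' Spatial clustering test for mutations over introns
#'
#' Are the observed mutations (e.g. fixed differences between haplogroups)
#' clustered in a target set of introns? Each permutation drops
#' \code{n_mutations} uniformly at random over the concatenated intron bases
#' and counts how many land in the target introns; the one-sided add-one
#' p-value is the fraction of permutations with a count >= observed.
#'
#' @param n_mutations total mutations to place.
#' @param model a \code{\link{gene_model}}.
#' @param target_introns integer set of target intron indices.
#' @param observed_in_target observed count in the target introns
#'   (<= \code{n_mutations}).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return a \code{\link{perm_result}} with extra field \code{fraction}
#'   (target fraction of intron bases).
#' @export
spatial_clustering_test <- function(n_mutations, model, target_introns,
                                    observed_in_target, n_perm = 9999L,
                                    seed = 1L) {
  stopifnot(observed_in_target <= n_mutations, length(target_introns) > 0)
  lens <- intron_lengths(model)
  total <- sum(lens)
  if (total == 0) stop("zero intron length")
  member <- rep(seq_along(lens), lens) %in% target_introns
  with_seed(seed, {
    draws <- sample.int(total, n_mutations * n_perm, replace = TRUE)
    counts <- colSums(matrix(member[draws], nrow = n_mutations))
    n_ge <- sum(counts >= observed_in_target)
    perm_result(observed_in_target, n_perm, n_ge,
                (n_ge + 1) / (n_perm + 1), seed, "greater",
                extra = list(fraction = sum(lens[target_introns]) / total))
  })
}

#' Exact binomial tail for the spatial clustering test
#'
#' Closed-form counterpart of \code{\link{spatial_clustering_test}}: with
#' mutations dropped independently and uniformly, the count in the target
#' region is Binomial(n, fraction), so the exact tail is
#' \eqn{P(X \ge observed)}.
#'
#' @param n_mutations total mutations.
#' @param fraction_in_target fraction of intron bases in the target set.
#' @param observed observed count in the target.
#' @return exact upper-tail probability.
#' @export
exact_spatial_tail <- function(n_mutations, fraction_in_target, observed) {
  stopifnot(fraction_in_target >= 0, fraction_in_target <= 1,
            observed >= 0, observed <= n_mutations)
  if (observed == 0) return(1)
  sum(stats::dbinom(observed:n_mutations, n_mutations, fraction_in_target))
}
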
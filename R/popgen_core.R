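#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_{n-1} L)} with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i},
#' the segregating-sites diversity estimator.
#'
#' @param S number of segregating sites.
#' @param n number of allele copies sampled.
#' @param L number of base pairs surveyed.
#' @return per-site theta.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("need at least 2 allele copies")
  stopifnot(L > 0, S >= 0)
  S / (sum(1 / seq_len(n - 1)) * L)
}

#' Alternate-allele frequency at one site
#'
#' Missing genotypes are excluded from the denominator (no imputation).
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param site site index (column).
#' @param population optional population label to restrict to.
#' @return frequency in [0, 1].
#' @export
allele_frequency <- function(gt, site, population = NULL) {
  g <- gt$genotypes[, site]
  if (!is.null(population)) g <- g[gt$population == population]
  called <- !is.na(g)
  if (!any(called)) stop("all genotypes missing at site ", site)
  sum(g[called]) / (2 * sum(called))
}

#' Alternate-allele frequencies at every site
#' @inheritParams allele_frequency
#' @return numeric vector, one frequency per site.
#' @export
allele_frequencies <- function(gt, population = NULL) {
  g <- gt$genotypes
  if (!is.null(population)) g <- g[gt$population == population, , drop = FALSE]
  called <- colSums(!is.na(g))
  if (any(called == 0)) stop("site with no called genotypes")
  colSums(g, na.rm = TRUE) / (2 * called)
}

#' Fraction of frequencies strictly below a cutoff
#'
#' Site-frequency-spectrum summary: the proportion of (minor or derived)
#' allele frequencies below the cutoff, e.g. the rare fraction below 1%.
#'
#' @param freqs non-empty numeric vector of frequencies.
#' @param cutoff value in (0, 1); comparison is strict (\code{<}).
#' @return proportion in [0, 1].
#' @export
sfs_fraction_below <- function(freqs, cutoff) {
  if (length(freqs) == 0) stop("empty frequency list")
  stopifnot(cutoff > 0, cutoff < 1)
  mean(freqs < cutoff)
}

#' Hudson's per-SNP F_ST from allele frequencies
#'
#' \eqn{F_{ST} = 1 - H_w / H_b} with \eqn{H_w} the mean of the two unbiased
#' within-population heterozygosities \eqn{2 p (1-p) n/(n-1)} (n = allele
#' copies) and \eqn{H_b = p_1(1-p_2) + p_2(1-p_1)}. Sites monomorphic for the
#' same allele in both populations have \eqn{H_b = 0} and return \code{NA}
#' (undefined, excluded from averages). Vectorized over sites.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 allele copies sampled (not individuals) per population.
#' @return per-SNP F_ST (\code{NA} where undefined); values never exceed 1 and
#'   may be negative.
#' @export
hudson_fst_snp <- function(p1, n1, p2, n2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
            all(n1 >= 2), all(n2 >= 2))
  hw <- (2 * p1 * (1 - p1) * n1 / (n1 - 1) +
           2 * p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(hb == 0, NA_real_, 1 - hw / hb)
}

#' Hudson F_ST between two labeled populations
#'
#' Computes per-SNP values over all sites defined in both populations and
#' combines them. The default combination is the arithmetic mean of per-SNP
#' values ("average of ratios"); the "ratio of averages"
#' \eqn{1 - \sum H_w / \sum H_b}, which is the consistent multi-SNP
#' combination, is available via \code{combine}.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param popA,popB population labels.
#' @param combine \code{"average_of_ratios"} (default) or
#'   \code{"ratio_of_averages"}.
#' @return object of class \code{"fst_result"}: \code{per_snp} data.frame
#'   (position, fst), \code{mean_fst}, \code{n_snps}, \code{combine}.
#' @export
hudson_fst_pair <- function(gt, popA, popB,
                            combine = c("average_of_ratios",
                                        "ratio_of_averages")) {
  combine <- match.arg(combine)
  gA <- gt$genotypes[gt$population == popA, , drop = FALSE]
  gB <- gt$genotypes[gt$population == popB, , drop = FALSE]
  if (nrow(gA) < 1 || nrow(gB) < 1) stop("population absent from table")
  nA <- 2 * colSums(!is.na(gA)); nB <- 2 * colSums(!is.na(gB))
  ok <- nA >= 2 & nB >= 2
  pA <- colSums(gA, na.rm = TRUE)[ok] / nA[ok]
  pB <- colSums(gB, na.rm = TRUE)[ok] / nB[ok]
  fst <- hudson_fst_snp(pA, nA[ok], pB, nB[ok])
  def <- !is.na(fst)
  if (!any(def)) stop("no SNP polymorphic in the pooled pair")
  mean_fst <- if (combine == "average_of_ratios") mean(fst[def]) else {
    hw <- (2 * pA * (1 - pA) * nA[ok] / (nA[ok] - 1) +
             2 * pB * (1 - pB) * nB[ok] / (nB[ok] - 1)) / 2
    hb <- pA * (1 - pB) + pB * (1 - pA)
    1 - sum(hw[def]) / sum(hb[def])
  }
  structure(list(per_snp = data.frame(position = gt$positions[ok],
                                      fst = fst),
                 mean_fst = mean_fst, n_snps = sum(def), combine = combine),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Hudson F_ST over", x$n_snps, "SNPs (", x$combine, "):",
      format(x$mean_fst), "\n")
  invisible(x)
}

# minor allele frequency per site of a haplotype matrix
hap_maf <- function(hm) {
  p <- colMeans(hm$alleles, na.rm = TRUE)
  pmin(p, 1 - p)
}

#' Pairwise linkage disequilibrium r-squared for two sites
#'
#' \eqn{r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))} with \eqn{D = p_{AB} - p_A p_B},
#' computed over haplotypes non-missing at both sites.
#'
#' @param hm a \code{\link{haplotype_matrix}}.
#' @param siteA,siteB site indices.
#' @return r-squared in [0, 1].
#' @export
ld_r2_pair <- function(hm, siteA, siteB) {
  a <- hm$alleles[, siteA]; b <- hm$alleles[, siteB]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic site among complete haplotypes")
  D <- mean(a * b) - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Pairwise r-squared matrix with a minor-allele-frequency filter
#'
#' Sites with MAF strictly below \code{maf_min} are removed before any pair
#' is computed; the matrix diagonal is 1.
#'
#' @param hm a \code{\link{haplotype_matrix}}.
#' @param maf_min retain sites with MAF >= this value (default 0.05).
#' @return symmetric matrix over retained sites, with attribute
#'   \code{"retained"} giving their original indices.
#' @export
ld_r2_matrix <- function(hm, maf_min = 0.05) {
  keep <- which(hap_maf(hm) >= maf_min)
  if (length(keep) < 2)
    stop("fewer than 2 sites retained by the MAF >= ", maf_min, " filter")
  m <- hm$alleles[, keep, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  dimnames(r2) <- list(hm$positions[keep], hm$positions[keep])
  attr(r2, "retained") <- keep
  r2
}

#' Mean r-squared by distance bin around anchor SNPs
#'
#' Profiles LD decay: for each distance bin, the mean r-squared between the
#' anchor sites and every other retained site whose distance to the anchor
#' falls in the bin. Empty bins are \code{NA} with \code{n_pairs = 0}, never
#' zero.
#'
#' @param hm a \code{\link{haplotype_matrix}}.
#' @param anchor_sites site indices used as anchors.
#' @param breaks ordered distance-bin breaks (bp); bins are
#'   \code{[breaks[i], breaks[i+1])}.
#' @param maf_min MAF filter applied to all sites first.
#' @return data.frame with \code{bin_lo}, \code{bin_hi}, \code{mean_r2},
#'   \code{n_pairs}.
#' @export
ld_decay_profile <- function(hm, anchor_sites, breaks, maf_min = 0) {
  stopifnot(!is.unsorted(breaks, strictly = TRUE))
  keep <- which(hap_maf(hm) >= maf_min)
  anchors <- intersect(anchor_sites, keep)
  if (length(anchors) == 0) stop("no anchor site passes the MAF filter")
  others <- setdiff(keep, anchor_sites)
  pairs <- expand.grid(a = anchors, o = others)
  d <- abs(hm$positions[pairs$a] - hm$positions[pairs$o])
  r2 <- mapply(function(i, j) ld_r2_pair(hm, i, j), pairs$a, pairs$o)
  bin <- cut(d, breaks, right = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  agg <- tapply(r2, bin, mean)
  cnt <- tapply(r2, bin, length)
  out$mean_r2 <- as.numeric(agg[levels(bin)])
  out$n_pairs <- ifelse(is.na(cnt[levels(bin)]), 0L, cnt[levels(bin)])
  rownames(out) <- NULL
  out
}

#' McDonald-Kreitman test
#'
#' 2 x 2 contrast of replacement vs neutral-proxy (intronic) variation,
#' polymorphism vs divergence, tested with a two-sided Fisher exact test. If
#' a MAF cutoff and per-variant frequency lists are supplied, polymorphism
#' counts are recomputed from variants with frequency >= cutoff before
#' testing (rare polymorphisms excluded). The odds ratio is the sample
#' cross-product ratio; a Haldane-Anscombe 0.5 correction is applied (and
#' flagged) only when a zero cell would make it undefined.
#'
#' @param replacement_poly,replacement_div,neutral_poly,neutral_div counts.
#' @param maf_cutoff optional frequency cutoff.
#' @param replacement_freqs,neutral_freqs per-variant frequencies of the
#'   polymorphic classes, required with \code{maf_cutoff}.
#' @return object of class \code{"mk_table"}: \code{table} (2x2),
#'   \code{odds_ratio}, \code{p_value}, \code{or_corrected},
#'   \code{maf_cutoff}.
#' @export
mk_test <- function(replacement_poly, replacement_div, neutral_poly,
                    neutral_div, maf_cutoff = NULL,
                    replacement_freqs = NULL, neutral_freqs = NULL) {
  if (!is.null(maf_cutoff)) {
    if (is.null(replacement_freqs) || is.null(neutral_freqs))
      stop("maf_cutoff requires per-variant frequency lists")
    replacement_poly <- sum(replacement_freqs >= maf_cutoff)
    neutral_poly <- sum(neutral_freqs >= maf_cutoff)
  }
  tab <- matrix(c(replacement_poly, neutral_poly,
                  replacement_div, neutral_div), nrow = 2,
                dimnames = list(c("replacement", "neutral"),
                                c("polymorphism", "divergence")))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero MK table")
  p <- stats::fisher.test(tab)$p.value
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  structure(list(table = tab, odds_ratio = or, p_value = p,
                 or_corrected = corrected, maf_cutoff = maf_cutoff),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  cat("McDonald-Kreitman 2x2 test\n")
  print(x$table)
  cat("odds ratio:", format(x$odds_ratio),
      if (x$or_corrected) "(Haldane-Anscombe corrected)" else "",
      " two-sided Fisher p:", format(x$p_value), "\n")
  invisible(x)
}
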
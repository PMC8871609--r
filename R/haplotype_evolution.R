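# pairwise Hamming mismatch counts with pairwise deletion of missing data
hamming_counts <- function(alleles) {
  M0 <- alleles; M0[is.na(M0)] <- 0L
  Mok <- (!is.na(alleles)) * 1L
  mism <- M0 %*% t(Mok) + Mok %*% t(M0) - 2 * (M0 %*% t(M0))
  valid <- Mok %*% t(Mok)
  list(mismatch = mism, valid = valid)
}

#' Partition haplotypes into two core haplogroups
#'
#' 2-medoid clustering on Hamming distance: seeded by the maximally distant
#' haplotype pair (ties broken by lowest indices), haplotypes assigned to the
#' nearest medoid (ties to the lower-index medoid), medoids re-chosen as the
#' within-group distance minimizers, iterated to convergence. Deterministic.
#'
#' @param hm a \code{\link{haplotype_matrix}} with >= 4 haplotypes and >= 1
#'   segregating site.
#' @return list with \code{assignment} (1/2 per haplotype), \code{score}
#'   (mean silhouette width over haplotypes), \code{medoids}.
#' @export
partition_core_haplogroups <- function(hm) {
  H <- nrow(hm$alleles)
  if (H < 4) stop("need at least 4 haplotypes")
  d <- hamming_counts(hm$alleles)$mismatch
  if (max(d) == 0) stop("degenerate partition: all haplotypes identical")
  w <- which(d == max(d), arr.ind = TRUE)
  w <- w[w[, 1] < w[, 2], , drop = FALSE]
  med <- as.integer(w[order(w[, 1], w[, 2])[1], ])
  assign_to <- function(med) {
    a <- ifelse(d[, med[1]] <= d[, med[2]], 1L, 2L)
    a[med[1]] <- 1L; a[med[2]] <- 2L
    a
  }
  best_medoid <- function(members) {
    tot <- rowSums(d[members, members, drop = FALSE])
    members[which.min(tot)]     # which.min takes the first = lowest index
  }
  asn <- assign_to(med)
  for (it in 1:100) {
    new_med <- c(best_medoid(which(asn == 1L)), best_medoid(which(asn == 2L)))
    new_asn <- assign_to(new_med)
    if (identical(new_asn, asn) && identical(new_med, med)) break
    med <- new_med; asn <- new_asn
  }
  sil <- vapply(seq_len(H), function(i) {
    own <- which(asn == asn[i] & seq_len(H) != i)
    oth <- which(asn != asn[i])
    if (length(own) == 0) return(0)
    a <- mean(d[i, own]); b <- mean(d[i, oth])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  list(assignment = asn, score = mean(sil), medoids = med)
}

#' Fixed differences between two haplotype groups
#'
#' A site counts iff every non-missing allele in group 1 differs from every
#' non-missing allele in group 2 (each group internally fixed, for opposite
#' alleles). Sites with no called allele in one group are excluded with a
#' logged count.
#'
#' @param hm a \code{\link{haplotype_matrix}}.
#' @param assignment vector of group codes (two distinct values) per
#'   haplotype.
#' @return list with \code{count} and \code{positions}.
#' @export
fixed_differences <- function(hm, assignment) {
  g <- unique(assignment)
  if (length(g) != 2) stop("assignment must define exactly two groups")
  A <- hm$alleles[assignment == g[1], , drop = FALSE]
  B <- hm$alleles[assignment == g[2], , drop = FALSE]
  if (nrow(A) == 0 || nrow(B) == 0) stop("both groups must be non-empty")
  rng <- function(m) {
    lo <- suppressWarnings(apply(m, 2, min, na.rm = TRUE))
    hi <- suppressWarnings(apply(m, 2, max, na.rm = TRUE))
    cbind(lo, hi)
  }
  ra <- rng(A); rb <- rng(B)
  uncalled <- !is.finite(ra[, 1]) | !is.finite(rb[, 1])
  if (any(uncalled))
    message(sum(uncalled), " site(s) uncalled in one group excluded")
  fixed <- !uncalled & ra[, 1] == ra[, 2] & rb[, 1] == rb[, 2] &
    ra[, 1] != rb[, 1]
  list(count = sum(fixed), positions = hm$positions[fixed])
}

#' Pairwise distance matrix between haplotypes
#'
#' Mismatch counts under pairwise deletion of missing data, optionally
#' normalized per variable site: the matrix's sites are the variable
#' (segregating) sites of the sample, so the p-distance divides each pair's
#' mismatch count by the number of those sites called in both haplotypes.
#'
#' @param hm a \code{\link{haplotype_matrix}}.
#' @param metric \code{"p_distance_per_variable_site"} (default) or
#'   \code{"raw_differences"}.
#' @return square symmetric matrix with haplotype labels and attribute
#'   \code{"metric"}.
#' @export
p_distance_matrix <- function(hm,
                              metric = c("p_distance_per_variable_site",
                                         "raw_differences")) {
  metric <- match.arg(metric)
  if (nrow(hm$alleles) < 2) stop("need at least 2 haplotypes")
  a <- hm$alleles
  if (metric == "p_distance_per_variable_site" && ncol(a) == 0)
    stop("no variable site: p-distance undefined")
  hc <- hamming_counts(a)
  d <- if (metric == "raw_differences") hc$mismatch
       else hc$mismatch / hc$valid
  dimnames(d) <- list(hm$sample_ids, hm$sample_ids)
  attr(d, "metric") <- metric
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimizing
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j} (ties broken by lexicographic
#' label order), with branch lengths from the standard two-point formulas and
#' a final three-way join closing the unrooted tree. Negative branch-length
#' estimates are clamped to zero with the deficit moved to the sister branch
#' and the tree flagged.
#'
#' @param dm square symmetric distance matrix with unique row/column labels.
#' @return an unrooted \code{ape} \code{"phylo"} tree; attribute
#'   \code{"negative_branches"} reports how many lengths were clamped.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nwk <- labels                      # newick fragment per active cluster
  key <- labels                      # lexicographic tie-break key
  D <- unname(dm)
  n_clamped <- 0L
  fmt <- function(x) sprintf("%.17g", x)
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ckey <- paste(pmin(key[cand[, 1]], key[cand[, 2]]),
                  pmax(key[cand[, 1]], key[cand[, 2]]))
    pick <- cand[order(ckey)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0; n_clamped <- n_clamped + 1L }
    if (vj < 0) { vi <- vi + vj; vj <- 0; n_clamped <- n_clamped + 1L }
    new_nwk <- paste0("(", nwk[i], ":", fmt(vi), ",", nwk[j], ":",
                      fmt(vj), ")")
    new_key <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keepv <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keepv, keepv, drop = FALSE], dnew[keepv]),
               c(dnew[keepv], 0))
    nwk <- c(nwk[keepv], new_nwk)
    key <- c(key[keepv], new_key)
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c("va", "vb", "vc")) if (get(v) < 0) {
    assign(v, 0); n_clamped <- n_clamped + 1L
  }
  tree <- ape::read.tree(text = paste0(
    "(", nwk[1], ":", fmt(va), ",", nwk[2], ":", fmt(vb), ",", nwk[3], ":",
    fmt(vc), ");"))
  attr(tree, "negative_branches") <- n_clamped
  tree
}

#' Is a leaf set monophyletic with respect to an outgroup?
#'
#' Roots the tree at the outgroup leaf and asks whether \code{leaf_set} is
#' exactly the leaf set of one clade.
#'
#' @param tree an \code{ape} \code{"phylo"} tree.
#' @param leaf_set character vector of tip labels (must exclude the
#'   outgroup).
#' @param outgroup_leaf tip label used to root.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
is_monophyletic <- function(tree, leaf_set, outgroup_leaf) {
  tips <- tree$tip.label
  unknown <- setdiff(c(leaf_set, outgroup_leaf), tips)
  if (length(unknown)) stop("unknown leaf: ", unknown[1])
  if (length(leaf_set) == 0) stop("empty leaf set")
  if (outgroup_leaf %in% leaf_set)
    stop("leaf set must not contain the outgroup")
  if (length(leaf_set) == 1) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup_leaf, resolve.root = TRUE)
  ape::is.monophyletic(rooted, leaf_set)
}

#' Per-locus mutation rate from interspecies divergence
#'
#' \eqn{\mu = \mathrm{substitutions} / (2T)}: substitutions accumulate along
#' both lineages since the species split, so the per-lineage per-year rate
#' divides the count by twice the divergence time. The alternative literal
#' reading (multiply by two rather than divide) is exposed via
#' \code{reading = "times_two"}. When \code{time_halfwidth} is given (e.g.
#' a 5 +/- 1 My calibration) the propagated rate interval is reported.
#'
#' @param substitutions substitutions between the species over the locus.
#' @param divergence_time_years species divergence time T in years.
#' @param time_halfwidth half-width of the T uncertainty, years.
#' @param reading \code{"two_t"} (default, divide by 2T) or
#'   \code{"times_two"}.
#' @return list with \code{mu} (per locus per year) and \code{mu_interval}.
#' @export
estimate_mu <- function(substitutions, divergence_time_years,
                        time_halfwidth = 0,
                        reading = c("two_t", "times_two")) {
  reading <- match.arg(reading)
  stopifnot(substitutions >= 0)
  if (divergence_time_years <= 0) stop("divergence time must be positive")
  f <- function(T) if (reading == "two_t") substitutions / (2 * T)
                   else 2 * substitutions / T
  lo <- divergence_time_years + time_halfwidth
  hi <- max(divergence_time_years - time_halfwidth, .Machine$double.eps)
  list(mu = f(divergence_time_years), mu_interval = c(f(lo), f(hi)))
}

#' Mutation counts of each haplotype from the reconstructed MRCA
#'
#' The MRCA allele at each polarizable site is the ancestral (outgroup)
#' state; sites the outgroup cannot polarize fall back to the locus-wide
#' majority allele for the reconstructed sequence but are flagged and
#' excluded from the counts. \eqn{x_i} is the Hamming distance of haplotype i
#' to the MRCA over polarized sites.
#'
#' @param hm a \code{\link{haplotype_matrix}} with ref/alt bases.
#' @param outgroup_alleles per-site outgroup base.
#' @return list with \code{x} (per-haplotype counts), \code{n_polarized},
#'   \code{n_flagged}, \code{mrca} (allele codes of the reconstruction).
#' @export
mutations_from_mrca <- function(hm, outgroup_alleles) {
  pol <- polarize_with_outgroup(hm, outgroup_alleles)
  ok <- pol$polarized
  if (!any(ok)) stop("no polarizable site")
  maj <- round(colMeans(hm$alleles, na.rm = TRUE))
  mrca <- ifelse(ok, 0L, as.integer(maj))       # 0 = ancestral after recode
  a <- pol$alleles[, ok, drop = FALSE]
  x <- rowSums(a == 1L, na.rm = TRUE)
  names(x) <- hm$sample_ids
  list(x = x, n_polarized = sum(ok), n_flagged = sum(!ok), mrca = mrca)
}

#' Thomson moment estimator of the TMRCA
#'
#' \eqn{t = \sum_i x_i / (n \mu)} where \eqn{x_i} is the number of mutational
#' differences between sequence i and the MRCA, n the number of sequences and
#' \eqn{\mu} the per-locus per-year mutation rate. No equilibrium or
#' recombination assumptions. The standard error uses the Poisson
#' star-genealogy approximation \eqn{\sqrt{\sum x_i}/(n\mu)} and is
#' approximate under shared (stem) mutations.
#'
#' @param x per-sequence mutation counts from the MRCA.
#' @param mu per-locus per-year mutation rate (> 0).
#' @return object of class \code{"tmrca_estimate"}: \code{t}, \code{se},
#'   \code{n}, \code{mu}, \code{x}.
#' @export
thomson_tmrca <- function(x, mu) {
  if (length(x) == 0) stop("empty mutation-count vector")
  if (mu <= 0) stop("mu must be positive")
  n <- length(x)
  t <- sum(x) / (n * mu)
  structure(list(t = t, se = sqrt(sum(x)) / (n * mu), n = n, mu = mu, x = x),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("Thomson TMRCA: %.3g +/- %.2g years (n = %d, mu = %.3g /locus/yr)\n",
              x$t, x$se, x$n, x$mu))
  invisible(x)
}
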
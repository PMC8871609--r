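#' Phased haplotype matrix
#'
#' H haplotypes x S biallelic sites, coded 0/1 with \code{NA} for missing.
#' When a site is polarized, allele 1 is the derived state.
#'
#' @param alleles integer matrix (H x S) of 0/1/\code{NA}.
#' @param positions strictly increasing 0-based genomic positions, length S.
#' @param ref,alt optional per-site reference / alternate bases.
#' @param sample_ids optional H haplotype labels.
#' @param group_labels optional per-haplotype population or subspecies tag.
#' @param polarized logical per-site flag (derived-vs-ancestral known);
#'   recycled if scalar.
#' @return an object of class \code{"haplotype_matrix"}.
#' @export
haplotype_matrix <- function(alleles, positions, ref = NULL, alt = NULL,
                             sample_ids = NULL, group_labels = NULL,
                             polarized = FALSE) {
  alleles <- as.matrix(alleles)
  S <- ncol(alleles); H <- nrow(alleles)
  stopifnot(length(positions) == S)
  if (S > 1 && is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (!all(alleles %in% c(0L, 1L, NA)))
    stop("alleles must be 0, 1 or NA")
  if (S > 0 && any(colSums(!is.na(alleles)) == 0))
    stop("every site needs at least one non-missing allele")
  if (is.null(sample_ids)) sample_ids <- paste0("hap", seq_len(H))
  stopifnot(length(sample_ids) == H)
  if (!is.null(group_labels)) stopifnot(length(group_labels) == H)
  polarized <- rep_len(as.logical(polarized), S)
  dimnames(alleles) <- list(sample_ids, NULL)
  structure(list(alleles = alleles, positions = as.numeric(positions),
                 ref = ref, alt = alt, sample_ids = sample_ids,
                 group_labels = group_labels, polarized = polarized),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("Haplotype matrix:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "sites\n")
  if (!is.null(x$group_labels))
    cat("  groups:", paste(names(table(x$group_labels)),
                           table(x$group_labels), sep = "=", collapse = " "),
        "\n")
  cat("  polarized sites:", sum(x$polarized), "/", length(x$polarized), "\n")
  invisible(x)
}

#' Diploid genotype table
#'
#' N individuals x S biallelic sites as alternate-allele dosages 0/1/2 with
#' \code{NA} for missing calls, plus a per-sample population label.
#'
#' @param genotypes integer matrix (N x S) of dosages.
#' @param positions 0-based genomic positions, length S.
#' @param sample_ids optional N labels.
#' @param population per-sample population label, length N.
#' @param ref,alt optional per-site bases.
#' @return an object of class \code{"genotype_table"}.
#' @export
genotype_table <- function(genotypes, positions, sample_ids = NULL,
                           population = NULL, ref = NULL, alt = NULL) {
  genotypes <- as.matrix(genotypes)
  S <- ncol(genotypes); N <- nrow(genotypes)
  stopifnot(length(positions) == S)
  if (S > 1 && is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(N))
  if (is.null(population)) population <- rep("pop1", N)
  stopifnot(length(sample_ids) == N, length(population) == N)
  dimnames(genotypes) <- list(sample_ids, NULL)
  structure(list(genotypes = genotypes, positions = as.numeric(positions),
                 sample_ids = sample_ids, population = population,
                 ref = ref, alt = alt),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "sites\n")
  cat("  populations:", paste(names(table(x$population)),
                              table(x$population), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Polarize alleles with an outgroup sequence
#'
#' Sites where the outgroup base matches one of the two observed alleles are
#' polarized (ancestral = outgroup state, allele 1 recoded to the derived
#' state). Sites where the outgroup carries a third base, or is missing, stay
#' unpolarized and untouched.
#'
#' @param hm a \code{haplotype_matrix} with \code{ref}/\code{alt} bases.
#' @param outgroup_alleles character vector of per-site outgroup bases
#'   (\code{NA} allowed).
#' @return the polarized \code{haplotype_matrix}; attribute \code{"flipped"}
#'   marks sites whose 0/1 codes were swapped.
#' @export
polarize_with_outgroup <- function(hm, outgroup_alleles) {
  stopifnot(inherits(hm, "haplotype_matrix"),
            length(outgroup_alleles) == ncol(hm$alleles))
  if (is.null(hm$ref) || is.null(hm$alt))
    stop("haplotype matrix carries no ref/alt bases to compare with")
  match_ref <- !is.na(outgroup_alleles) & outgroup_alleles == hm$ref
  match_alt <- !is.na(outgroup_alleles) & outgroup_alleles == hm$alt
  if (!any(match_ref | match_alt))
    stop("no site could be polarized against the outgroup")
  flip <- match_alt & !match_ref
  out <- hm
  if (any(flip)) out$alleles[, flip] <- 1L - out$alleles[, flip]
  out$polarized <- match_ref | match_alt
  attr(out, "flipped") <- flip
  out
}

n_haplotypes <- function(hm) nrow(hm$alleles)
n_sites <- function(x) {
  if (inherits(x, "haplotype_matrix")) ncol(x$alleles) else ncol(x$genotypes)
}
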
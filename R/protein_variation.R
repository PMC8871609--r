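#' Classify a coding SNP's effect on the protein
#'
#' Recomputes the codon from the gene model's coding offset, translates
#' reference and alternate codons, and classifies the variant as replacement
#' or silent. \code{glycine_flag} marks replacement variants whose
#' \emph{reference} residue is glycine (the mutated-glycine convention of
#' collagen clinical genetics); it is \code{NA} for silent variants.
#'
#' @param position 0-based genomic position; must be exonic and coding.
#' @param ref_base,alt_base single bases; \code{ref_base} must match the
#'   coding sequence.
#' @param model a \code{\link{gene_model}}.
#' @param coding_sequence the spliced coding sequence (one string, gene
#'   orientation).
#' @return list: \code{position}, \code{feature}, \code{variant_class},
#'   \code{residue}, \code{aa_from}, \code{aa_to}, \code{glycine_flag},
#'   \code{domain}.
#' @export
classify_aa_variant <- function(position, ref_base, alt_base, model,
                                coding_sequence) {
  loc <- locate_site(position, model)
  if (!grepl("^exon_", loc$feature))
    stop("position ", position, " is ", loc$feature,
         ": intronic variants are handled by the intron statistics")
  if (is.na(loc$residue))
    stop("position ", position, " is exonic but non-coding")
  idx <- (loc$residue - 1L) * 3L + loc$codon_pos
  if (substr(coding_sequence, idx, idx) != ref_base)
    stop("reference base mismatch with coding sequence at index ", idx)
  codon <- substr(coding_sequence, idx - loc$codon_pos + 1L,
                  idx - loc$codon_pos + 3L)
  alt_codon <- codon
  substr(alt_codon, loc$codon_pos, loc$codon_pos) <- alt_base
  aa_from <- seqinr::translate(strsplit(tolower(codon), "")[[1]])
  aa_to <- seqinr::translate(strsplit(tolower(alt_codon), "")[[1]])
  repl <- aa_from != aa_to
  list(position = position, feature = loc$feature,
       variant_class = if (repl) "replacement" else "silent",
       residue = loc$residue, aa_from = aa_from, aa_to = aa_to,
       glycine_flag = if (repl) aa_from == "G" else NA,
       domain = domain_of_residue(loc$residue, model))
}

#' Cross-tabulate variant records by group and attribute
#'
#' Builds the contingency tables behind the severity/domain and
#' severity/glycine contrasts. Rows are groups (severity categories, or any
#' label column), columns the chosen dimension; all declared levels are kept
#' even at zero count, and cells always sum to the record count.
#'
#' @param records data.frame of DAM records or variant annotations.
#' @param grouping column name for rows (default \code{"severity"}).
#' @param dimension \code{"domain"} or \code{"glycine_flag"}.
#' @param merge_groups optional named list collapsing row levels, e.g.
#'   \code{list(cat1 = 1, cat2_4 = 2:4)}.
#' @return object of class \code{"contingency_table"} wrapping the integer
#'   matrix.
#' @export
build_domain_contingency <- function(records, grouping = "severity",
                                     dimension = c("domain", "glycine_flag"),
                                     merge_groups = NULL) {
  dimension <- match.arg(dimension)
  if (nrow(records) == 0) stop("empty record set")
  if (!grouping %in% names(records)) stop("unknown grouping column: ", grouping)
  g <- records[[grouping]]
  if (!is.null(merge_groups)) {
    g2 <- rep(NA_character_, length(g))
    for (nm in names(merge_groups)) g2[g %in% merge_groups[[nm]]] <- nm
    keep <- !is.na(g2)
    records <- records[keep, , drop = FALSE]
    g <- factor(g2[keep], levels = names(merge_groups))
  } else g <- factor(g)
  v <- if (dimension == "domain")
    factor(records$domain, levels = c("N_terminal", "triple_helix",
                                      "C_terminal"))
  else factor(records$aa_from == "G", levels = c(TRUE, FALSE),
              labels = c("glycine", "other"))
  tab <- table(g, v)
  structure(list(table = unclass(as.matrix(tab)), grouping = grouping,
                 dimension = dimension, n = nrow(records)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency of", x$grouping, "x", x$dimension, "(n =", x$n, ")\n")
  print(x$table)
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing the hypergeometric probabilities of every table
#' with the observed margins whose probability does not exceed the observed
#' table's. The odds ratio reported is the sample cross-product ratio, with a
#' Haldane-Anscombe 0.5 correction only when a zero cell makes it undefined
#' (flagged).
#'
#' @param tab 2x2 matrix of non-negative integers with positive margins.
#' @return list with \code{odds_ratio}, \code{p_value}, \code{or_corrected}.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  p <- stats::fisher.test(tab)$p.value
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  list(odds_ratio = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]),
       p_value = p, or_corrected = corrected)
}

#' Pearson chi-square test for an r x c table
#'
#' Plain Pearson statistic (no continuity correction by default, matching how
#' collagen-domain contrasts are conventionally reported); a Yates-corrected
#' variant is available for 2x2 tables. A flag reports expected counts below
#' 5.
#'
#' @param tab r x c matrix of counts (r, c >= 2).
#' @param yates apply the continuity correction (2x2 only).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{low_expected}.
#' @export
chi_square_rxc <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("zero grand total")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, low_expected = any(ct$expected < 5))
}

#' Reading-frame effect of an exonic insertion
#'
#' An insertion is encodable in frame iff its length is divisible by 3 and
#' the flanking intron splice sites are intact; it then adds length/3
#' residues, otherwise it is a frameshift.
#'
#' @param insertion_length_nt insertion length in nucleotides (>= 0).
#' @param splice_sites_intact are the surrounding splice sites intact?
#' @return list with \code{in_frame}, \code{added_residues} (\code{NA} on
#'   frameshift), \code{frameshift}.
#' @export
exon_insertion_effect <- function(insertion_length_nt, splice_sites_intact) {
  if (insertion_length_nt < 0) stop("negative insertion length")
  in_frame <- (insertion_length_nt %% 3 == 0) && isTRUE(splice_sites_intact)
  list(in_frame = in_frame,
       added_residues = if (in_frame) insertion_length_nt %/% 3 else NA_integer_,
       frameshift = insertion_length_nt %% 3 != 0)
}
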
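#' Gene model for a multi-exon collagen-type locus
#'
#' Holds the exon/intron structure of the locus plus the residue ranges of the
#' three protein domains (N-propeptide, triple helix, C-propeptide). All
#' genomic coordinates are 0-based half-open; residue coordinates are 1-based.
#' Introns are always derived from the exon list, never stored independently.
#'
#' @param chrom chromosome / contig name.
#' @param strand \code{"+"} or \code{"-"}. Exon coordinates are given in the
#'   gene's own 5'->3' reading order, so residue arithmetic is
#'   strand-agnostic.
#' @param exon_starts,exon_ends integer vectors of equal length; sorted,
#'   non-overlapping 0-based half-open intervals.
#' @param domains named list with elements \code{N_terminal},
#'   \code{triple_helix}, \code{C_terminal}, each \code{c(first, last)}
#'   1-based residue bounds; must be contiguous, non-overlapping and jointly
#'   cover the protein.
#' @param coding_offset genomic position of the first coding base
#'   (defaults to the first exon base).
#' @return an object of class \code{"gene_model"}.
#' @export
gene_model <- function(chrom, strand, exon_starts, exon_ends, domains,
                       coding_offset = exon_starts[1]) {
  stopifnot(length(exon_starts) == length(exon_ends),
            all(exon_ends > exon_starts),
            strand %in% c("+", "-"))
  if (is.unsorted(exon_starts, strictly = TRUE))
    stop("exons must be sorted by start")
  if (any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    stop("exons must be disjoint")
  n <- length(exon_starts)
  if (n < 2) stop("a collagen-type model needs at least 2 exons")
  introns <- cbind(start = exon_ends[-n], end = exon_starts[-1])
  if (any(introns[, "end"] <= introns[, "start"]))
    stop("zero-length intron: adjacent exons must not touch")
  need <- c("N_terminal", "triple_helix", "C_terminal")
  if (!setequal(names(domains), need)) stop("domains must name exactly: ",
                                            paste(need, collapse = ", "))
  dom <- do.call(rbind, domains[need])
  if (any(dom[, 2] < dom[, 1])) stop("empty domain residue range")
  n_res <- sum(exon_ends - exon_starts) %/% 3L
  cover <- c(dom[1, 1] == 1L,
             dom[-1, 1] == dom[-3, 2] + 1L,
             dom[3, 2] >= n_res - 1L)  # allow a stop codon at the end
  if (!all(cover))
    stop("domain residue ranges must be contiguous and cover the protein")
  structure(list(chrom = chrom, strand = strand,
                 exons = cbind(start = as.integer(exon_starts),
                               end = as.integer(exon_ends)),
                 introns = introns,
                 domains = lapply(domains[need], as.integer),
                 coding_offset = as.integer(coding_offset)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model on ", x$chrom, " (", x$strand, " strand)\n", sep = "")
  cat("  ", nrow(x$exons), " exons / ", nrow(x$introns), " introns, locus ",
      x$exons[1, 1], "-", x$exons[nrow(x$exons), 2], "\n", sep = "")
  cat("  coding bases:", sum(exon_lengths(x)), " domains:",
      paste(sprintf("%s[%d-%d]", names(x$domains),
                    vapply(x$domains, `[`, 1L, 1),
                    vapply(x$domains, `[`, 1L, 2)), collapse = " "), "\n")
  invisible(x)
}

#' Exon and intron lengths of a gene model
#' @param model a \code{gene_model}.
#' @return integer vector of lengths in bp.
#' @export
exon_lengths <- function(model) unname(model$exons[, 2] - model$exons[, 1])

#' @rdname exon_lengths
#' @export
intron_lengths <- function(model) unname(model$introns[, 2] - model$introns[, 1])

#' Locus span of a gene model
#' @param model a \code{gene_model}.
#' @return \code{c(start, end)}, 0-based half-open.
#' @export
locus_span <- function(model)
  c(model$exons[1, 1], model$exons[nrow(model$exons), 2])

#' Map a genomic position onto the gene structure
#'
#' Partitions the locus: every base maps to exactly one \code{exon_i} or
#' \code{intron_j}. For coding exonic positions the 1-based residue number and
#' the within-codon position (1-3) are computed from \code{coding_offset}.
#'
#' @param position 0-based genomic position inside the locus span.
#' @param model a \code{gene_model}.
#' @return list with \code{feature} (e.g. \code{"intron_21"}), and for coding
#'   exonic positions \code{residue} and \code{codon_pos} (otherwise
#'   \code{NA}).
#' @export
locate_site <- function(position, model) {
  span <- locus_span(model)
  if (position < span[1] || position >= span[2])
    stop("position ", position, " outside locus span [",
         span[1], ",", span[2], ")")
  ex <- which(position >= model$exons[, 1] & position < model$exons[, 2])
  if (length(ex) == 1L) {
    res <- NA_integer_; cpos <- NA_integer_
    if (position >= model$coding_offset) {
      # coding index: exonic bases in [coding_offset, position]
      lo <- pmax(model$exons[, 1], model$coding_offset)
      full <- pmin(model$exons[, 2], position + 1L) - lo
      idx <- sum(pmax(full[seq_len(ex)], 0L))
      res <- (idx - 1L) %/% 3L + 1L
      cpos <- (idx - 1L) %% 3L + 1L
    }
    return(list(feature = paste0("exon_", ex), residue = res,
                codon_pos = cpos))
  }
  int <- which(position >= model$introns[, 1] & position < model$introns[, 2])
  list(feature = paste0("intron_", int), residue = NA_integer_,
       codon_pos = NA_integer_)
}

#' Protein domain containing a residue
#' @param residue 1-based residue number.
#' @param model a \code{gene_model}.
#' @return one of \code{"N_terminal"}, \code{"triple_helix"},
#'   \code{"C_terminal"}.
#' @export
domain_of_residue <- function(residue, model) {
  for (d in names(model$domains)) {
    r <- model$domains[[d]]
    if (residue >= r[1] && residue <= r[2]) return(d)
  }
  stop("residue ", residue, " outside all domain ranges")
}

#' Read / write a gene model as tab-separated text
#'
#' The format is a plain TSV of exon intervals (columns \code{feature},
#' \code{start}, \code{end}) preceded by \code{#key=value} header lines for
#' chrom, strand, coding offset and the three domain residue ranges.
#'
#' @param model a \code{gene_model}.
#' @param path file path.
#' @return \code{read_gene_model} returns a \code{gene_model};
#'   \code{write_gene_model} returns \code{path} invisibly.
#' @export
write_gene_model <- function(model, path) {
  hdr <- c(paste0("#chrom=", model$chrom),
           paste0("#strand=", model$strand),
           paste0("#coding_offset=", model$coding_offset),
           vapply(names(model$domains), function(d)
             sprintf("#domain_%s=%d-%d", d, model$domains[[d]][1],
                     model$domains[[d]][2]), ""))
  body <- sprintf("exon_%d\t%d\t%d", seq_len(nrow(model$exons)),
                  model$exons[, 1], model$exons[, 2])
  writeLines(c(hdr, "feature\tstart\tend", body), path)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", hdr)
  keys <- sub("=.*$", "", kv); vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  doms <- lapply(c("N_terminal", "triple_helix", "C_terminal"), function(d) {
    as.integer(strsplit(vals[[paste0("domain_", d)]], "-")[[1]])
  })
  names(doms) <- c("N_terminal", "triple_helix", "C_terminal")
  gene_model(chrom = vals[["chrom"]], strand = vals[["strand"]],
             exon_starts = tab$start, exon_ends = tab$end, domains = doms,
             coding_offset = as.integer(vals[["coding_offset"]]))
}
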
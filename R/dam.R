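#' Read a disease-associated-mutation (DAM) catalog
#'
#' TSV with header columns \code{residue}, \code{aa_from}, \code{aa_to},
#' \code{domain}, \code{severity} (clinical category 1 = mildest to
#' 4 = lethal) and \code{site_score} (conservation score at the underlying
#' nucleotide). Records with a severity outside 1-4 are dropped with a logged
#' count; severity categorization itself is consumed as input, never computed.
#'
#' @param path TSV file.
#' @return data.frame of class \code{"dam_table"} with the six columns above.
#' @export
read_dam_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "aa_from", "aa_to", "domain", "severity", "site_score")
  if (!all(need %in% names(tab)))
    stop("DAM table must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(tab$residue) | is.na(tab$severity) |
                 !nzchar(tab$aa_from) | !nzchar(tab$aa_to))
  if (length(bad))
    stop("malformed DAM row at line ", bad[1] + 1L)  # +1 for header
  same <- which(tab$aa_from == tab$aa_to)
  if (length(same))
    stop("aa_from equals aa_to at line ", same[1] + 1L)
  keep <- tab$severity %in% 1:4
  if (any(!keep))
    message(sum(!keep), " record(s) outside severity categories 1-4 dropped")
  out <- tab[keep, need, drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dam_table", "data.frame")
  out
}

#' Write a DAM catalog as TSV
#' @param dam a \code{dam_table} data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dam_table <- function(dam, path) {
  utils::write.table(dam, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
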
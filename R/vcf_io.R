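#' Read biallelic SNP genotypes from a VCF
#'
#' Thin wrapper around \code{vcfR} that keeps only biallelic SNP records
#' (single-base REF and ALT); multiallelic sites and indels are skipped with a
#' logged count. Positions are converted to 0-based. When every retained
#' record is fully phased (\code{|} separators) the phased haplotypes are
#' returned as well; a record mixing phased and unphased calls is treated as
#' unphased.
#'
#' @param path VCF 4.x file.
#' @param region optional \code{c(start, end)} 0-based half-open interval.
#' @param pop_map optional named character vector mapping sample id to
#'   population label.
#' @return list with \code{genotypes} (a \code{\link{genotype_table}}),
#'   \code{haplotypes} (a \code{\link{haplotype_matrix}} or \code{NULL}),
#'   and \code{n_skipped}.
#' @export
read_vcf <- function(path, region = NULL, pop_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos0 <- as.numeric(fix[, "POS"]) - 1
  keep <- nchar(fix[, "REF"]) == 1L & !is.na(fix[, "ALT"]) &
    nchar(fix[, "ALT"]) == 1L & !grepl(",", fix[, "ALT"]) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  if (!is.null(region)) keep <- keep & pos0 >= region[1] & pos0 < region[2]
  if (!any(keep)) stop("no biallelic SNP records retained",
                       if (!is.null(region)) " in the requested region")
  gt_raw <- v@gt[keep, -1, drop = FALSE]
  samples <- colnames(gt_raw)
  gt_field <- sub(":.*$", "", gt_raw)          # GT is mandated first
  pos0 <- pos0[keep]
  ord <- order(pos0)
  gt_field <- gt_field[ord, , drop = FALSE]
  pos0 <- pos0[ord]
  ref <- fix[keep, "REF"][ord]; alt <- fix[keep, "ALT"][ord]

  a1 <- substr(gt_field, 1, 1); a2 <- substr(gt_field, 3, 3)
  sep <- substr(gt_field, 2, 2)
  to_int <- function(a) { a[a == "."] <- NA; suppressWarnings(as.integer(a)) }
  d1 <- to_int(a1); d2 <- to_int(a2)
  dosage <- matrix(d1 + d2, nrow = nrow(gt_field))
  gt <- genotype_table(t(dosage), pos0, sample_ids = samples,
                       population = if (is.null(pop_map)) NULL
                                    else unname(pop_map[samples]),
                       ref = ref, alt = alt)
  rec_phased <- apply(sep == "|", 1, all)
  if (any(!rec_phased) && any(rec_phased))
    message(sum(!rec_phased), " record(s) with unphased calls; ",
            "treating the file as unphased")
  hm <- NULL
  if (all(rec_phased)) {
    H <- matrix(NA_integer_, nrow = 2 * length(samples), ncol = nrow(gt_field))
    H[seq(1, 2 * length(samples), 2), ] <- t(matrix(d1, nrow = nrow(gt_field)))
    H[seq(2, 2 * length(samples), 2), ] <- t(matrix(d2, nrow = nrow(gt_field)))
    hap_ids <- as.vector(rbind(paste0(samples, "_a"), paste0(samples, "_b")))
    grp <- if (is.null(pop_map)) NULL else rep(unname(pop_map[samples]), each = 2)
    hm <- haplotype_matrix(H, pos0, ref = ref, alt = alt,
                           sample_ids = hap_ids, group_labels = grp)
  }
  list(genotypes = gt, haplotypes = hm, n_skipped = n_skipped)
}

#' Write genotypes or haplotypes as a minimal VCF 4.2 file
#'
#' @param x a \code{\link{genotype_table}} or \code{\link{haplotype_matrix}}
#'   (haplotypes are written as phased diploid pairs, so H must be even).
#' @param path output file.
#' @param chrom chromosome name to write.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(x, path, chrom = "locus") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", chrom, ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (inherits(x, "haplotype_matrix")) {
    H <- nrow(x$alleles)
    if (H %% 2 != 0) stop("need an even number of haplotypes to write pairs")
    samples <- paste0("ind", seq_len(H / 2))
    a <- x$alleles
    a_chr <- ifelse(is.na(a), ".", a)
    gt <- matrix(paste(a_chr[seq(1, H, 2), , drop = FALSE],
                       a_chr[seq(2, H, 2), , drop = FALSE], sep = "|"),
                 nrow = H / 2)
    ref <- if (is.null(x$ref)) rep("A", ncol(a)) else x$ref
    alt <- if (is.null(x$alt)) rep("G", ncol(a)) else x$alt
    pos <- x$positions
  } else if (inherits(x, "genotype_table")) {
    samples <- x$sample_ids
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    g <- x$genotypes
    gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
    ok <- !is.na(g)
    gt[ok] <- code[as.character(g[ok])]
    ref <- if (is.null(x$ref)) rep("A", ncol(g)) else x$ref
    alt <- if (is.null(x$alt)) rep("G", ncol(g)) else x$alt
    pos <- x$positions
  } else stop("unsupported object")
  cols <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT", samples), collapse = "\t")
  body <- vapply(seq_along(pos), function(s)
    paste(c(chrom, format(pos[s] + 1, scientific = FALSE), ".", ref[s],
            alt[s], ".", "PASS", ".", "GT", gt[, s]), collapse = "\t"), "")
  writeLines(c(hdr, cols, body), path)
  invisible(path)
}
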
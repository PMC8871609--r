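# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Minimal line-by-line VCF parser: biallelic SNPs only, returns dosages,
# 0-based positions and per-haplotype alleles when phased.
ref_parse_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^##", lines)]
  hdr <- strsplit(body[1], "\t")[[1]]
  samples <- hdr[-(1:9)]
  recs <- strsplit(body[-1], "\t")
  keep <- vapply(recs, function(f)
    nchar(f[4]) == 1 && nchar(f[5]) == 1 && !grepl(",", f[5]) &&
      f[4] %in% c("A", "C", "G", "T") && f[5] %in% c("A", "C", "G", "T"),
    TRUE)
  recs <- recs[keep]
  pos <- vapply(recs, function(f) as.numeric(f[2]) - 1, 0)
  gts <- lapply(recs, function(f) sub(":.*", "", f[-(1:9)]))
  dos <- t(vapply(gts, function(g) {
    a1 <- suppressWarnings(as.integer(substr(g, 1, 1)))
    a2 <- suppressWarnings(as.integer(substr(g, 3, 3)))
    a1 + a2
  }, numeric(length(samples))))
  phased <- vapply(gts, function(g) all(substr(g, 2, 2) == "|"), TRUE)
  hap <- NULL
  if (all(phased)) {
    hap <- matrix(NA_integer_, 2 * length(samples), length(recs))
    for (s in seq_along(recs)) {
      g <- gts[[s]]
      hap[seq(1, nrow(hap), 2), s] <- suppressWarnings(as.integer(substr(g, 1, 1)))
      hap[seq(2, nrow(hap), 2), s] <- suppressWarnings(as.integer(substr(g, 3, 3)))
    }
  }
  list(dosage = matrix(dos, ncol = length(samples)), positions = pos,
       samples = samples, n_skipped = sum(!keep), hap = hap)
}

# Exhaustive two-sided Fisher p for a 2x2 table: sum hypergeometric
# probabilities of all margin-compatible tables not exceeding the observed
# table's probability (with the same relative tolerance fisher.test uses).
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random unrooted binary tree with positive branch lengths plus its exact
# path-length (cophenetic) matrix: the additivity oracle for NJ.
random_additive_case <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.3, 2.5))
  tr <- ape::unroot(tr)
  list(tree = tr, D = stats::cophenetic(tr))
}

# Brute-force pairwise mismatch/p-distance for a haplotype matrix.
ref_p_distance <- function(alleles, normalize) {
  a <- alleles
  H <- nrow(a)
  d <- matrix(0, H, H)
  for (i in seq_len(H)) for (j in seq_len(H)) {
    ok <- !is.na(a[i, ]) & !is.na(a[j, ])
    mm <- sum(a[i, ok] != a[j, ok])
    d[i, j] <- if (normalize) mm / sum(ok) else mm
  }
  d
}

# Genomic position of the base coding for (residue, codon_pos) in a model
# whose exons are fully coding: inverse of locate_site for tests.
coding_index_to_position <- function(idx, model) {
  elen <- colpopgen::exon_lengths(model)
  ends <- cumsum(elen)
  ex <- which(ends >= idx)[1]
  offset <- idx - c(0, ends)[ex] - 1
  model$exons[ex, 1] + offset
}

# Small phased fixture VCF with 3 biallelic SNPs, 1 indel and 2 samples,
# written through the synthetic generators plus one literal indel record.
write_fixture_vcf <- function(path, phased = TRUE) {
  sep <- if (phased) "|" else "/"
  gt <- function(a, b) paste0(a, sep, b)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=colgene>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    paste(c("colgene", "101", ".", "A", "G", ".", "PASS", ".", "GT",
            gt(0, 1), gt(1, 1)), collapse = "\t"),
    paste(c("colgene", "205", ".", "AT", "A", ".", "PASS", ".", "GT",
            gt(0, 0), gt(0, 1)), collapse = "\t"),   # indel, skipped
    paste(c("colgene", "300", ".", "C", "T", ".", "PASS", ".", "GT",
            gt(0, 0), gt(1, 0)), collapse = "\t"),
    paste(c("colgene", "412", ".", "G", "A", ".", "PASS", ".", "GT",
            gt(1, 0), gt(0, 0)), collapse = "\t"))
  writeLines(lines, path)
  path
}
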
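#' Per-base conservation track
#'
#' Stores one signed score per base over a genomic interval, with phyloP
#' semantics: scores are signed -log10 p-values against a neutral model,
#' positive = conservation (slower than neutral), negative = acceleration
#' (faster). Uncovered bases are \code{NA}.
#'
#' @param scores numeric vector, one value per base (\code{NA} = uncovered).
#' @param start 0-based genomic start of the first base.
#' @param chrom chromosome name.
#' @return an object of class \code{"conservation_track"}.
#' @export
conservation_track <- function(scores, start = 0, chrom = "locus") {
  if (any(!is.finite(scores) & !is.na(scores)))
    stop("scores must be finite or NA")
  structure(list(scores = as.numeric(scores), start = as.numeric(start),
                 chrom = chrom),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat("Conservation track ", x$chrom, ":", x$start, "-",
      x$start + length(x$scores), " (", sum(is.na(x$scores)),
      " uncovered bases)\n", sep = "")
  invisible(x)
}

#' Read a 4-column bedGraph into a per-base conservation track
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param region optional \code{c(start, end)} interval to expand over;
#'   defaults to the span of the file.
#' @return a \code{\link{conservation_track}} with uncovered bases \code{NA}.
#' @export
read_conservation_track <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           stringsAsFactors = FALSE)
  tab <- tab[order(tab$start), , drop = FALSE]
  if (nrow(tab) > 1) {
    ov <- which(tab$start[-1] < tab$end[-nrow(tab)])
    if (length(ov))
      stop(sprintf("overlapping bedGraph intervals: [%d,%d) and [%d,%d)",
                   tab$start[ov[1]], tab$end[ov[1]],
                   tab$start[ov[1] + 1], tab$end[ov[1] + 1]))
  }
  if (is.null(region)) region <- c(min(tab$start), max(tab$end))
  scores <- rep(NA_real_, region[2] - region[1])
  for (i in seq_len(nrow(tab))) {
    lo <- max(tab$start[i], region[1]); hi <- min(tab$end[i], region[2])
    if (hi > lo)
      scores[(lo - region[1] + 1):(hi - region[1])] <- tab$value[i]
  }
  conservation_track(scores, start = region[1], chrom = tab$chrom[1])
}

#' Write a conservation track as bedGraph (runs of equal value collapsed)
#' @param track a \code{\link{conservation_track}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  s <- track$scores
  covered <- !is.na(s)
  key <- ifelse(covered, s, NA)
  r <- rle(paste0(covered, "_", key))
  ends <- cumsum(r$lengths); starts <- c(0, ends[-length(ends)])
  keep <- !grepl("^FALSE", r$values)
  vals <- s[starts[keep] + 1]
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom,
                     as.integer(track$start + starts[keep]),
                     as.integer(track$start + ends[keep]),
                     format(vals, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' Extract per-base scores over an interval
#' @param track a \code{\link{conservation_track}}.
#' @param interval \code{c(start, end)}, 0-based half-open genomic.
#' @return numeric vector of scores (\code{NA} where uncovered).
#' @export
track_scores <- function(track, interval) {
  lo <- interval[1] - track$start; hi <- interval[2] - track$start
  if (lo < 0 || hi > length(track$scores))
    stop("interval outside track span")
  track$scores[(lo + 1):hi]
}
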
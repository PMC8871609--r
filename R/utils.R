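#' Permutation test result
#'
#' Uniform container returned by every randomization test in the package.
#' The achieved p-value always uses the add-one convention
#' \code{p = (n_as_extreme + 1) / (n_perm + 1)}, so it is strictly positive
#' and never understates significance relative to the Monte-Carlo resolution.
#'
#' @param observed observed value of the test statistic.
#' @param n_perm number of random permutations drawn.
#' @param n_as_extreme number of permuted statistics at least as extreme as
#'   the observed one (in the direction(s) given by \code{sidedness}).
#' @param p_value achieved p-value.
#' @param seed integer seed used for the permutation stream.
#' @param sidedness one of \code{"greater"}, \code{"less"}, \code{"two.sided"}.
#' @param extra optional named list of test-specific fields.
#' @return an object of class \code{"perm_result"}.
#' @export
perm_result <- function(observed, n_perm, n_as_extreme, p_value, seed,
                        sidedness, extra = list()) {
  stopifnot(p_value > 0, p_value <= 1, n_as_extreme >= 0, n_perm >= 1)
  structure(
    c(list(observed = observed, n_perm = as.integer(n_perm),
           n_as_extreme = as.integer(n_as_extreme), p_value = p_value,
           seed = as.integer(seed), sidedness = sidedness), extra),
    class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Permutation test (", x$sidedness, ")\n", sep = "")
  cat("  observed statistic:", format(x$observed), "\n")
  cat("  permutations:      ", x$n_perm, " (seed ", x$seed, ")\n", sep = "")
  cat("  p-value:           ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Derive a stage seed from a top-level seed
#'
#' Maps (seed, label) to a reproducible 31-bit integer so that every pipeline
#' stage gets its own independent stream and adding a stage never perturbs the
#' randomness of the others.
#'
#' @param seed top-level integer seed.
#' @param label character stage label.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 69069 + h * 10007) %% 2147483587L) + 1L
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  code
}
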
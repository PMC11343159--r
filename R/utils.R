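# Internal helpers: seeding, edge bookkeeping, small numeric utilities.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the given seed, evaluates `expr`, and restores the caller's RNG
#' state, so that package functions are reproducible without clobbering the
#' session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its stream from the master
#' seed and a stage key, so reruns of one stage reproduce the monolithic
#' run. The derivation hashes the key characters into a 31-bit integer.
#'
#' @param master integer master seed.
#' @param key character stage key, e.g. `"permutation"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' deriveSeed(1L, "permutation")
deriveSeed <- function(master, key) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## edge bookkeeping -----------------------------------------------------------

#' Enumerate the unique edges of a parcellation
#'
#' Edges are the strict lower triangle of the parcel x parcel matrix in
#' column-major order: edge (i, j) with i > j. This fixed order is the
#' vectorization convention used for all FC matrices in the package.
#'
#' @param parc a [Parcellation-class].
#' @return data.frame with columns `i`, `j` (parcel indices, `i > j`),
#'   `label` ("parcelA-parcelB"), and `block` (unordered network pair
#'   "a-b", a <= b).
#' @export
edgeInfo <- function(parc) {
  n <- length(parc)
  j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(col) (col + 1L):n),
              use.names = FALSE)
  net <- networks(parc)
  a <- pmin(net[i], net[j]); b <- pmax(net[i], net[j])
  data.frame(
    i = i, j = j,
    label = paste0(parcelIds(parc)[j], "-", parcelIds(parc)[i]),
    block = paste0(a, "-", b),
    stringsAsFactors = FALSE
  )
}

#' Number of unique connections of a parcellation
#'
#' @param parc a [Parcellation-class].
#' @return the lower-triangle edge count `n * (n - 1) / 2`.
#' @export
edgeCount <- function(parc) {
  n <- length(parc)
  n * (n - 1L) / 2
}

# Rebuild a symmetric unit-diagonal parcel matrix from an edge vector.
edgesToMatrix <- function(edges, parc) {
  n <- length(parc)
  M <- diag(1, n)
  M[lower.tri(M)] <- edges
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  dimnames(M) <- list(parcelIds(parc), parcelIds(parc))
  M
}

# z-score columns, tolerating zero-variance columns (used inside bootstrap
# draws, where resampling can flatten a rare ordinal item).
zscoreSafe <- function(M) {
  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  s[s == 0] <- Inf
  sweep(sweep(M, 2, mu, "-"), 2, s, "/")
}

# Stop unless x is a numeric matrix with finite entries.
checkFiniteMatrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (any(!is.finite(x)))
    stop(what, " contains non-finite entries")
  invisible(x)
}
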
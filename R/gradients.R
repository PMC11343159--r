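# Connectivity gradients: group-mean FC, row thresholding, cosine
# affinity, diffusion map embedding, and Procrustes alignment.

#' Group-mean cortical FC matrix
#'
#' Element-wise mean over participants of the per-participant FC,
#' restricted to cortical parcels; symmetric with unit diagonal.
#'
#' @param fc participants x edges matrix of vectorized lower-triangle FC
#'   (canonical edge order of [edgeInfo()]), or a list of symmetric parcel
#'   matrices.
#' @param parc a [Parcellation-class].
#' @return cortical parcels x parcels symmetric matrix.
#' @export
groupMeanFC <- function(fc, parc) {
  if (is.list(fc)) {
    dims <- vapply(fc, function(m) dim(m), integer(2))
    if (any(dims != length(parc)))
      stop("FC matrix dimensions do not match the parcellation")
    for (m in fc)
      if (max(abs(m - t(m))) > 1e-8)
        stop("FC input is not symmetric")
    M <- Reduce("+", fc) / length(fc)
  } else {
    if (ncol(fc) != edgeCount(parc))
      stop("edge count does not match the parcellation")
    M <- edgesToMatrix(colMeans(fc), parc)
  }
  diag(M) <- 1
  ctx <- isCortical(parc)
  M[ctx, ctx, drop = FALSE]
}

#' Keep the strongest entries of each row
#'
#' Per row, retains the `ceiling(density * (n - 1))` largest off-diagonal
#' entries and zeroes the rest; values tied with the cutoff are all kept.
#' The diagonal is zeroed. The result is generally asymmetric; symmetry is
#' restored by the cosine affinity step.
#'
#' @param matrix square numeric matrix.
#' @param density fraction of off-diagonal entries to keep per row,
#'   in (0, 1].
#' @return thresholded matrix.
#' @export
rowThreshold <- function(matrix, density = 0.10) {
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  n <- nrow(matrix)
  keep <- ceiling(density * (n - 1))
  if (!is.finite(keep) || keep < 1)
    stop("row density ", density, " keeps no entries per row")
  out <- matrix
  diag(out) <- 0
  for (i in seq_len(n)) {
    row <- out[i, -i]
    cut <- sort(row, decreasing = TRUE)[keep]
    drop <- out[i, ] < cut
    drop[i] <- TRUE
    out[i, drop] <- 0
  }
  out
}

#' Cosine similarity affinity of connection profiles
#'
#' `A[i, j]` is the cosine of rows `i` and `j` of the thresholded
#' connectivity matrix. Negative cosines are clipped to zero so that the
#' diffusion operator is a valid Markov matrix (rare after top-10%
#' thresholding), the matrix is symmetrized as `(A + t(A)) / 2` to guard
#' numerics, and the diagonal is zeroed for the Markov construction.
#'
#' @param matrix thresholded connectivity matrix (no all-zero rows).
#' @return symmetric non-negative affinity with zero diagonal.
#' @export
cosineAffinity <- function(matrix) {
  nrm <- sqrt(rowSums(matrix^2))
  if (any(nrm == 0))
    stop("all-zero row(s) in thresholded matrix: ",
         paste(head(rownames(matrix)[nrm == 0], 5), collapse = ", "))
  A <- tcrossprod(matrix / nrm)
  A[A < 0] <- 0
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# Connected components of the graph A > 0 (simple BFS).
graphComponents <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(A[u, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion map embedding of an affinity matrix
#'
#' Implements the anisotropic diffusion operator: with degrees
#' `d = rowSums(A)`, the alpha-normalized kernel is
#' `W = A / (d^alpha d^alpha)`, and the Markov operator is the
#' row-normalization `P` of `W`. Eigenvectors are obtained through the
#' symmetric conjugate of `P`; the trivial constant eigenvector
#' (eigenvalue 1) is dropped, and components are ordered by descending
#' eigenvalue. With `diffusionTime = 0`, component `i` is scaled by
#' `lambda_i / (1 - lambda_i)` (the multi-scale convention); with
#' `diffusionTime = t > 0`, by `lambda_i^t`. The variance-explained
#' fraction of component `i` is `lambda_i / sum(lambda)` over retained
#' non-trivial eigenvalues.
#'
#' @param affinity symmetric non-negative affinity matrix describing a
#'   connected graph.
#' @param alpha density-normalization exponent in \[0, 1\] (default 0.5).
#' @param diffusionTime diffusion time `t` (default 0, multi-scale).
#' @param nComponents number of gradients to retain (default 10).
#' @return a [GradientSet-class].
#' @export
diffusionEmbedding <- function(affinity, alpha = 0.5, diffusionTime = 0,
                               nComponents = 10L) {
  if (nrow(affinity) != ncol(affinity))
    stop("affinity must be square")
  if (max(abs(affinity - t(affinity))) > 1e-10)
    stop("affinity must be symmetric")
  if (any(affinity < 0))
    stop("affinity must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  comp <- graphComponents(affinity)
  if (max(comp) > 1)
    stop("affinity graph is disconnected (", max(comp), " components)")
  n <- nrow(affinity)
  d <- rowSums(affinity)
  W <- affinity / outer(d^alpha, d^alpha)
  d2 <- rowSums(W)
  # symmetric conjugate S = D2^{-1/2} W D2^{-1/2} shares eigenvalues with
  # the Markov operator P = D2^{-1} W
  Sm <- W / outer(sqrt(d2), sqrt(d2))
  eig <- eigen((Sm + t(Sm)) / 2, symmetric = TRUE)
  lam <- eig$values
  phi <- eig$vectors / sqrt(d2)        # right eigenvectors of P
  # normalize against the trivial constant eigenvector
  psi <- phi / phi[, 1]
  keep <- seq(2L, min(n, nComponents + 1L))
  lamK <- lam[keep]
  scaling <- if (diffusionTime == 0) lamK / (1 - lamK) else lamK^diffusionTime
  emb <- sweep(psi[, keep, drop = FALSE], 2, scaling, "*")
  rownames(emb) <- rownames(affinity)
  colnames(emb) <- sprintf("G%d", seq_along(keep))
  new("GradientSet", embedding = emb, eigenvalues = lamK,
      varianceExplained = lamK / sum(lamK),
      alignment = diag(length(keep)))
}

#' Procrustes-align gradients to a reference
#'
#' Finds the orthogonal transform (rotation/reflection, no scaling)
#' minimizing the Frobenius distance between the embedding and a
#' reference gradient set, via the SVD of their cross-product. The
#' transform is stored in the returned object; the unaligned variant is
#' simply the input.
#'
#' @param gradients a [GradientSet-class].
#' @param reference parcels x k reference matrix (same parcel count and
#'   `k` as the embedding).
#' @return a [GradientSet-class] with rotated embedding and the transform
#'   in its `alignment` slot.
#' @export
procrustesAlign <- function(gradients, reference) {
  stopifnot(is(gradients, "GradientSet"))
  E <- gradients@embedding
  if (!all(dim(reference) == dim(E)))
    stop("reference dimensions (", nrow(reference), " x ", ncol(reference),
         ") do not match the embedding (", nrow(E), " x ", ncol(E), ")")
  sv <- svd(crossprod(E, reference))
  Q <- sv$u %*% t(sv$v)
  out <- gradients
  out@embedding <- E %*% Q
  dimnames(out@embedding) <- dimnames(E)
  out@alignment <- Q
  out
}
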
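# Per-modality PCA with a cumulative-variance truncation rule.
#
# Columns are mean-centered but not variance-scaled before the
# decomposition: the downstream PLS step z-scores the concatenated PCA
# scores, so scaling here would double-normalize while making the
# cumulative-variance rule depend on an arbitrary rescaling of each
# modality's native covariance.

#' Fit a truncated PCA to one modality
#'
#' Centers the columns, decomposes the covariance (via SVD of the centered
#' matrix), and retains `k` = the smallest number of components whose
#' cumulative explained-variance fraction reaches `threshold`. When the
#' eigenvalue at the cut is tied with the next one (within relative 1e-9),
#' the extra component is retained as well. Coefficient signs follow a
#' deterministic convention: each column's largest-magnitude entry is
#' positive.
#'
#' @param matrix participants x features numeric matrix (more than one
#'   row, finite entries).
#' @param threshold cumulative variance fraction in (0, 1].
#' @param modality label stored in the model.
#' @return list with `model` (a [PCAModel-class]) and `scores`
#'   (participants x k matrix, equal to centered data times coefficients).
#' @export
#' @examples
#' M <- matrix(rnorm(40), 10, 4)
#' fit <- fitPCA(M, 0.5)
#' fit$model
fitPCA <- function(matrix, threshold = 0.5, modality = "modality") {
  checkFiniteMatrix(matrix, "PCA input")
  if (nrow(matrix) < 2)
    stop("PCA needs more than one participant")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop("variance threshold must lie in (0, 1]")
  mu <- colMeans(matrix)
  Xc <- sweep(matrix, 2, mu, "-")
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  ev <- d^2 / (nrow(matrix) - 1)
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= threshold - 1e-12)[1]
  while (k < length(ev) && abs(ev[k + 1] - ev[k]) <= 1e-9 * ev[k])
    k <- k + 1L
  rot <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(col) sign(col[which.max(abs(col))]))
  rot <- sweep(rot, 2, flip, "*")
  rownames(rot) <- colnames(matrix)
  colnames(rot) <- sprintf("PC%d", seq_len(k))
  scores <- Xc %*% rot
  rownames(scores) <- rownames(matrix)
  model <- new("PCAModel", modality = modality, center = mu,
               rotation = rot, varFrac = frac[seq_len(k)],
               k = as.integer(k), threshold = threshold)
  list(model = model, scores = scores)
}

#' Project data onto a fitted PCA model
#'
#' Exact out-of-sample projection: `(matrix - center) %*% coefficients`.
#' On the training matrix this reproduces the fitted scores exactly, which
#' is what allows discovery-sample PCA coefficients to be applied verbatim
#' to replication data.
#'
#' @param model a [PCAModel-class].
#' @param matrix participants x features matrix whose feature labels match
#'   the model.
#' @return participants x k score matrix.
#' @export
projectPCA <- function(model, matrix) {
  stopifnot(is(model, "PCAModel"))
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  feats <- rownames(model@rotation)
  if (!is.null(feats) && !is.null(colnames(matrix))) {
    if (!identical(colnames(matrix), feats)) {
      off <- union(setdiff(colnames(matrix), feats),
                   setdiff(feats, colnames(matrix)))
      if (length(off))
        stop("feature labels do not match the PCA model: ",
             paste(head(off, 5), collapse = ", "))
      matrix <- matrix[, feats, drop = FALSE]
    }
  } else if (ncol(matrix) != nrow(model@rotation)) {
    stop("feature count does not match the PCA model")
  }
  scores <- sweep(matrix, 2, model@center, "-") %*% model@rotation
  rownames(scores) <- rownames(matrix)
  scores
}

#' Concatenate per-modality PCA scores into the PLS imaging block
#'
#' Binds score blocks horizontally in the declared modality order and
#' records which columns belong to which modality, as required by
#' [modalityImportance()].
#'
#' @param scoresList named list of participants x k_m score matrices.
#' @param order modality order (default: the canonical
#'   area, thickness, volume, fc).
#' @return list with `X` (the concatenated matrix) and `blockIndex`
#'   (named list of column index vectors).
#' @export
concatenateBlocks <- function(scoresList,
                              order = c("area", "thickness", "volume", "fc")) {
  order <- intersect(order, names(scoresList))
  if (!length(order))
    stop("no requested modality found in scoresList")
  scoresList <- scoresList[order]
  ref <- rownames(scoresList[[1]])
  for (m in order) {
    rn <- rownames(scoresList[[m]])
    if (nrow(scoresList[[m]]) != nrow(scoresList[[1]]) ||
        (!is.null(ref) && !is.null(rn) && !identical(rn, ref)))
      stop("participant rows of block '", m,
           "' are not aligned with block '", order[1], "'")
  }
  X <- do.call(cbind, scoresList)
  widths <- vapply(scoresList, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  blockIndex <- mapply(function(s, e) seq.int(s, e), starts, ends,
                       SIMPLIFY = FALSE)
  names(blockIndex) <- order
  colnames(X) <- unlist(mapply(function(m, w) sprintf("%s_PC%d", m, seq_len(w)),
                               order, widths, SIMPLIFY = FALSE))
  list(X = X, blockIndex = blockIndex)
}

#' Serialize a PCA model to JSON
#'
#' Stores means, coefficients, explained-variance fractions, `k` and the
#' threshold so replication runs can reuse the discovery decomposition.
#'
#' @param model a [PCAModel-class].
#' @param path output file.
#' @export
writePCAModel <- function(model, path) {
  jsonlite::write_json(
    list(modality = model@modality,
         center = model@center,
         features = rownames(model@rotation),
         coefficients = unname(apply(model@rotation, 2, as.numeric,
                                     simplify = FALSE)),
         varianceFractions = model@varFrac,
         k = model@k,
         threshold = model@threshold),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a PCA model written by [writePCAModel()]
#'
#' @param path JSON file.
#' @return a [PCAModel-class].
#' @export
readPCAModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- if (is.list(o$coefficients))
    do.call(cbind, lapply(o$coefficients, as.numeric))
  else t(as.matrix(o$coefficients))  # simplified to k x features
  rownames(rot) <- o$features
  colnames(rot) <- sprintf("PC%d", seq_len(ncol(rot)))
  new("PCAModel", modality = o$modality, center = as.numeric(o$center),
      rotation = rot, varFrac = as.numeric(o$varianceFractions),
      k = as.integer(o$k), threshold = as.numeric(o$threshold))
}
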
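# Core PLS correlation: z-scoring, cross-covariance SVD, composite
# scores, loadings, covariance explained, and modality importance.

#' Z-score matrix columns
#'
#' Columns are centered to mean 0 and scaled to standard deviation 1
#' (denominator n - 1). Zero-variance columns are an error here: degenerate
#' behavior items must be filtered upstream with [dropDegenerateItems()].
#'
#' @param matrix numeric matrix with at least two rows.
#' @return the z-scored matrix.
#' @export
#' @examples
#' zscoreColumns(matrix(1:3, 3, 1))
zscoreColumns <- function(matrix) {
  checkFiniteMatrix(matrix, "input")
  if (nrow(matrix) < 2) stop("z-scoring needs at least two rows")
  s <- apply(matrix, 2, sd)
  if (any(s == 0))
    stop("zero-variance column(s): ",
         paste(head(colnames(matrix)[s == 0], 5), collapse = ", "))
  sweep(sweep(matrix, 2, colMeans(matrix), "-"), 2, s, "/")
}

#' Fit the PLS correlation decomposition
#'
#' Forms the cross-covariance `R = t(Y) %*% X` of the z-scored behavior
#' and imaging blocks and takes its singular value decomposition
#' `R = U S t(V)`. Composite scores are the projections `LX = X V` and
#' `LY = Y U`. Each component's sign is fixed so that the column sum of
#' `U` is non-negative (ties broken by making the largest-magnitude entry
#' of `U` positive), so a component on which every item loads with the
#' same sign appears with positive loadings. `cor(LX[,l], LY[,l])` is
#' non-negative by construction since `cov(LY[,l], LX[,l]) = S[l] >= 0`.
#'
#' @param X participants x imaging-PCs z-scored matrix.
#' @param Y participants x items z-scored matrix, same rows as `X`.
#' @param blockIndex optional named list mapping modalities to columns of
#'   `X` (from [concatenateBlocks()]).
#' @return a [PLSModel-class] with all `min(ncol(Y), ncol(X))` components.
#' @export
fitPLS <- function(X, Y, blockIndex = list()) {
  checkFiniteMatrix(X, "X"); checkFiniteMatrix(Y, "Y")
  if (nrow(X) != nrow(Y))
    stop("X and Y have different numbers of rows")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    stop("X and Y rows are not aligned")
  R <- crossprod(Y, X)
  sv <- svd(R)
  U <- sv$u; V <- sv$v; S <- sv$d
  for (l in seq_along(S)) {
    cs <- sum(U[, l])
    flip <- if (cs != 0) sign(cs) else sign(U[which.max(abs(U[, l])), l])
    if (flip < 0) { U[, l] <- -U[, l]; V[, l] <- -V[, l] }
  }
  rownames(U) <- colnames(Y)
  rownames(V) <- colnames(X)
  LX <- X %*% V; LY <- Y %*% U
  cn <- sprintf("LC%d", seq_along(S))
  colnames(U) <- colnames(V) <- colnames(LX) <- colnames(LY) <- cn
  new("PLSModel", U = U, V = V, S = S, LX = LX, LY = LY,
      covexp = covarianceExplained(S), loadings = list(),
      blockIndex = blockIndex)
}

#' Covariance explained by each latent component
#'
#' The fraction for component `l` is its squared singular value divided by
#' the sum of all squared singular values.
#'
#' @param S non-negative singular values.
#' @return fractions summing to 1.
#' @export
#' @examples
#' covarianceExplained(c(2, 1)) # 0.8, 0.2
covarianceExplained <- function(S) {
  if (any(S < 0)) stop("singular values must be non-negative")
  tot <- sum(S^2)
  if (tot == 0) stop("all singular values are zero: degenerate decomposition")
  S^2 / tot
}

#' Compute loadings: correlations of original features with composite scores
#'
#' Behavioral loadings are Pearson correlations between each item column
#' and the behavioral composite scores `LY`; imaging loadings correlate
#' each original (pre-PCA, residualized) feature column with the imaging
#' composite scores `LX`. FC loadings are produced at the edge level.
#' Zero-variance features get `NA` loadings (with a warning) and are
#' excluded from downstream summaries.
#'
#' @param model a [PLSModel-class].
#' @param modalityData named list of residualized participants x features
#'   matrices (the original data entered into PCA).
#' @param Y items matrix (residualized) used for behavioral loadings.
#' @param nComponents number of components to correlate (default
#'   `min(5, length of S)`).
#' @return the model with its `loadings` slot filled (`behavior` plus one
#'   entry per imaging modality).
#' @export
computeLoadings <- function(model, modalityData, Y,
                            nComponents = min(5L, length(model@S))) {
  stopifnot(is(model, "PLSModel"))
  comps <- seq_len(nComponents)
  safeCor <- function(M, scores, what) {
    v <- apply(M, 2, var)
    out <- matrix(NA_real_, ncol(M), length(comps),
                  dimnames = list(colnames(M),
                                  colnames(scores)[comps]))
    if (any(v == 0))
      warning("zero-variance ", what, " feature(s) get NA loadings: ",
              paste(head(colnames(M)[v == 0], 5), collapse = ", "))
    ok <- v > 0
    out[ok, ] <- cor(M[, ok, drop = FALSE], scores[, comps, drop = FALSE])
    out
  }
  loadings <- list(behavior = safeCor(Y, model@LY, "behavior"))
  for (m in names(modalityData)) {
    if (nrow(modalityData[[m]]) != nrow(model@LX))
      stop("modality '", m, "' rows do not align with composite scores")
    loadings[[m]] <- safeCor(modalityData[[m]], model@LX, m)
  }
  model@loadings <- loadings
  validObject(model)
  model
}

#' Relative importance of each imaging modality per component
#'
#' For modality `m`, the imaging weights `V` are copied with every row
#' outside `m`'s block set to zero, and the importance is the Pearson
#' correlation between the full composite scores `X V` and the
#' modality-specific scores `X V_m`, per component.
#'
#' @param model a [PLSModel-class] with a non-empty `blockIndex`.
#' @param X the z-scored imaging block used to fit the model.
#' @param nComponents number of components (default `min(5, L)`).
#' @return modalities x components matrix of correlations.
#' @export
modalityImportance <- function(model, X,
                               nComponents = min(5L, length(model@S))) {
  stopifnot(is(model, "PLSModel"))
  if (!length(model@blockIndex))
    stop("model has no block index map")
  comps <- seq_len(nComponents)
  full <- X %*% model@V[, comps, drop = FALSE]
  out <- matrix(NA_real_, length(model@blockIndex), length(comps),
                dimnames = list(names(model@blockIndex),
                                colnames(model@V)[comps]))
  for (m in names(model@blockIndex)) {
    idx <- model@blockIndex[[m]]
    if (!length(idx)) stop("empty block for modality '", m, "'")
    Vm <- matrix(0, nrow(model@V), length(comps))
    Vm[idx, ] <- model@V[idx, comps, drop = FALSE]
    partial <- X %*% Vm
    out[m, ] <- diag(cor(full, partial))
  }
  out
}
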
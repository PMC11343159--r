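# Site-constrained inference: permutation significance of components,
# bootstrap stability of loadings (with 18-network block averaging for
# FC), and Benjamini-Hochberg FDR control.

#' Permute participants within acquisition sites
#'
#' Returns a permutation of `seq_along(sites)` that only exchanges rows
#' sharing a site label (the composition of independent per-site
#' permutations), drawn from the current RNG stream.
#'
#' @param sites site label per row.
#' @return integer permutation vector.
#' @export
#' @examples
#' set.seed(1); permuteWithinSites(c("a", "a", "b", "b", "b"))
permuteWithinSites <- function(sites) {
  idx <- seq_along(sites)
  for (s in unique(sites)) {
    pos <- which(sites == s)
    if (length(pos) > 1) idx[pos] <- pos[sample.int(length(pos))]
  }
  idx
}

#' Resample participants with replacement within sites
#'
#' Within each site, draws that site's participant count with replacement,
#' preserving per-site row counts exactly.
#'
#' @param sites site label per row.
#' @return integer index vector of the same length as `sites`.
#' @export
bootstrapWithinSites <- function(sites) {
  idx <- seq_along(sites)
  for (s in unique(sites)) {
    pos <- which(sites == s)
    idx[pos] <- pos[sample.int(length(pos), length(pos), replace = TRUE)]
  }
  idx
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up control of the false discovery rate at level `q`. `NA`
#' p-values (undefined loadings) are excluded from the family and mapped
#' to `FALSE`.
#'
#' @param p p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return logical rejection mask of the same length.
#' @export
#' @examples
#' fdrBH(c(0.01, 0.5), 0.05)
fdrBH <- function(p, q = 0.05) {
  if (!length(p)) return(logical(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  mask <- rep(FALSE, length(p))
  mask[ok] <- p.adjust(p[ok], method = "BH") <= q
  mask
}

#' Site-constrained permutation test of the latent components
#'
#' For each permutation, rows of the behavioral block are permuted within
#' site, the PLS is refitted, and the first `nComponents` singular values
#' are recorded. P-values use the add-one convention
#' `p = (1 + #\{null >= observed\}) / (1 + nPerm)`, giving a valid
#' finite-sample test with lower bound `1/(nPerm+1)`; the five component
#' p-values form one FDR family.
#'
#' @param X,Y z-scored imaging and behavior blocks.
#' @param sites site label per participant.
#' @param nPerm number of permutations (paper-scale default 10000).
#' @param nComponents number of leading components tested (default 5).
#' @param q FDR level.
#' @param seed optional integer seed.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(X, Y, sites, nPerm = 10000L,
                            nComponents = 5L, q = 0.05, seed = NULL) {
  if (nPerm < 1) stop("nPerm must be at least 1")
  nComponents <- min(nComponents, ncol(X), ncol(Y))
  obs <- svd(crossprod(Y, X), nu = 0, nv = 0)$d[seq_len(nComponents)]
  nullS <- matrix(NA_real_, nPerm, nComponents)
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      idx <- permuteWithinSites(sites)
      nullS[b, ] <- svd(crossprod(Y[idx, , drop = FALSE], X),
                        nu = 0, nv = 0)$d[seq_len(nComponents)]
    }
  })
  pv <- vapply(seq_len(nComponents), function(l)
    (1 + sum(nullS[, l] >= obs[l])) / (1 + nPerm), numeric(1))
  new("PermutationResult", observedS = obs, nullS = nullS,
      pValues = pv, fdrMask = fdrBH(pv, q), nPerm = as.integer(nPerm),
      seed = as.integer(if (is.null(seed)) NA else seed))
}

#' Average FC edge values within and between networks
#'
#' Reduces edge-level values to one mean per unordered network pair
#' (including within-network diagonal blocks): `K` networks yield
#' `K (K + 1) / 2` blocks. Used to limit multiple comparisons before
#' bootstrap z-scoring of FC loadings.
#'
#' @param edgeValues numeric vector or edges x L matrix; rownames (or
#'   names), when present, must be "parcelA-parcelB" edge labels of the
#'   parcellation.
#' @param parc a [Parcellation-class].
#' @return blocks x L matrix with "a-b" network-pair rownames.
#' @export
blockAverageFC <- function(edgeValues, parc) {
  if (is.null(dim(edgeValues)))
    edgeValues <- matrix(edgeValues, ncol = 1,
                         dimnames = list(names(edgeValues), NULL))
  einfo <- edgeInfo(parc)
  lab <- rownames(edgeValues)
  if (!is.null(lab)) {
    pos <- match(lab, einfo$label)
    if (any(is.na(pos)))
      stop("edge label(s) not resolvable in the parcellation: ",
           paste(head(lab[is.na(pos)], 5), collapse = ", "))
    blocks <- einfo$block[pos]
  } else {
    if (nrow(edgeValues) != nrow(einfo))
      stop("edge count does not match the parcellation")
    blocks <- einfo$block
  }
  K <- nNetworks(parc)
  pairs <- outer(seq_len(K), seq_len(K), function(a, b)
    ifelse(a <= b, paste0(a, "-", b), NA))
  allBlocks <- sort(na.omit(as.vector(pairs)))
  allBlocks <- allBlocks[order(as.integer(sub("-.*", "", allBlocks)),
                               as.integer(sub(".*-", "", allBlocks)))]
  out <- matrix(NA_real_, length(allBlocks), ncol(edgeValues),
                dimnames = list(allBlocks, colnames(edgeValues)))
  for (l in seq_len(ncol(edgeValues))) {
    m <- tapply(edgeValues[, l], blocks, mean)
    out[names(m), l] <- m
  }
  out
}

# Greedy component matching of a bootstrap replicate to the original model:
# match by maximal |t(U_rep) U_orig|, then flip signs so the dot product is
# positive. Ambiguous matches (two |dot| within 1e-6) fall back to original
# order.
alignComponents <- function(Urep, Vrep, Uorig, nComponents) {
  D <- crossprod(Urep, Uorig)  # rep x orig
  ord <- integer(nComponents)
  sgn <- numeric(nComponents)
  free <- rep(TRUE, nrow(D))
  for (l in seq_len(nComponents)) {
    cand <- abs(D[, l]); cand[!free] <- -Inf
    best <- which.max(cand)
    runner <- max(cand[-best])
    if (is.finite(runner) && abs(cand[best] - runner) < 1e-6 && free[l])
      best <- l  # ambiguity: resolve by original order
    ord[l] <- best
    sgn[l] <- if (D[best, l] >= 0) 1 else -1
    free[best] <- FALSE
  }
  list(order = ord, sign = sgn)
}

#' Bootstrap stability of PLS loadings, accounting for site
#'
#' Per draw, participants are resampled with replacement within sites,
#' both blocks are re-z-scored, the PLS is refitted, each replicate
#' component is matched to the original by maximal absolute dot product of
#' behavioral weights (sign-aligned), and loadings are recomputed on the
#' resampled data. FC loadings are averaged into 18-network blocks before
#' the standard deviation is taken. The bootstrap z-score is the observed
#' (block-averaged where applicable) loading divided by its bootstrap SD;
#' two-sided normal p-values are FDR-corrected jointly across all features,
#' blocks and components of the run.
#'
#' @param X,Y un-z-scored imaging (concatenated PCA scores) and behavior
#'   blocks; z-scoring happens inside each draw.
#' @param sites site label per participant.
#' @param modalityData named list of residualized original matrices used
#'   for loadings (e.g. `area`, `thickness`, `volume`, `fc`).
#' @param parc [Parcellation-class], required when `"fc"` (or any task FC
#'   block) is present.
#' @param nBoot number of draws (paper-scale default 1000).
#' @param nComponents components carried into inference (default 5).
#' @param q FDR level.
#' @param seed optional integer seed.
#' @return a [BootstrapResult-class].
#' @export
bootstrapLoadings <- function(X, Y, sites, modalityData, parc = NULL,
                              nBoot = 1000L, nComponents = 5L,
                              q = 0.05, seed = NULL) {
  if (nBoot < 2) stop("nBoot must be at least 2")
  nComponents <- min(nComponents, ncol(X), ncol(Y))
  fcLike <- intersect(names(modalityData),
                      c("fc", "taskMID", "taskENback", "taskSST"))
  if (length(fcLike) && is.null(parc))
    stop("a parcellation is required to block-average FC loadings")

  Xz <- zscoreColumns(X); Yz <- zscoreColumns(Y)
  orig <- fitPLS(Xz, Yz)
  obs <- list(behavior = cor(Y, orig@LY[, seq_len(nComponents), drop = FALSE]))
  for (m in names(modalityData))
    obs[[m]] <- cor(modalityData[[m]],
                    orig@LX[, seq_len(nComponents), drop = FALSE])
  for (m in fcLike) obs[[m]] <- blockAverageFC(obs[[m]], parc)

  draws <- lapply(obs, function(M)
    array(NA_real_, c(dim(M), nBoot), dimnames = c(dimnames(M), NULL)))
  corSafe <- function(M, scores) {
    s <- apply(M, 2, sd)
    out <- matrix(NA_real_, ncol(M), ncol(scores))
    ok <- s > 0
    out[ok, ] <- cor(M[, ok, drop = FALSE], scores)
    rownames(out) <- colnames(M)
    out
  }
  withSeed(seed, {
    for (b in seq_len(nBoot)) {
      idx <- bootstrapWithinSites(sites)
      Xb <- zscoreSafe(X[idx, , drop = FALSE])
      Yb <- zscoreSafe(Y[idx, , drop = FALSE])
      sv <- svd(crossprod(Yb, Xb))
      al <- alignComponents(sv$u, sv$v, orig@U, nComponents)
      Ub <- sweep(sv$u[, al$order, drop = FALSE], 2, al$sign, "*")
      Vb <- sweep(sv$v[, al$order, drop = FALSE], 2, al$sign, "*")
      LXb <- Xb %*% Vb; LYb <- Yb %*% Ub
      draws$behavior[, , b] <- corSafe(Y[idx, , drop = FALSE], LYb)
      for (m in names(modalityData)) {
        ld <- corSafe(modalityData[[m]][idx, , drop = FALSE], LXb)
        if (m %in% fcLike) ld <- blockAverageFC(ld, parc)
        draws[[m]][, , b] <- ld
      }
    }
  })
  sdL <- lapply(draws, function(a) apply(a, c(1, 2), sd, na.rm = TRUE))
  zL <- mapply(function(o, s) o / s, obs, sdL, SIMPLIFY = FALSE)
  pL <- lapply(zL, function(z) 2 * pnorm(-abs(z)))
  pAll <- unlist(pL, use.names = FALSE)
  maskAll <- fdrBH(pAll, q)
  maskL <- pL
  off <- 0
  for (m in names(pL)) {
    nm <- length(pL[[m]])
    maskL[[m]] <- matrix(maskAll[off + seq_len(nm)], nrow(pL[[m]]),
                         ncol(pL[[m]]), dimnames = dimnames(pL[[m]]))
    off <- off + nm
  }
  new("BootstrapResult", observed = obs, sd = sdL, z = zL,
      pValues = pL, fdrMask = maskL, nBoot = as.integer(nBoot),
      seed = as.integer(if (is.null(seed)) NA else seed))
}
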
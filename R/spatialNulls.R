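# Spin permutation nulls for spatially autocorrelated cortical maps, and
# the per-parcel within/between-network FC-loading profiles compared
# against gradients.

# Uniform (Haar) random rotation in SO(3) from the current RNG stream.
randomRotation <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(q)
  Q <- Q %*% diag(sign(diag(qr.R(q))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Build a spin-permutation null for cortical maps
#'
#' Per spin, one uniform random 3-D rotation is applied to the
#' left-hemisphere parcel centroids and its x-mirrored counterpart to the
#' right hemisphere; every parcel is then reassigned the value of the
#' nearest rotated source parcel (parcel-level nearest-neighbour scheme).
#' Duplicated sources are permitted, as usual for parcel-level spins.
#'
#' @param parc a [Parcellation-class] with unit cortical centroids.
#' @param nSpins number of rotations (paper-scale default 1000).
#' @param seed optional integer seed.
#' @return a [SpinNull-class] whose assignment indices refer to cortical
#'   parcels in parcellation order.
#' @export
buildSpinNull <- function(parc, nSpins = 1000L, seed = NULL) {
  ctx <- which(isCortical(parc))
  if (!length(ctx)) stop("parcellation has no cortical parcels")
  cent <- centroids(parc)[ctx, , drop = FALSE]
  if (any(!is.finite(cent)))
    stop("cortical parcels must have centroids")
  hemi <- hemispheres(parc)[ctx]
  mirror <- diag(c(-1, 1, 1))
  assignments <- matrix(NA_integer_, nSpins, length(ctx))
  withSeed(seed, {
    for (s in seq_len(nSpins)) {
      R <- randomRotation()
      Rright <- mirror %*% R %*% mirror
      for (h in c("left", "right")) {
        sel <- which(hemi == h)
        if (!length(sel)) next
        rot <- cent[sel, , drop = FALSE] %*%
          t(if (h == "left") R else Rright)
        # nearest rotated source parcel for each original position
        assignments[s, sel] <-
          sel[max.col(cent[sel, , drop = FALSE] %*% t(rot),
                      ties.method = "first")]
      }
    }
  })
  new("SpinNull", assignments = assignments, nSpins = as.integer(nSpins),
      seed = as.integer(if (is.null(seed)) NA else seed))
}

#' Correlate two cortical maps against a spin null
#'
#' The observed statistic is the Pearson correlation of the two maps; the
#' null distribution spins `mapA` (reassigning its values by the stored
#' rotations) against the fixed `mapB`, preserving the spatial
#' autocorrelation of the map under test. The two-sided p-value is
#' `(1 + #\{|r_null| >= |r_obs|\}) / (1 + nSpins)`.
#'
#' @param mapA,mapB numeric vectors on the same cortical parcels.
#' @param null a [SpinNull-class] built on that parcellation.
#' @param naRm drop parcels that are `NA` in either map (pairwise, per
#'   spin).
#' @return list with `r` (observed), `p` (spin p-value) and `nullR`.
#' @export
spinCorrelation <- function(mapA, mapB, null, naRm = FALSE) {
  stopifnot(is(null, "SpinNull"))
  if (length(mapA) != ncol(null@assignments) ||
      length(mapB) != ncol(null@assignments))
    stop("maps must live on the null's cortical parcels")
  use <- if (naRm) "pairwise.complete.obs" else "everything"
  if (var(mapA, na.rm = TRUE) == 0 || var(mapB, na.rm = TRUE) == 0)
    stop("constant map: correlation undefined")
  r <- cor(mapA, mapB, use = use)
  nullR <- apply(null@assignments, 1, function(idx)
    cor(mapA[idx], mapB, use = use))
  p <- (1 + sum(abs(nullR) >= abs(r), na.rm = TRUE)) / (1 + null@nSpins)
  list(r = r, p = p, nullR = nullR)
}

#' Per-parcel within- and between-network FC loading profiles
#'
#' For each cortical parcel, the within map averages the edge loadings
#' joining it to parcels of its own network, and the between map averages
#' the loadings joining it to parcels of other networks. A parcel whose
#' network is a singleton has no within-network edges; its within value is
#' `NA` and excluded downstream.
#'
#' @param edgeLoadings numeric vector (or edges x L matrix) in canonical
#'   edge order, or named by edge label.
#' @param parc a [Parcellation-class].
#' @return list of `within` and `between` (cortical parcels x L matrices).
#' @export
fcLoadingParcelProfiles <- function(edgeLoadings, parc) {
  if (is.null(dim(edgeLoadings)))
    edgeLoadings <- matrix(edgeLoadings, ncol = 1,
                           dimnames = list(names(edgeLoadings), NULL))
  einfo <- edgeInfo(parc)
  lab <- rownames(edgeLoadings)
  if (!is.null(lab)) {
    pos <- match(lab, einfo$label)
    if (any(is.na(pos)))
      stop("edge label(s) not resolvable: ",
           paste(head(lab[is.na(pos)], 5), collapse = ", "))
    einfo <- einfo[pos, ]
  } else if (nrow(edgeLoadings) != nrow(einfo)) {
    stop("edge count does not match the parcellation")
  }
  net <- networks(parc)
  sameNet <- net[einfo$i] == net[einfo$j]
  ctx <- which(isCortical(parc))
  L <- ncol(edgeLoadings)
  within <- between <- matrix(NA_real_, length(ctx), L,
                              dimnames = list(parcelIds(parc)[ctx],
                                              colnames(edgeLoadings)))
  for (pi in seq_along(ctx)) {
    p <- ctx[pi]
    touch <- einfo$i == p | einfo$j == p
    w <- touch & sameNet
    b <- touch & !sameNet
    if (any(w))
      within[pi, ] <- colMeans(edgeLoadings[w, , drop = FALSE])
    if (any(b))
      between[pi, ] <- colMeans(edgeLoadings[b, , drop = FALSE])
  }
  list(within = within, between = between)
}
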
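#' @import methods
#' @importFrom stats cor sd var qnorm pnorm rnorm quantile na.omit
#'   p.adjust t.test prcomp setNames model.matrix cor.test
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom tools md5sum
NULL

## ---------------------------------------------------------------------------
## Parcellation
## ---------------------------------------------------------------------------

#' Spherical parcellation with network assignments
#'
#' Describes a cortical + subcortical parcellation: one row per parcel, with a
#' hemisphere label, a unit-norm spherical centroid for cortical parcels
#' (`NA` for subcortical ones), and a network label in `1..nNetworks`.
#' Network labels of cortical parcels form contiguous spatial caps on the
#' sphere, so that parcel-wise maps carry spatial autocorrelation; all
#' subcortical parcels share the last network.
#'
#' @slot parcelId character vector of unique parcel identifiers.
#' @slot hemisphere one of `"left"`, `"right"`, `"subcortical"` per parcel.
#' @slot centroid numeric matrix (parcels x 3); unit rows for cortical
#'   parcels, `NA` rows for subcortical parcels.
#' @slot network integer network label per parcel.
#' @slot nNetworks total number of networks (the last one is subcortical).
#'
#' @export
setClass("Parcellation",
  representation(
    parcelId   = "character",
    hemisphere = "character",
    centroid   = "matrix",
    network    = "integer",
    nNetworks  = "integer"
  )
)

setValidity("Parcellation", function(object) {
  n <- length(object@parcelId)
  if (anyDuplicated(object@parcelId))
    return("parcel ids must be unique")
  if (length(object@hemisphere) != n || nrow(object@centroid) != n ||
      length(object@network) != n)
    return("slot lengths disagree")
  if (!all(object@hemisphere %in% c("left", "right", "subcortical")))
    return("hemisphere must be left/right/subcortical")
  ctx <- object@hemisphere != "subcortical"
  if (any(ctx)) {
    nrm <- sqrt(rowSums(object@centroid[ctx, , drop = FALSE]^2))
    if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 1e-6))
      return("cortical centroids must have unit norm")
  }
  if (any(object@network < 1L) || any(object@network > object@nNetworks))
    return("network labels must lie in 1..nNetworks")
  TRUE
})

#' @describeIn Parcellation number of parcels
#' @param x,object a `Parcellation`
#' @export
setMethod("length", "Parcellation", function(x) length(x@parcelId))

#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))
#' @describeIn Parcellation parcel identifiers
#' @export
setMethod("parcelIds", "Parcellation", function(x) x@parcelId)

#' @export
setGeneric("hemispheres", function(x) standardGeneric("hemispheres"))
#' @describeIn Parcellation hemisphere labels
#' @export
setMethod("hemispheres", "Parcellation", function(x) x@hemisphere)

#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @describeIn Parcellation parcel centroids (parcels x 3)
#' @export
setMethod("centroids", "Parcellation", function(x) x@centroid)

#' @export
setGeneric("networks", function(x) standardGeneric("networks"))
#' @describeIn Parcellation integer network assignment per parcel
#' @export
setMethod("networks", "Parcellation", function(x) x@network)

#' @export
setGeneric("nNetworks", function(x) standardGeneric("nNetworks"))
#' @describeIn Parcellation number of networks
#' @export
setMethod("nNetworks", "Parcellation", function(x) x@nNetworks)

#' @export
setGeneric("isCortical", function(x) standardGeneric("isCortical"))
#' @describeIn Parcellation logical mask of cortical parcels
#' @export
setMethod("isCortical", "Parcellation",
          function(x) x@hemisphere != "subcortical")

setMethod("show", "Parcellation", function(object) {
  nc <- sum(isCortical(object))
  cat("Parcellation:", length(object), "parcels (", nc, "cortical,",
      length(object) - nc, "subcortical ),", object@nNetworks, "networks\n")
})

## ---------------------------------------------------------------------------
## SynthConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic multimodal cohort generator
#'
#' Captures the study conditions emulated by [generateCohort()]: cohort and
#' parcellation sizes, the rank and strength of the planted latent
#' brain-behavior structure, confound effect sizes, and noise level.
#' Build with [synthConfig()].
#'
#' @slot nParticipants,nSites,nCorticalParcels,nSubcorticalParcels,nNetworks,nItems,nLatent,nConstantItems counts.
#' @slot latentStrengths positive, strictly descending strengths of the
#'   planted latent components.
#' @slot confoundEffects named numeric vector of covariate effect sizes.
#' @slot noiseSd residual noise standard deviation (FC edges use
#'   `0.1 * noiseSd` on the correlation scale).
#' @slot nTaskSets,nTracts held-out modality sizes.
#' @slot seed integer seed making all generator output reproducible.
#'
#' @export
setClass("SynthConfig",
  representation(
    nParticipants       = "integer",
    nSites              = "integer",
    nCorticalParcels    = "integer",
    nSubcorticalParcels = "integer",
    nNetworks           = "integer",
    nItems              = "integer",
    nLatent             = "integer",
    latentStrengths     = "numeric",
    confoundEffects     = "numeric",
    noiseSd             = "numeric",
    nConstantItems      = "integer",
    nTaskSets           = "integer",
    nTracts             = "integer",
    seed                = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  cnt <- c(object@nParticipants, object@nSites, object@nCorticalParcels,
           object@nSubcorticalParcels, object@nNetworks, object@nItems,
           object@nLatent)
  if (any(!is.finite(cnt)) || any(cnt < 1L))
    return("counts must be positive integers")
  if (object@nNetworks < 2L)
    return("nNetworks must be at least 2")
  if (object@nNetworks > object@nCorticalParcels + 1L)
    return("nNetworks must not exceed nCorticalParcels + 1")
  s <- object@latentStrengths
  if (length(s) != object@nLatent)
    return("latentStrengths must have length nLatent")
  if (any(!is.finite(s)))
    return("latentStrengths must be finite")
  if (!(all(s == 0) || (all(s > 0) && all(diff(s) < 0))))
    return("latentStrengths must be positive and strictly descending (or all zero for a null cohort)")
  if (!is.finite(object@noiseSd) || object@noiseSd <= 0)
    return("noiseSd must be a positive real")
  if (any(!is.finite(object@confoundEffects)))
    return("confoundEffects must be finite")
  if (object@nConstantItems < 0L || object@nConstantItems >= object@nItems)
    return("nConstantItems must be in [0, nItems)")
  TRUE
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig:", object@nParticipants, "participants,",
      object@nSites, "sites,",
      object@nCorticalParcels, "+", object@nSubcorticalParcels, "parcels,",
      object@nItems, "items,", object@nLatent, "latent components\n")
  cat("  latent strengths:", paste(object@latentStrengths, collapse = ", "),
      "| noise sd:", object@noiseSd, "| seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## SyntheticGroundTruth
## ---------------------------------------------------------------------------

#' Planted latent structure of a synthetic cohort
#'
#' Stores the loadings and factor scores planted by [generateCohort()],
#' enabling parameter-recovery tests: item loadings `B` (unit-norm columns),
#' per-modality structural loadings, edge-level connectivity loadings, and
#' the participant factor scores shared by all modalities.
#'
#' @slot itemLoadings items x nLatent matrix with unit-norm columns.
#' @slot structuralLoadings named list of parcels x nLatent matrices.
#' @slot edgeLoadings edges x nLatent matrix.
#' @slot factorScores participants x nLatent matrix.
#' @slot seed integer seed the cohort was generated under.
#'
#' @export
setClass("SyntheticGroundTruth",
  representation(
    itemLoadings       = "matrix",
    structuralLoadings = "list",
    edgeLoadings       = "matrix",
    factorScores       = "matrix",
    seed               = "integer"
  )
)

setValidity("SyntheticGroundTruth", function(object) {
  nrm <- sqrt(colSums(object@itemLoadings^2))
  if (any(abs(nrm - 1) > 1e-8))
    return("columns of itemLoadings must have unit norm")
  TRUE
})

setMethod("show", "SyntheticGroundTruth", function(object) {
  cat("SyntheticGroundTruth:", ncol(object@factorScores),
      "latent components,", nrow(object@factorScores), "participants\n")
})

## ---------------------------------------------------------------------------
## SynthCohort
## ---------------------------------------------------------------------------

#' A complete synthetic multimodal cohort
#'
#' Container returned by [generateCohort()]: covariates, ordinal behavior
#' items, per-modality feature matrices (structural parcels, vectorized FC
#' edges), held-out modalities sharing the same planted factors, the
#' parcellation, and the ground truth.
#'
#' @slot cohort data.frame of covariates, one row per participant.
#' @slot behavior participants x items integer matrix in \{0,1,2\}.
#' @slot modalities named list of participants x features matrices
#'   (`area`, `thickness`, `volume`, `fc`).
#' @slot heldout named list of held-out matrices (task FC sets, tract FA/MD).
#' @slot parcellation the [Parcellation-class].
#' @slot groundTruth the [SyntheticGroundTruth-class].
#' @slot config the [SynthConfig-class] used.
#'
#' @export
setClass("SynthCohort",
  representation(
    cohort       = "data.frame",
    behavior     = "matrix",
    modalities   = "list",
    heldout      = "list",
    parcellation = "Parcellation",
    groundTruth  = "SyntheticGroundTruth",
    config       = "SynthConfig"
  )
)

setValidity("SynthCohort", function(object) {
  n <- nrow(object@cohort)
  if (nrow(object@behavior) != n)
    return("behavior rows must match cohort rows")
  bad <- vapply(object@modalities, function(m) nrow(m) != n, logical(1))
  if (any(bad))
    return("modality rows must match cohort rows")
  TRUE
})

setMethod("show", "SynthCohort", function(object) {
  cat("SynthCohort:", nrow(object@cohort), "participants,",
      ncol(object@behavior), "behavior items\n")
  cat("  modalities:", paste(names(object@modalities), collapse = ", "), "\n")
  cat("  held-out:  ", paste(names(object@heldout), collapse = ", "), "\n")
  show(object@parcellation)
})

#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
#' @describeIn SynthCohort covariate table
#' @param x a `SynthCohort`
#' @export
setMethod("cohortTable", "SynthCohort", function(x) x@cohort)

#' @export
setGeneric("behaviorMatrix", function(x) standardGeneric("behaviorMatrix"))
#' @describeIn SynthCohort participants x items behavior matrix
#' @export
setMethod("behaviorMatrix", "SynthCohort", function(x) x@behavior)

#' @export
setGeneric("modalityMatrices", function(x) standardGeneric("modalityMatrices"))
#' @describeIn SynthCohort named list of modality matrices
#' @export
setMethod("modalityMatrices", "SynthCohort", function(x) x@modalities)

#' @export
setGeneric("heldoutMatrices", function(x) standardGeneric("heldoutMatrices"))
#' @describeIn SynthCohort named list of held-out modality matrices
#' @export
setMethod("heldoutMatrices", "SynthCohort", function(x) x@heldout)

#' @export
setGeneric("parcellation", function(x) standardGeneric("parcellation"))
#' @describeIn SynthCohort the parcellation
#' @export
setMethod("parcellation", "SynthCohort", function(x) x@parcellation)

#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @describeIn SynthCohort the planted ground truth
#' @export
setMethod("groundTruth", "SynthCohort", function(x) x@groundTruth)

## ---------------------------------------------------------------------------
## PCAModel
## ---------------------------------------------------------------------------

#' Per-modality PCA model with cumulative-variance truncation
#'
#' Principal component model of one imaging modality: feature means, the
#' orthonormal coefficient matrix, per-component explained-variance
#' fractions, and the number of components `k` retained as the smallest
#' count whose cumulative explained variance reaches `threshold`.
#'
#' @slot modality modality label.
#' @slot center feature means used for centering.
#' @slot rotation features x k orthonormal coefficient matrix.
#' @slot varFrac explained-variance fraction of each retained component.
#' @slot k number of retained components.
#' @slot threshold cumulative variance threshold in (0, 1].
#'
#' @export
setClass("PCAModel",
  representation(
    modality  = "character",
    center    = "numeric",
    rotation  = "matrix",
    varFrac   = "numeric",
    k         = "integer",
    threshold = "numeric"
  )
)

setValidity("PCAModel", function(object) {
  G <- crossprod(object@rotation)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    return("rotation columns must be orthonormal")
  if (object@threshold <= 0 || object@threshold > 1)
    return("threshold must lie in (0, 1]")
  TRUE
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel [", object@modality, "]: ", nrow(object@rotation),
      " features -> ", object@k, " components (threshold ",
      object@threshold, ")\n", sep = "")
})

## ---------------------------------------------------------------------------
## PLSModel
## ---------------------------------------------------------------------------

#' Partial least squares correlation model
#'
#' Result of the SVD of the behavior-by-imaging cross-covariance
#' `R = t(Y) %*% X`: behavioral weights `U`, imaging weights `V`, singular
#' values `S`, participant composite scores `LX = X V` and `LY = Y U`,
#' covariance-explained fractions, and (once computed) per-feature loadings.
#'
#' @slot U items x L behavioral weight matrix (orthonormal columns).
#' @slot V imaging-PCs x L imaging weight matrix (orthonormal columns).
#' @slot S non-negative descending singular values.
#' @slot LX,LY participants x L composite score matrices.
#' @slot covexp covariance-explained fraction per component (sums to 1).
#' @slot loadings named list of feature x component correlation matrices
#'   (filled by [computeLoadings()]).
#' @slot blockIndex named list mapping each modality to its columns of `X`.
#'
#' @export
setClass("PLSModel",
  representation(
    U          = "matrix",
    V          = "matrix",
    S          = "numeric",
    LX         = "matrix",
    LY         = "matrix",
    covexp     = "numeric",
    loadings   = "list",
    blockIndex = "list"
  )
)

setValidity("PLSModel", function(object) {
  if (max(abs(crossprod(object@U) - diag(ncol(object@U)))) > 1e-8)
    return("U must have orthonormal columns")
  if (max(abs(crossprod(object@V) - diag(ncol(object@V)))) > 1e-8)
    return("V must have orthonormal columns")
  if (any(object@S < -1e-12) || is.unsorted(rev(object@S)))
    return("singular values must be non-negative and descending")
  if (abs(sum(object@covexp) - 1) > 1e-10)
    return("covexp must sum to 1")
  ld <- unlist(object@loadings, use.names = FALSE)
  if (length(ld) && any(abs(ld) > 1 + 1e-8, na.rm = TRUE))
    return("loadings must lie in [-1, 1]")
  TRUE
})

setMethod("show", "PLSModel", function(object) {
  L <- length(object@S)
  cat("PLSModel:", nrow(object@U), "items x", nrow(object@V),
      "imaging components,", L, "latent components\n")
  k <- min(5L, L)
  cat("  covariance explained (first", k, "):",
      paste0(sprintf("%.1f", 100 * object@covexp[seq_len(k)]), "%",
             collapse = ", "), "\n")
})

#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))
#' @describeIn PLSModel singular values
#' @param x,object a `PLSModel`
#' @export
setMethod("singularValues", "PLSModel", function(x) x@S)

#' @export
setGeneric("covexp", function(x) standardGeneric("covexp"))
#' @describeIn PLSModel covariance-explained fractions
#' @export
setMethod("covexp", "PLSModel", function(x) x@covexp)

#' @export
setGeneric("behavioralWeights", function(x) standardGeneric("behavioralWeights"))
#' @describeIn PLSModel behavioral singular vectors U
#' @export
setMethod("behavioralWeights", "PLSModel", function(x) x@U)

#' @export
setGeneric("imagingWeights", function(x) standardGeneric("imagingWeights"))
#' @describeIn PLSModel imaging singular vectors V
#' @export
setMethod("imagingWeights", "PLSModel", function(x) x@V)

#' @export
setGeneric("compositeScores",
           function(x, side = c("imaging", "behavior"))
             standardGeneric("compositeScores"))
#' @describeIn PLSModel composite scores LX (imaging) or LY (behavior)
#' @param side `"imaging"` for LX or `"behavior"` for LY
#' @export
setMethod("compositeScores", "PLSModel", function(x, side = c("imaging", "behavior")) {
  side <- match.arg(side)
  if (side == "imaging") x@LX else x@LY
})

#' @export
setGeneric("plsLoadings", function(x, modality = NULL) standardGeneric("plsLoadings"))
#' @describeIn PLSModel loadings (all, or for one modality)
#' @param modality optional modality name
#' @export
setMethod("plsLoadings", "PLSModel", function(x, modality = NULL) {
  if (is.null(modality)) return(x@loadings)
  if (!modality %in% names(x@loadings))
    stop("no loadings stored for modality '", modality, "'")
  x@loadings[[modality]]
})

## ---------------------------------------------------------------------------
## Inference results
## ---------------------------------------------------------------------------

#' Site-constrained permutation test result
#'
#' @slot observedS observed singular values of the tested components.
#' @slot nullS nPerm x components matrix of permuted singular values.
#' @slot pValues add-one permutation p-values, bounded below by
#'   `1/(nPerm+1)`.
#' @slot fdrMask Benjamini-Hochberg rejections at the configured q.
#' @slot nPerm number of permutations.
#' @slot seed integer seed.
#'
#' @export
setClass("PermutationResult",
  representation(
    observedS = "numeric",
    nullS     = "matrix",
    pValues   = "numeric",
    fdrMask   = "logical",
    nPerm     = "integer",
    seed      = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  lo <- 1 / (object@nPerm + 1)
  if (any(object@pValues < lo - 1e-12) || any(object@pValues > 1 + 1e-12))
    return("p-values must lie in [1/(nPerm+1), 1]")
  TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult:", object@nPerm, "site-constrained permutations\n")
  print(data.frame(component = seq_along(object@pValues),
                   S = object@observedS, p = object@pValues,
                   significant = object@fdrMask))
})

#' Site-constrained bootstrap stability result
#'
#' Per-feature (or per network block, for FC) bootstrap standard deviations
#' of PLS loadings, the derived z-scores (observed loading / bootstrap SD),
#' two-sided normal p-values, and a joint FDR mask.
#'
#' @slot observed,sd,z,pValues named lists of feature x component matrices.
#' @slot fdrMask named list of logical matrices.
#' @slot nBoot number of bootstrap draws.
#' @slot seed integer seed.
#'
#' @export
setClass("BootstrapResult",
  representation(
    observed = "list",
    sd       = "list",
    z        = "list",
    pValues  = "list",
    fdrMask  = "list",
    nBoot    = "integer",
    seed     = "integer"
  )
)

setMethod("show", "BootstrapResult", function(object) {
  cat("BootstrapResult:", object@nBoot, "site-constrained bootstraps over",
      paste(names(object@observed), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## GradientSet
## ---------------------------------------------------------------------------

#' Connectivity gradients from diffusion map embedding
#'
#' @slot embedding cortical parcels x components embedding matrix.
#' @slot eigenvalues descending non-trivial eigenvalues of the diffusion
#'   operator (all below 1).
#' @slot varianceExplained eigenvalue fractions over retained components.
#' @slot alignment orthogonal transform applied by Procrustes alignment
#'   (identity if unaligned).
#'
#' @export
setClass("GradientSet",
  representation(
    embedding         = "matrix",
    eigenvalues       = "numeric",
    varianceExplained = "numeric",
    alignment         = "matrix"
  )
)

setValidity("GradientSet", function(object) {
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be descending")
  if (any(object@eigenvalues >= 1 + 1e-10))
    return("eigenvalues must be below 1")
  if (abs(sum(object@varianceExplained) - 1) > 1e-8)
    return("varianceExplained must sum to 1 over retained components")
  TRUE
})

setMethod("show", "GradientSet", function(object) {
  cat("GradientSet:", nrow(object@embedding), "parcels x",
      ncol(object@embedding), "gradients; variance explained:",
      paste0(sprintf("%.1f", 100 * head(object@varianceExplained, 3)), "%",
             collapse = ", "), "...\n")
})

#' @export
setGeneric("gradientScores", function(x) standardGeneric("gradientScores"))
#' @describeIn GradientSet the parcel x component embedding
#' @param x,object a `GradientSet`
#' @export
setMethod("gradientScores", "GradientSet", function(x) x@embedding)

#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @describeIn GradientSet eigenvalue fractions of retained components
#' @export
setMethod("varianceExplained", "GradientSet", function(x) x@varianceExplained)

## ---------------------------------------------------------------------------
## SpinNull
## ---------------------------------------------------------------------------

#' Spin-permutation null for cortical maps
#'
#' Each row maps every cortical parcel to the source parcel whose rotated
#' centroid is nearest, under one uniform random rotation of the left
#' hemisphere sphere (mirrored to the right). Duplicated source parcels are
#' permitted, as is standard for parcel-level nearest-neighbour spins.
#'
#' @slot assignments nSpins x cortical-parcels integer matrix.
#' @slot nSpins number of spins.
#' @slot seed integer seed.
#'
#' @export
setClass("SpinNull",
  representation(
    assignments = "matrix",
    nSpins      = "integer",
    seed        = "integer"
  )
)

setValidity("SpinNull", function(object) {
  a <- object@assignments
  if (nrow(a) != object@nSpins)
    return("assignments must have nSpins rows")
  if (any(a < 1L) || any(a > ncol(a)))
    return("assignment entries must be valid cortical parcel indices")
  TRUE
})

setMethod("show", "SpinNull", function(object) {
  cat("SpinNull:", object@nSpins, "spins over", ncol(object@assignments),
      "cortical parcels\n")
})

## ---------------------------------------------------------------------------
## SplitAssignment
## ---------------------------------------------------------------------------

#' Matched discovery/replication split
#'
#' @slot labels named character vector, `"discovery"` or `"replication"`
#'   per participant.
#' @slot ratio target discovery fraction.
#' @slot strata stratum label per participant (site x sex x age tertile x
#'   overall-psychopathology tertile).
#' @slot balance data.frame of standardized mean differences.
#' @slot seed integer seed.
#'
#' @export
setClass("SplitAssignment",
  representation(
    labels  = "character",
    ratio   = "numeric",
    strata  = "character",
    balance = "data.frame",
    seed    = "integer"
  )
)

setValidity("SplitAssignment", function(object) {
  if (!all(object@labels %in% c("discovery", "replication")))
    return("labels must be discovery/replication")
  if (length(object@strata) != length(object@labels))
    return("strata must match labels")
  TRUE
})

setMethod("show", "SplitAssignment", function(object) {
  tb <- table(object@labels)
  cat("SplitAssignment:", tb[["discovery"]], "discovery /",
      tb[["replication"]], "replication (target ratio",
      round(object@ratio, 3), ")\n")
})
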
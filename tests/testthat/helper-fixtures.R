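# Shared fixtures, built in code. The default planted-signal cohort is
# generated once per test run and cached, since several suites exercise it.

.fixtureCache <- new.env(parent = emptyenv())

# Full default synthetic cohort (600 participants, 100 cortical parcels,
# rank-3 planted structure).
defaultCohort <- function() {
  if (is.null(.fixtureCache$default))
    .fixtureCache$default <- generateCohort(synthConfig(seed = 20260928L))
  .fixtureCache$default
}

# Small cohort for cheap structural checks.
smallCohort <- function(seed = 5L, ...) {
  generateCohort(synthConfig(nParticipants = 80L, nSites = 3L,
                             nCorticalParcels = 24L,
                             nSubcorticalParcels = 6L,
                             nItems = 30L, seed = seed, ...))
}

# Toy parcellation with hand-chosen centroids/networks for edge and spin
# bookkeeping tests.
toyParcellation <- function(centroids, networks, hemispheres = NULL,
                            nNetworks = max(networks)) {
  n <- nrow(centroids)
  if (is.null(hemispheres)) hemispheres <- rep("left", n)
  cent <- centroids / sqrt(rowSums(centroids^2))
  cent[hemispheres == "subcortical", ] <- NA_real_
  new("Parcellation",
      parcelId = sprintf("P_%02d", seq_len(n)),
      hemisphere = hemispheres,
      centroid = cent,
      network = as.integer(networks),
      nNetworks = as.integer(nNetworks))
}

# Residualize + PCA + PLS on a cohort sample, mirroring the pipeline's
# discovery branch (no resampling stages). Returns the pieces recovery
# tests need.
fitCohortPLS <- function(synth, ids = rownames(cohortTable(synth)),
                         threshold = 0.5) {
  cohort <- cohortTable(synth)[ids, , drop = FALSE]
  behavior <- behaviorMatrix(synth)[ids, , drop = FALSE]
  mods <- lapply(modalityMatrices(synth), function(M) M[ids, , drop = FALSE])
  filt <- dropDegenerateItems(behavior)
  Y <- residualize(filt$behavior, buildDesign(cohort, "behavior"))
  modRes <- lapply(names(mods), function(m)
    residualize(mods[[m]], buildDesign(cohort, m)))
  names(modRes) <- names(mods)
  pca <- lapply(names(modRes), function(m) fitPCA(modRes[[m]], threshold, m))
  names(pca) <- names(modRes)
  cc <- concatenateBlocks(lapply(pca, `[[`, "scores"))
  model <- fitPLS(zscoreColumns(cc$X), zscoreColumns(Y), cc$blockIndex)
  model <- computeLoadings(model, modRes, Y)
  list(model = model, Y = Y, modalities = modRes, X = cc$X,
       pcaModels = lapply(pca, `[[`, "model"), dropped = filt$dropped,
       cohort = cohort)
}

# Greedy alignment of estimated loading columns to planted columns by
# maximal |correlation|; returns the aligned absolute correlations.
matchedAbsCor <- function(estimated, planted) {
  C <- abs(cor(estimated, planted))
  k <- ncol(planted)
  out <- numeric(k)
  used <- rep(FALSE, nrow(C))
  for (l in seq_len(k)) {
    cand <- C[, l]; cand[used] <- -Inf
    best <- which.max(cand)
    out[l] <- C[best, l]
    used[best] <- TRUE
  }
  out
}

# Spatially smooth random map on the cortical parcels of a parcellation
# (Gaussian kernel on the sphere, per hemisphere).
smoothCorticalMap <- function(parc, ell = 0.6) {
  ctx <- which(isCortical(parc))
  cent <- centroids(parc)[ctx, , drop = FALSE]
  hemi <- hemispheres(parc)[ctx]
  D <- tcrossprod(cent)
  D <- acos(pmin(pmax(D, -1), 1))
  K <- exp(-(D / ell)^2)
  K[outer(hemi, hemi, "!=")] <- 0
  diag(K) <- diag(K) + 1e-8
  as.numeric(t(chol(K)) %*% rnorm(length(ctx)))
}
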
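# Synthetic multimodal cohort with planted latent brain-behavior structure.
#
# The generator emulates the study conditions the rest of the pipeline is
# designed for: a multi-site developmental cohort with ordinal symptom
# items, parcel-wise structural features, vectorized functional
# connectivity, held-out task-FC and tract-diffusion modalities, site batch
# effects, demographic confounds, and a spherical parcellation whose
# networks form contiguous caps (so parcel maps are spatially
# autocorrelated). A low-rank cross-covariance between items and imaging
# features is planted through shared participant factor scores, and kept in
# a SyntheticGroundTruth object so recovery can be tested.

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate a desk-scale version of a multi-site pediatric imaging
#' study: 600 participants over 5 sites, 100 cortical + 19 subcortical
#' parcels, 18 networks (one subcortical), 119 three-level symptom items of
#' which one is constant, and a planted rank-3 latent structure with
#' strengths (5, 4, 3) against unit residual noise.
#'
#' @param nParticipants,nSites cohort size and number of acquisition sites.
#' @param nCorticalParcels,nSubcorticalParcels parcellation size (the
#'   full-scale analog is 400 + 19).
#' @param nNetworks number of networks including the subcortical one.
#' @param nItems number of ordinal behavior items.
#' @param nLatent rank of the planted latent structure.
#' @param latentStrengths positive strictly descending effect strengths.
#' @param confoundEffects named effect sizes for `site`, `age`, `sex`,
#'   `motion`, `icv`, `totalSA`.
#' @param noiseSd residual noise SD (FC edges use `0.1 * noiseSd`).
#' @param nConstantItems how many items are forced constant at 0.
#' @param nTaskSets,nTracts held-out modality sizes.
#' @param seed integer seed.
#' @return a [SynthConfig-class].
#' @export
#' @examples
#' synthConfig(nParticipants = 50, nSites = 2, seed = 1)
synthConfig <- function(nParticipants = 600L,
                        nSites = 5L,
                        nCorticalParcels = 100L,
                        nSubcorticalParcels = 19L,
                        nNetworks = 18L,
                        nItems = 119L,
                        nLatent = 3L,
                        latentStrengths = c(5, 4, 3),
                        confoundEffects = c(site = 0.3, age = 0.1,
                                            sex = 0.1, motion = 0.1,
                                            icv = 0.2, totalSA = 0.2),
                        noiseSd = 1,
                        nConstantItems = 1L,
                        nTaskSets = 3L,
                        nTracts = 35L,
                        seed = 1L) {
  new("SynthConfig",
      nParticipants = as.integer(nParticipants),
      nSites = as.integer(nSites),
      nCorticalParcels = as.integer(nCorticalParcels),
      nSubcorticalParcels = as.integer(nSubcorticalParcels),
      nNetworks = as.integer(nNetworks),
      nItems = as.integer(nItems),
      nLatent = as.integer(nLatent),
      latentStrengths = as.numeric(latentStrengths),
      confoundEffects = confoundEffects,
      noiseSd = as.numeric(noiseSd),
      nConstantItems = as.integer(nConstantItems),
      nTaskSets = as.integer(nTaskSets),
      nTracts = as.integer(nTracts),
      seed = as.integer(seed))
}

# Deterministic even-coverage (Fibonacci) lattice of m points on the unit
# sphere.
fibonacciSphere <- function(m) {
  k <- seq_len(m) - 0.5
  z <- 1 - 2 * k / m
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * k
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Seed directions of the cortical networks (deterministic lattice).
networkSeeds <- function(nCorticalNetworks) {
  fibonacciSphere(nCorticalNetworks)
}

#' Generate a spherical parcellation with contiguous network caps
#'
#' Cortical parcels are placed on two hemispheric unit spheres via a
#' deterministic Fibonacci lattice (even coverage); each cortical parcel is
#' assigned to the nearest of `nNetworks - 1` deterministic seed directions,
#' yielding contiguous spatial caps. All subcortical parcels form the last
#' network and carry no centroid.
#'
#' @param config a [SynthConfig-class].
#' @return a [Parcellation-class]. Deterministic for a fixed config.
#' @export
#' @examples
#' p <- generateParcellation(synthConfig(nParticipants = 10))
#' length(p)
generateParcellation <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  nc <- config@nCorticalParcels
  ns <- config@nSubcorticalParcels
  nL <- as.integer(ceiling(nc / 2))
  nR <- nc - nL
  ptsL <- fibonacciSphere(nL)
  ptsR <- if (nR > 0) fibonacciSphere(nR) else matrix(0, 0, 3)
  cent <- rbind(ptsL, ptsR,
                matrix(NA_real_, ns, 3))
  hemi <- c(rep("left", nL), rep("right", nR), rep("subcortical", ns))
  ids <- c(sprintf("L_%03d", seq_len(nL)),
           sprintf("R_%03d", seq_len(nR)),
           sprintf("S_%03d", seq_len(ns)))
  seeds <- networkSeeds(config@nNetworks - 1L)
  ctx <- rbind(ptsL, ptsR)
  net <- max.col(ctx %*% t(seeds), ties.method = "first")
  network <- c(as.integer(net), rep(config@nNetworks, ns))
  new("Parcellation", parcelId = ids, hemisphere = hemi,
      centroid = cent, network = network,
      nNetworks = config@nNetworks)
}

# Baseline FC of a network pair: strong within-network, distance-decaying
# between cortical networks, weak to/within subcortex. Gives the group-mean
# matrix meaningful community structure for the gradients stage.
networkBaseline <- function(parc) {
  K <- nNetworks(parc)
  seeds <- networkSeeds(K - 1L)
  base <- matrix(0.05, K, K)
  for (a in seq_len(K - 1L)) for (b in seq_len(K - 1L)) {
    if (a == b) next
    d <- acos(pmin(1, pmax(-1, sum(seeds[a, ] * seeds[b, ]))))
    base[a, b] <- 0.05 + 0.4 * exp(-d / 0.75)
  }
  diag(base) <- 0.5
  base[K, K] <- 0.5
  base
}

#' Generate a full synthetic multimodal cohort
#'
#' Draws participant factor scores `F`, then builds every block from them:
#' item liabilities `F diag(s) t(B)` plus site offsets, age and sex effects
#' and noise, discretized at fixed thresholds into \{0,1,2\} with marginal
#' prevalences of roughly 70/20/10 percent; structural modality matrices
#' `F diag(s) t(C)` plus confound effects and noise; per-participant FC edge
#' vectors as a network block-model baseline plus factor-driven edge
#' perturbations and noise (clipped to \[-1, 1\]); and held-out task-FC and
#' tract FA/MD matrices sharing the same factors with modality-specific
#' noise. Exactly `nConstantItems` items are forced constant at 0.
#'
#' @param config a [SynthConfig-class].
#' @return a [SynthCohort-class]; all output is bit-identical for a fixed
#'   seed.
#' @export
#' @examples
#' sc <- generateCohort(synthConfig(nParticipants = 40, nSites = 2,
#'                                  nCorticalParcels = 20,
#'                                  nSubcorticalParcels = 5, seed = 7))
#' sc
generateCohort <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  parc <- generateParcellation(config)
  withSeed(config@seed, {
    n <- config@nParticipants
    k <- config@nLatent
    s <- config@latentStrengths
    eff <- config@confoundEffects
    nsd <- config@noiseSd
    ids <- sprintf("sub_%04d", seq_len(n))

    ## covariates ------------------------------------------------------------
    site <- factor(sprintf("site%02d", sample.int(config@nSites, n, TRUE)))
    age <- rnorm(n, 9.94, 0.62)
    sex <- factor(sample(c("F", "M"), n, TRUE))
    ethnicity <- factor(sample(sprintf("eth%d", 1:4), n, TRUE,
                               prob = c(0.5, 0.2, 0.2, 0.1)))
    meanFD <- exp(rnorm(n, log(0.15), 0.4))
    meanDVARS <- rnorm(n, 30, 5)
    icv <- rnorm(n, 1450, 120)          # cm^3
    totalSA <- rnorm(n, 1800, 150)      # cm^2
    cohort <- data.frame(
      participant_id = ids, site = site, age = age, age2 = age^2,
      sex = sex, ethnicity = ethnicity, meanFD = meanFD,
      meanDVARS = meanDVARS, icv = icv, totalSA = totalSA,
      stringsAsFactors = FALSE, row.names = ids)

    siteOffset <- rnorm(config@nSites, 0, eff[["site"]])
    siteEff <- siteOffset[as.integer(site)]
    ageZ <- as.numeric(scale(age))
    sexNum <- as.numeric(sex == "M")
    icvZ <- as.numeric(scale(icv))
    saZ <- as.numeric(scale(totalSA))
    fdZ <- as.numeric(scale(meanFD))

    ## latent factors and planted loadings ------------------------------------
    F <- matrix(rnorm(n * k), n, k, dimnames = list(ids, NULL))
    itemNames <- sprintf("item_%03d", seq_len(config@nItems))
    B <- qr.Q(qr(matrix(rnorm(config@nItems * k), config@nItems, k)))
    constIdx <- seq_len(config@nConstantItems)
    if (length(constIdx)) B[constIdx, ] <- 0
    B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    rownames(B) <- itemNames

    ## behavior: liability -> fixed-threshold ordinal discretization ----------
    liab <- F %*% (t(B) * s) + siteEff +
      eff[["age"]] * ageZ + eff[["sex"]] * sexNum +
      matrix(rnorm(n * config@nItems, 0, nsd), n, config@nItems)
    sdTot <- sqrt(mean(colSums((t(B) * s)^2)) + eff[["site"]]^2 +
                  eff[["age"]]^2 + eff[["sex"]]^2 / 4 + nsd^2)
    th <- qnorm(c(0.7, 0.9), 0, sdTot)
    behavior <- matrix(0L, n, config@nItems, dimnames = list(ids, itemNames))
    behavior[liab > th[1]] <- 1L
    behavior[liab > th[2]] <- 2L
    if (length(constIdx)) behavior[, constIdx] <- 0L

    ## structural modalities (cortical parcels) -------------------------------
    nc <- config@nCorticalParcels
    ctxIds <- parcelIds(parc)[isCortical(parc)]
    structuralLoadings <- list()
    modalities <- list()
    volNorm <- list(area = saZ * eff[["totalSA"]],
                    thickness = icvZ * eff[["icv"]],
                    volume = icvZ * eff[["icv"]])
    for (m in c("area", "thickness", "volume")) {
      C <- qr.Q(qr(matrix(rnorm(nc * k), nc, k)))
      C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
      rownames(C) <- ctxIds
      structuralLoadings[[m]] <- C
      M <- F %*% (t(C) * s) + siteEff + eff[["age"]] * ageZ +
        eff[["sex"]] * sexNum + volNorm[[m]] +
        matrix(rnorm(n * nc, 0, nsd), n, nc)
      dimnames(M) <- list(ids, ctxIds)
      modalities[[m]] <- M
    }

    ## functional connectivity (edge level, block-model baseline) -------------
    einfo <- edgeInfo(parc)
    ne <- nrow(einfo)
    net <- networks(parc)
    baseNet <- networkBaseline(parc)
    base <- baseNet[cbind(net[einfo$i], net[einfo$j])]
    blockKey <- match(einfo$block, unique(einfo$block))
    Bnet <- matrix(rnorm(length(unique(blockKey)) * k), ncol = k)
    E <- Bnet[blockKey, , drop = FALSE] +
      matrix(rnorm(ne * k, 0, 0.3), ne, k)
    E <- sweep(E, 2, sqrt(colSums(E^2)), "/")
    rownames(E) <- einfo$label
    fcNoise <- 0.1 * nsd
    makeFC <- function(strengthScale, noiseScale) {
      M <- matrix(rep(base, each = n), n, ne) +
        F %*% (t(E) * (s * strengthScale)) +
        eff[["motion"]] * fdZ +
        matrix(rnorm(n * ne, 0, fcNoise * noiseScale), n, ne)
      M[M > 1] <- 1; M[M < -1] <- -1
      dimnames(M) <- list(ids, einfo$label)
      M
    }
    modalities[["fc"]] <- makeFC(1, 1)

    ## held-out modalities sharing the same factors ---------------------------
    heldout <- list()
    taskNames <- c("taskMID", "taskENback", "taskSST")[seq_len(config@nTaskSets)]
    for (tn in taskNames) heldout[[tn]] <- makeFC(0.8, 1.5)
    tractIds <- sprintf("tract_%02d", seq_len(config@nTracts))
    for (m in c("tractFA", "tractMD")) {
      Tm <- qr.Q(qr(matrix(rnorm(config@nTracts * k), config@nTracts, k)))
      Tm <- sweep(Tm, 2, sqrt(colSums(Tm^2)), "/")
      M <- F %*% (t(Tm) * s) + siteEff + eff[["age"]] * ageZ +
        matrix(rnorm(n * config@nTracts, 0, nsd), n, config@nTracts)
      dimnames(M) <- list(ids, tractIds)
      heldout[[m]] <- M
    }

    gt <- new("SyntheticGroundTruth",
              itemLoadings = B,
              structuralLoadings = structuralLoadings,
              edgeLoadings = E,
              factorScores = F,
              seed = config@seed)
    new("SynthCohort", cohort = cohort, behavior = behavior,
        modalities = modalities, heldout = heldout,
        parcellation = parc, groundTruth = gt, config = config)
  })
}
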
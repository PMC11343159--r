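# Orchestration: the full discovery/replication analysis on a cohort,
# with keyed seed derivation, a provenance manifest, and TSV/JSON output.

residualizeSample <- function(cohort, behavior, modalities) {
  filt <- dropDegenerateItems(behavior)
  designB <- buildDesign(cohort, "behavior")
  Yres <- residualize(filt$behavior, designB)
  modRes <- list()
  for (m in names(modalities)) {
    design <- buildDesign(cohort, m)
    modRes[[m]] <- residualize(modalities[[m]], design)
  }
  list(Y = Yres, modalities = modRes, dropped = filt$dropped)
}

#' Run the full brain-behavior PLS pipeline
#'
#' Executes, in order: matched discovery/replication split; per-sample
#' item filtering and confound residualization; per-modality PCA with the
#' cumulative-variance rule and block concatenation; PLS correlation of
#' the z-scored blocks; site-constrained permutation significance;
#' site-constrained bootstrap loading stability with 18-network block
#' averaging; connectivity-gradient embedding of the group-mean FC; spin
#' correlations of cortical loading maps with the principal gradient;
#' out-of-sample projection and loading replication; held-out modality
#' contextualization; and covariate post hocs. Every stochastic stage
#' derives its stream from the master seed via [deriveSeed()], so a rerun
#' of the same configuration reproduces all outputs bit-identically.
#'
#' @param data a [SynthCohort-class] (or any list-like object with
#'   `cohort`, `behavior`, `modalities`, `heldout`, `parcellation`
#'   entries of the same shapes).
#' @param varianceThreshold PCA cumulative-variance threshold
#'   (default 0.5).
#' @param nPerm,nBoot,nSpins resampling sizes (paper-scale defaults
#'   10000, 1000, 1000; reduce for desk-scale runs).
#' @param splitRatio discovery fraction (default 2/3).
#' @param nComponents latent components carried into inference
#'   (default 5).
#' @param gradientAlpha,diffusionTime,rowDensity gradient parameters
#'   (defaults 0.5, 0, 0.10).
#' @param gradientReference optional parcels x k reference for Procrustes
#'   alignment.
#' @param fdrQ FDR level (default 0.05).
#' @param seed master seed.
#' @param outDir optional output directory; when given, results and the
#'   manifest are written there.
#' @return a result bundle (named list); see the vignette for a tour.
#' @export
runPipeline <- function(data,
                        varianceThreshold = 0.5,
                        nPerm = 10000L, nBoot = 1000L, nSpins = 1000L,
                        splitRatio = 2/3, nComponents = 5L,
                        gradientAlpha = 0.5, diffusionTime = 0,
                        rowDensity = 0.10, gradientReference = NULL,
                        fdrQ = 0.05, seed = 1L, outDir = NULL) {
  if (is(data, "SynthCohort")) {
    cohort <- cohortTable(data); behavior <- behaviorMatrix(data)
    modalities <- modalityMatrices(data); heldout <- heldoutMatrices(data)
    parc <- parcellation(data)
  } else {
    cohort <- data$cohort; behavior <- data$behavior
    modalities <- data$modalities; heldout <- data$heldout
    parc <- data$parcellation
  }
  order <- intersect(c("area", "thickness", "volume", "fc"),
                     names(modalities))

  ## 1. matched split ---------------------------------------------------------
  split <- matchedSplit(cohort, behavior, splitRatio,
                        seed = deriveSeed(seed, "split"))
  disc <- names(split@labels)[split@labels == "discovery"]
  repl <- names(split@labels)[split@labels == "replication"]

  ## 2. per-sample filtering + residualization --------------------------------
  prep <- lapply(list(discovery = disc, replication = repl), function(idx) {
    residualizeSample(cohort[idx, , drop = FALSE],
                      behavior[idx, , drop = FALSE],
                      lapply(modalities, function(M) M[idx, , drop = FALSE]))
  })

  ## 3. discovery PCA + PLS ----------------------------------------------------
  pcaFits <- lapply(order, function(m)
    fitPCA(prep$discovery$modalities[[m]], varianceThreshold, m))
  names(pcaFits) <- order
  pcaModels <- lapply(pcaFits, `[[`, "model")
  cc <- concatenateBlocks(lapply(pcaFits, `[[`, "scores"), order)
  Xz <- zscoreColumns(cc$X)
  Yz <- zscoreColumns(prep$discovery$Y)
  model <- fitPLS(Xz, Yz, cc$blockIndex)
  model <- computeLoadings(model, prep$discovery$modalities,
                           prep$discovery$Y,
                           nComponents = min(nComponents, length(model@S)))
  importance <- modalityImportance(model, Xz,
                                   min(nComponents, length(model@S)))
  sitesDisc <- as.character(cohort[disc, "site"])

  ## 4. permutation significance ----------------------------------------------
  perm <- permutationTest(Xz, Yz, sitesDisc, nPerm = nPerm,
                          nComponents = nComponents, q = fdrQ,
                          seed = deriveSeed(seed, "permutation"))

  ## 5. bootstrap loading stability ---------------------------------------------
  boot <- bootstrapLoadings(cc$X, prep$discovery$Y, sitesDisc,
                            prep$discovery$modalities, parc,
                            nBoot = nBoot, nComponents = nComponents,
                            q = fdrQ, seed = deriveSeed(seed, "bootstrap"))

  ## 6. connectivity gradients ---------------------------------------------------
  gradients <- NULL
  if ("fc" %in% names(modalities)) {
    gm <- groupMeanFC(modalities$fc, parc)
    aff <- cosineAffinity(rowThreshold(gm, rowDensity))
    gradients <- diffusionEmbedding(aff, alpha = gradientAlpha,
                                    diffusionTime = diffusionTime)
    if (!is.null(gradientReference))
      gradients <- procrustesAlign(gradients, gradientReference)
  }

  ## 7. spin correlations with the principal gradient -----------------------------
  spins <- buildSpinNull(parc, nSpins, seed = deriveSeed(seed, "spins"))
  gradientTests <- NULL
  if (!is.null(gradients) && length(model@loadings)) {
    g1 <- gradientScores(gradients)[, 1]
    rows <- list()
    prof <- fcLoadingParcelProfiles(model@loadings$fc, parc)
    for (l in seq_len(min(nComponents, ncol(model@loadings$fc)))) {
      for (kind in c("within", "between")) {
        mp <- prof[[kind]][, l]
        sc <- spinCorrelation(mp, g1, spins, naRm = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          map = paste0("fc_", kind), component = l, r = sc$r, p = sc$p)
      }
      for (m in intersect(c("area", "thickness", "volume"), names(model@loadings))) {
        sc <- spinCorrelation(model@loadings[[m]][, l], g1, spins,
                              naRm = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          map = m, component = l, r = sc$r, p = sc$p)
      }
    }
    gradientTests <- do.call(rbind, rows)
    gradientTests$significant <- fdrBH(gradientTests$p, fdrQ)
  }

  ## 8. replication: out-of-sample + refit --------------------------------------
  oos <- outOfSampleProject(pcaModels, model, prep$replication$modalities,
                            prep$replication$Y, order)
  repPcaFits <- lapply(order, function(m)
    fitPCA(prep$replication$modalities[[m]], varianceThreshold, m))
  names(repPcaFits) <- order
  repCC <- concatenateBlocks(lapply(repPcaFits, `[[`, "scores"), order)
  repModel <- fitPLS(zscoreColumns(repCC$X),
                     zscoreColumns(prep$replication$Y), repCC$blockIndex)
  repModel <- computeLoadings(repModel, prep$replication$modalities,
                              prep$replication$Y,
                              nComponents = min(nComponents,
                                                length(repModel@S)))
  replication <- loadingReplication(model@loadings, repModel@loadings,
                                    parc, spins)

  ## 9. held-out contextualization ------------------------------------------------
  heldoutRes <- NULL
  if (length(heldout)) {
    heldoutRes <- contextualizeHeldout(
      heldout, model, parc,
      sites = setNames(as.character(cohort$site), rownames(cohort)),
      nBoot = nBoot, nComponents = nComponents, q = fdrQ,
      seed = deriveSeed(seed, "heldout"))
  }

  ## 10. covariate post hocs --------------------------------------------------------
  covar <- covariateAssociations(model, cohort[disc, , drop = FALSE],
                                 min(nComponents, length(model@S)), fdrQ)

  manifest <- list(
    package = as.character(utils::packageVersion("bbpls")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    parameters = list(varianceThreshold = varianceThreshold,
                      nPerm = nPerm, nBoot = nBoot, nSpins = nSpins,
                      splitRatio = splitRatio, nComponents = nComponents,
                      gradientAlpha = gradientAlpha,
                      diffusionTime = diffusionTime,
                      rowDensity = rowDensity, fdrQ = fdrQ,
                      masterSeed = seed),
    stageSeeds = sapply(c("split", "permutation", "bootstrap", "spins",
                          "heldout"), function(k) deriveSeed(seed, k)),
    droppedItems = lapply(prep, `[[`, "dropped"),
    counts = list(
      discovery = length(disc), replication = length(repl),
      itemsRetained = ncol(prep$discovery$Y),
      pcaComponents = vapply(pcaModels, function(m) m@k, integer(1)),
      testedComponents = length(perm@pValues),
      fcBlocks = nrow(boot@observed$fc %||% matrix(NA, 0, 0))))

  result <- list(split = split, prep = prep, pcaModels = pcaModels,
                 model = model, importance = importance,
                 permutation = perm, bootstrap = boot,
                 gradients = gradients, gradientTests = gradientTests,
                 spins = spins, outOfSample = oos,
                 replicationModel = repModel, replication = replication,
                 heldout = heldoutRes, covariates = covar,
                 manifest = manifest)
  if (!is.null(outDir)) writePipelineOutputs(result, outDir)
  result
}

#' Write the main pipeline outputs to a directory
#'
#' Emits the PLS model (JSON), loading tables (TSV per modality),
#' permutation and bootstrap summaries, gradient scores, replication and
#' covariate tables, and the provenance manifest with its MD5 hash.
#'
#' @param result the bundle returned by [runPipeline()].
#' @param dir output directory.
#' @export
writePipelineOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- result$model
  jsonlite::write_json(
    list(singularValues = m@S, covexp = m@covexp,
         U = unname(apply(m@U, 2, as.numeric, simplify = FALSE)),
         V = unname(apply(m@V, 2, as.numeric, simplify = FALSE)),
         permutationP = result$permutation@pValues,
         significant = result$permutation@fdrMask),
    file.path(dir, "pls_model.json"), digits = NA, auto_unbox = TRUE)
  for (mod in names(m@loadings)) {
    df <- data.frame(feature = rownames(m@loadings[[mod]]),
                     fmtNum(m@loadings[[mod]]), check.names = FALSE)
    write.table(df, file.path(dir, paste0("loadings_", mod, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (mod in names(result$bootstrap@z)) {
    df <- data.frame(feature = rownames(result$bootstrap@z[[mod]]),
                     fmtNum(result$bootstrap@z[[mod]]), check.names = FALSE)
    write.table(df, file.path(dir, paste0("bootstrap_z_", mod, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$gradients)) {
    E <- gradientScores(result$gradients)
    write.table(data.frame(parcel_id = rownames(E), fmtNum(E)),
                file.path(dir, "gradients.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(eigenvalues = result$gradients@eigenvalues,
           varianceExplained = varianceExplained(result$gradients)),
      file.path(dir, "gradient_eigenvalues.json"), digits = NA,
      auto_unbox = TRUE)
  }
  if (!is.null(result$gradientTests))
    write.table(result$gradientTests, file.path(dir, "gradient_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$replication, file.path(dir, "replication.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$covariates, file.path(dir, "covariates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, manifestPath, digits = NA,
                       auto_unbox = TRUE)
  hash <- unname(tools::md5sum(manifestPath))
  writeLines(hash, file.path(dir, "manifest.md5"))
  invisible(dir)
}
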
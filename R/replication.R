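# Discovery/replication machinery: matched splitting, out-of-sample
# projection, loading replication, held-out modality contextualization,
# and covariate post hocs.

#' Matched discovery/replication split
#'
#' Computes an overall-psychopathology score as the first principal
#' component of the (non-degenerate) behavior items, forms strata as
#' site x sex x age tertile x psychopathology tertile, and performs an
#' independent random `ratio` split within each stratum. Strata of size 1
#' go to discovery. A balance report of standardized mean differences is
#' attached.
#'
#' @param cohort covariate data.frame with `site`, `sex`, `age`.
#' @param behavior participants x items matrix (pre-filtering; constant
#'   items are ignored for the score).
#' @param ratio target discovery fraction (default 2/3).
#' @param seed optional integer seed.
#' @return a [SplitAssignment-class].
#' @export
matchedSplit <- function(cohort, behavior, ratio = 2/3, seed = NULL) {
  stopifnot(nrow(cohort) == nrow(behavior))
  keep <- apply(behavior, 2, var) > 0
  pScore <- prcomp(behavior[, keep, drop = FALSE], center = TRUE,
                   scale. = FALSE)$x[, 1]
  tert <- function(x) {
    qs <- quantile(x, c(1/3, 2/3))
    cut(x, c(-Inf, qs, Inf), labels = FALSE)
  }
  strata <- paste(cohort$site, cohort$sex, tert(cohort$age), tert(pScore),
                  sep = "|")
  ids <- rownames(cohort)
  labels <- setNames(rep("replication", nrow(cohort)), ids)
  withSeed(seed, {
    for (st in unique(strata)) {
      pos <- which(strata == st)
      if (length(pos) == 1) { labels[pos] <- "discovery"; next }
      nd <- round(ratio * length(pos))
      labels[pos[sample.int(length(pos), nd)]] <- "discovery"
    }
  })
  disc <- labels == "discovery"
  smd <- function(x) {
    if (!any(disc) || all(disc)) return(NA_real_)  # one-sided split
    num <- if (is.numeric(x)) x else as.numeric(factor(x))
    s <- sqrt((var(num[disc]) + var(num[!disc])) / 2)
    if (is.na(s) || s == 0) 0 else (mean(num[disc]) - mean(num[!disc])) / s
  }
  balance <- data.frame(
    variable = c("age", "sex", "pScore"),
    smd = c(smd(cohort$age), smd(cohort$sex), smd(pScore)))
  new("SplitAssignment", labels = labels, ratio = ratio, strata = strata,
      balance = balance, seed = as.integer(if (is.null(seed)) NA else seed))
}

#' Project discovery PCA and PLS weights onto replication data
#'
#' The replication blocks are residualized and z-scored with
#' replication-sample statistics, projected through the discovery PCA
#' coefficients, and the discovery PLS weights are applied directly:
#' `LX_rep = X_pca_rep V_disc`, `LY_rep = Y_rep U_disc`. No replication
#' data enters the estimation of coefficients or weights. Items dropped in
#' only one sample are intersected (with a message), mirroring the
#' different degenerate items of the two subsamples.
#'
#' @param pcaModels named list of discovery [PCAModel-class] objects.
#' @param plsModel discovery [PLSModel-class].
#' @param replicationData named list of residualized replication modality
#'   matrices (same modalities as the PCA models).
#' @param replicationY residualized replication behavior matrix.
#' @param order modality concatenation order used in discovery.
#' @return list with `LX`, `LY`, and `loadings` (replication-sample
#'   correlations with these scores, per modality and `behavior`).
#' @export
outOfSampleProject <- function(pcaModels, plsModel, replicationData,
                               replicationY,
                               order = c("area", "thickness", "volume", "fc")) {
  stopifnot(is(plsModel, "PLSModel"))
  scores <- lapply(intersect(order, names(pcaModels)), function(m)
    projectPCA(pcaModels[[m]], replicationData[[m]]))
  names(scores) <- intersect(order, names(pcaModels))
  cc <- concatenateBlocks(scores, order)
  Xz <- zscoreColumns(cc$X)
  discItems <- rownames(plsModel@U)
  repItems <- colnames(replicationY)
  common <- intersect(discItems, repItems)
  if (length(common) < length(discItems) ||
      length(common) < length(repItems))
    message("item sets differ between samples; intersecting to ",
            length(common), " items")
  Yz <- zscoreColumns(replicationY[, common, drop = FALSE])
  LX <- Xz %*% plsModel@V
  LY <- Yz %*% plsModel@U[common, , drop = FALSE]
  nComp <- min(5L, ncol(LX), ncol(LY))
  loadings <- list(behavior = cor(replicationY[, common, drop = FALSE],
                                  LY[, seq_len(nComp), drop = FALSE]))
  for (m in names(scores))
    loadings[[m]] <- cor(replicationData[[m]],
                         LX[, seq_len(nComp), drop = FALSE])
  list(LX = LX, LY = LY, loadings = loadings)
}

#' Agreement between discovery and replication loadings
#'
#' Behavioral loading agreement is plain Pearson correlation; cortical
#' structural maps are compared with spin correlations (preserving spatial
#' autocorrelation); FC loadings are compared at the network-block level
#' with plain Pearson correlation.
#'
#' @param discLoadings,repLoadings named lists of feature x component
#'   loading matrices (as stored in a fitted model).
#' @param parc a [Parcellation-class].
#' @param spinNull a [SpinNull-class] for the cortical map comparisons.
#' @return data.frame with `modality`, `component`, `r`, `p`.
#' @export
loadingReplication <- function(discLoadings, repLoadings, parc, spinNull) {
  out <- list()
  for (m in names(discLoadings)) {
    if (!m %in% names(repLoadings)) next
    D <- discLoadings[[m]]; Rp <- repLoadings[[m]]
    if (ncol(D) != ncol(Rp))
      stop("component count mismatch for modality '", m, "'")
    if (m %in% c("fc", "taskMID", "taskENback", "taskSST")) {
      D <- blockAverageFC(D, parc); Rp <- blockAverageFC(Rp, parc)
    }
    for (l in seq_len(ncol(D))) {
      if (m %in% c("area", "thickness", "volume")) {
        sc <- spinCorrelation(D[, l], Rp[, l], spinNull, naRm = TRUE)
        r <- sc$r; p <- sc$p
      } else {
        ok <- !is.na(D[, l]) & !is.na(Rp[, l])
        r <- cor(D[ok, l], Rp[ok, l])
        p <- stats::cor.test(D[ok, l], Rp[ok, l])$p.value
      }
      out[[length(out) + 1]] <- data.frame(
        modality = m, component = colnames(D)[l] %||% paste0("LC", l),
        r = r, p = p)
    }
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contextualize held-out modalities against fitted composite scores
#'
#' Correlates held-out features (task FC, tract FA/MD) with the imaging
#' and behavioral composite scores on the overlapping participants, and
#' assesses stability by bootstrapping the correlations within sites. Task
#' FC loadings are averaged into network blocks; tract loadings stay per
#' tract. Two-sided normal p-values from the bootstrap z-scores are
#' FDR-corrected jointly.
#'
#' @param heldout named list of participants x features matrices (rows a
#'   subset of the fitted sample).
#' @param model fitted [PLSModel-class].
#' @param parc a [Parcellation-class].
#' @param sites site labels named by participant id (or aligned with the
#'   fitted sample rows).
#' @param nBoot bootstrap draws.
#' @param nComponents components reported (default 5).
#' @param q FDR level.
#' @param seed optional integer seed.
#' @return named list per modality with `loadingsLX`, `loadingsLY`,
#'   `sd`, `z`, `p`, `fdrMask` (all on the block/tract level).
#' @export
contextualizeHeldout <- function(heldout, model, parc, sites,
                                 nBoot = 1000L,
                                 nComponents = min(5L, length(model@S)),
                                 q = 0.05, seed = NULL) {
  stopifnot(is(model, "PLSModel"))
  fitted <- rownames(model@LX)
  comps <- seq_len(nComponents)
  results <- list()
  sd0 <- function(a) apply(a, c(1, 2), sd, na.rm = TRUE)
  for (m in names(heldout)) {
    M <- heldout[[m]]
    ov <- intersect(rownames(M), fitted)
    if (length(ov) == 0) stop("no overlap between held-out '", m,
                              "' and the fitted sample")
    if (length(ov) < 2) stop("overlap of ", length(ov),
                             " participant(s): correlation undefined")
    M <- M[ov, , drop = FALSE]
    LX <- model@LX[ov, comps, drop = FALSE]
    LY <- model@LY[ov, comps, drop = FALSE]
    st <- if (!is.null(names(sites))) sites[ov] else
      sites[match(ov, fitted)]
    isFC <- m %in% c("fc", "taskMID", "taskENback", "taskSST")
    reduce <- function(ld) if (isFC) blockAverageFC(ld, parc) else ld
    obsX <- reduce(cor(M, LX)); obsY <- reduce(cor(M, LY))
    dX <- array(NA_real_, c(dim(obsX), nBoot))
    dY <- array(NA_real_, c(dim(obsY), nBoot))
    withSeed(if (is.null(seed)) NULL else deriveSeed(seed, m), {
      for (b in seq_len(nBoot)) {
        idx <- bootstrapWithinSites(st)
        s <- apply(M[idx, , drop = FALSE], 2, sd)
        ok <- s > 0
        ldX <- matrix(NA_real_, ncol(M), length(comps),
                      dimnames = list(colnames(M), NULL))
        ldY <- ldX
        ldX[ok, ] <- cor(M[idx, ok, drop = FALSE], LX[idx, , drop = FALSE])
        ldY[ok, ] <- cor(M[idx, ok, drop = FALSE], LY[idx, , drop = FALSE])
        dX[, , b] <- reduce(ldX); dY[, , b] <- reduce(ldY)
      }
    })
    zX <- obsX / sd0(dX); zY <- obsY / sd0(dY)
    pX <- 2 * pnorm(-abs(zX)); pY <- 2 * pnorm(-abs(zY))
    results[[m]] <- list(loadingsLX = obsX, loadingsLY = obsY,
                         sdLX = sd0(dX), sdLY = sd0(dY),
                         zLX = zX, zLY = zY, pLX = pX, pLY = pY)
  }
  pAll <- unlist(lapply(results, function(r) c(r$pLX, r$pLY)))
  maskAll <- fdrBH(pAll, q)
  off <- 0
  for (m in names(results)) {
    nX <- length(results[[m]]$pLX); nY <- length(results[[m]]$pLY)
    results[[m]]$fdrMaskLX <- array(maskAll[off + seq_len(nX)],
                                    dim(results[[m]]$pLX),
                                    dimnames(results[[m]]$pLX))
    results[[m]]$fdrMaskLY <- array(maskAll[off + nX + seq_len(nY)],
                                    dim(results[[m]]$pLY),
                                    dimnames(results[[m]]$pLY))
    off <- off + nX + nY
  }
  results
}

#' Associations between composite scores and demographics
#'
#' Two-sample t statistics (pooled variance) per component for sex on the
#' imaging and behavioral composite scores, and Pearson correlations for
#' age and age squared, with a joint FDR correction. Single-sex cohorts
#' skip the sex tests with a message.
#'
#' @param model fitted [PLSModel-class].
#' @param cohort covariate data.frame with `sex`, `age`, `age2`, rows
#'   aligned with the fitted sample.
#' @param nComponents components tested (default 5).
#' @param q FDR level.
#' @return data.frame with `component`, `score`, `covariate`,
#'   `statistic`, `estimate`, `p`, `significant`.
#' @export
covariateAssociations <- function(model, cohort,
                                  nComponents = min(5L, length(model@S)),
                                  q = 0.05) {
  stopifnot(is(model, "PLSModel"))
  comps <- seq_len(nComponents)
  rows <- list()
  twoSex <- length(unique(cohort$sex)) >= 2
  if (!twoSex) message("single-sex cohort: sex associations skipped")
  for (scoreName in c("imaging", "behavior")) {
    Sc <- if (scoreName == "imaging") model@LX else model@LY
    for (l in comps) {
      x <- Sc[, l]
      if (twoSex) {
        tt <- t.test(x ~ cohort$sex, var.equal = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          component = l, score = scoreName, covariate = "sex",
          statistic = unname(tt$statistic), estimate = diff(rev(tt$estimate)),
          p = tt$p.value)
      }
      for (cv in c("age", "age2")) {
        ct <- stats::cor.test(x, cohort[[cv]])
        rows[[length(rows) + 1]] <- data.frame(
          component = l, score = scoreName, covariate = cv,
          statistic = unname(ct$statistic), estimate = unname(ct$estimate),
          p = ct$p.value)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- fdrBH(out$p, q)
  out
}
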
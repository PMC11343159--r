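# Matched splitting, out-of-sample projection, replication statistics,
# held-out contextualization, and covariate post hocs.

test_that("matched split respects the ratio and balances strata", {
  sc <- generateCohort(synthConfig(nParticipants = 300L, nSites = 3L,
                                   nCorticalParcels = 20L,
                                   nSubcorticalParcels = 4L,
                                   nItems = 25L, seed = 31L))
  cohort <- cohortTable(sc); behavior <- behaviorMatrix(sc)
  sp <- matchedSplit(cohort, behavior, ratio = 2 / 3, seed = 1L)
  nd <- sum(sp@labels == "discovery")
  # per-stratum rounding keeps the total within a small band of the target
  expect_gte(nd, 185L); expect_lte(nd, 215L)
  expect_equal(sort(names(sp@labels)), sort(rownames(cohort)))
  # balance: standardized mean differences small on the default fixture
  expect_true(all(abs(sp@balance$smd) < 0.1))
  # ratio 1: everything to discovery
  sp1 <- matchedSplit(cohort, behavior, ratio = 1, seed = 1L)
  expect_true(all(sp1@labels == "discovery"))
  # determinism
  sp2 <- matchedSplit(cohort, behavior, ratio = 2 / 3, seed = 1L)
  expect_identical(sp@labels, sp2@labels)
})

test_that("out-of-sample projection on discovery reproduces its own scores", {
  sc <- smallCohort(seed = 41L)
  fit <- fitCohortPLS(sc)
  oos <- outOfSampleProject(fit$pcaModels, fit$model, fit$modalities,
                            fit$Y)
  expect_lt(max(abs(oos$LX - fit$model@LX)), 1e-10)
  expect_lt(max(abs(oos$LY - fit$model@LY)), 1e-10)
})

test_that("discovery weights generalize to a matched replication sample", {
  sc <- defaultCohort()
  sp <- matchedSplit(cohortTable(sc), behaviorMatrix(sc), 2 / 3, seed = 2L)
  disc <- names(sp@labels)[sp@labels == "discovery"]
  repl <- names(sp@labels)[sp@labels == "replication"]
  fitD <- fitCohortPLS(sc, disc)
  fitR <- fitCohortPLS(sc, repl)  # only for residualized replication data
  oos <- outOfSampleProject(fitD$pcaModels, fitD$model, fitR$modalities,
                            fitR$Y)
  items <- intersect(rownames(fitD$model@loadings$behavior),
                     rownames(oos$loadings$behavior))
  rs <- vapply(1:3, function(l)
    abs(cor(fitD$model@loadings$behavior[items, l],
            oos$loadings$behavior[items, l])), numeric(1))
  expect_gte(mean(rs), 0.8)
})

test_that("out-of-sample brain-behavior correspondence vanishes under the null", {
  cfg <- synthConfig(nParticipants = 200L, nSites = 2L,
                     nCorticalParcels = 20L, nSubcorticalParcels = 4L,
                     nItems = 25L, latentStrengths = c(0, 0, 0), seed = 8L)
  sc <- generateCohort(cfg)
  sp <- matchedSplit(cohortTable(sc), behaviorMatrix(sc), 0.5, seed = 3L)
  disc <- names(sp@labels)[sp@labels == "discovery"]
  repl <- names(sp@labels)[sp@labels == "replication"]
  fitD <- fitCohortPLS(sc, disc)
  fitR <- fitCohortPLS(sc, repl)
  oos <- outOfSampleProject(fitD$pcaModels, fitD$model, fitR$modalities,
                            fitR$Y)
  # the generalizability statistic: correlation of projected imaging and
  # behavioral composite scores in the held-out sample
  rNull <- abs(cor(oos$LX[, 1], oos$LY[, 1]))
  expect_lt(rNull, 0.3)
  # contrast: the planted-signal default cohort generalizes strongly
  scS <- defaultCohort()
  spS <- matchedSplit(cohortTable(scS), behaviorMatrix(scS), 2 / 3,
                      seed = 3L)
  dS <- names(spS@labels)[spS@labels == "discovery"]
  rS <- names(spS@labels)[spS@labels == "replication"]
  fD <- fitCohortPLS(scS, dS); fR <- fitCohortPLS(scS, rS)
  oosS <- outOfSampleProject(fD$pcaModels, fD$model, fR$modalities, fR$Y)
  expect_gt(cor(oosS$LX[, 1], oosS$LY[, 1]), 0.5)
})

test_that("loading replication reports r = 1 for identical and -1 for flipped", {
  sc <- smallCohort(seed = 51L)
  fit <- fitCohortPLS(sc)
  parc <- parcellation(sc)
  spins <- buildSpinNull(parc, nSpins = 49L, seed = 5L)
  ld <- fit$model@loadings
  tab <- loadingReplication(ld, ld, parc, spins)
  expect_true(all(abs(tab$r - 1) < 1e-10))
  flipped <- lapply(ld, function(M) -M)
  tab2 <- loadingReplication(ld, flipped, parc, spins)
  expect_true(all(abs(tab2$r + 1) < 1e-10))
  # component-count mismatch rejected
  short <- lapply(ld, function(M) M[, 1:2, drop = FALSE])
  expect_error(loadingReplication(ld, short, parc, spins), "mismatch")
})

test_that("held-out features identical to composite scores load 1", {
  sc <- smallCohort(seed = 61L)
  fit <- fitCohortPLS(sc)
  parc <- parcellation(sc)
  ids <- rownames(fit$model@LX)
  H <- cbind(h1 = fit$model@LX[, 1], h2 = rnorm(length(ids)))
  rownames(H) <- ids
  sites <- setNames(as.character(fit$cohort$site), ids)
  res <- contextualizeHeldout(list(tracts = H), fit$model, parc, sites,
                              nBoot = 30L, nComponents = 2L, seed = 6L)
  expect_equal(unname(res$tracts$loadingsLX["h1", 1]), 1, tolerance = 1e-10)
  expect_true(res$tracts$fdrMaskLX["h1", 1])
  # single-participant overlap rejected
  H1 <- H[1, , drop = FALSE]
  expect_error(contextualizeHeldout(list(tracts = H1), fit$model, parc,
                                    sites, nBoot = 5L), "undefined")
  # empty overlap rejected
  H0 <- H; rownames(H0) <- paste0("zz", seq_along(ids))
  expect_error(contextualizeHeldout(list(tracts = H0), fit$model, parc,
                                    sites, nBoot = 5L), "overlap")
})

test_that("planted tract signal is recovered in held-out loadings", {
  sc <- smallCohort(seed = 71L)
  fit <- fitCohortPLS(sc)
  parc <- parcellation(sc)
  ids <- rownames(fit$model@LX)
  sites <- setNames(as.character(fit$cohort$site), ids)
  res <- contextualizeHeldout(heldoutMatrices(sc)["tractFA"], fit$model,
                              parc, sites, nBoot = 60L,
                              nComponents = 3L, seed = 7L)
  # tract loadings correlate with the planted tract pattern of the
  # matching component (sign/order aligned)
  gt <- groundTruth(sc)
  F <- gt@factorScores[ids, ]
  # identify which latent factor each LC tracks
  A <- abs(cor(fit$model@LX[, 1:3], F))
  ld <- res$tractFA$loadingsLX
  plantedFA <- cor(heldoutMatrices(sc)$tractFA[ids, ], F)
  for (l in 1:3) {
    fac <- which.max(A[l, ])
    expect_gt(abs(cor(ld[, l], plantedFA[, fac])), 0.8)
  }
})

test_that("covariate associations match closed-form oracles", {
  sc <- smallCohort(seed = 81L)
  fit <- fitCohortPLS(sc)
  cohort <- fit$cohort
  tab <- covariateAssociations(fit$model, cohort, nComponents = 2L)
  expect_true(all(c("sex", "age", "age2") %in% tab$covariate))
  # two-sample pooled-variance t oracle for sex on LX component 1
  x <- fit$model@LX[, 1]
  g1 <- x[cohort$sex == "F"]; g2 <- x[cohort$sex == "M"]
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  tOracle <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  got <- tab$statistic[tab$covariate == "sex" & tab$component == 1 &
                         tab$score == "imaging"]
  expect_equal(got, tOracle, tolerance = 1e-10)
  # scores equal to age: r = 1
  m2 <- fit$model
  m2@LX[, 1] <- cohort$age
  tab2 <- covariateAssociations(m2, cohort, nComponents = 1L)
  rAge <- tab2$estimate[tab2$covariate == "age" & tab2$score == "imaging"]
  expect_equal(unname(rAge), 1, tolerance = 1e-10)
  # single-sex cohort: sex tests skipped with a message
  cohort1 <- cohort; cohort1$sex <- factor("F", levels = c("F", "M"))
  expect_message(tab3 <- covariateAssociations(fit$model, cohort1, 1L),
                 "single-sex")
  expect_false("sex" %in% tab3$covariate)
})

test_that("sex associations are calibrated under the null", {
  # scores independent of sex: rejection rate ~ alpha over simulations
  set.seed(32)
  nSim <- 200
  rej <- 0
  for (i in seq_len(nSim)) {
    n <- 60
    x <- rnorm(n)
    sex <- rep(c("F", "M"), each = n / 2)
    tt <- t.test(x ~ sex, var.equal = TRUE)
    rej <- rej + (tt$p.value <= 0.05)
  }
  bounds <- qbinom(c(0.025, 0.975), nSim, 0.05)
  expect_gte(rej, bounds[1]); expect_lte(rej, bounds[2])
})

test_that("discovery model is untouched by replication-side data", {
  sc <- smallCohort(seed = 91L)
  sp <- matchedSplit(cohortTable(sc), behaviorMatrix(sc), 0.5, seed = 9L)
  disc <- names(sp@labels)[sp@labels == "discovery"]
  fit1 <- fitCohortPLS(sc, disc)
  # rebuild the cohort with replication rows replaced by noise
  sc2 <- sc
  repl <- names(sp@labels)[sp@labels == "replication"]
  set.seed(99)
  sc2@behavior[repl, ] <- sample(0:2, length(repl) * ncol(sc2@behavior),
                                 replace = TRUE)
  for (m in names(sc2@modalities))
    sc2@modalities[[m]][repl, ] <-
      matrix(rnorm(length(repl) * ncol(sc2@modalities[[m]])),
             nrow = length(repl))
  fit2 <- fitCohortPLS(sc2, disc)
  expect_equal(fit1$model@S, fit2$model@S, tolerance = 1e-12)
  expect_equal(fit1$model@U, fit2$model@U, tolerance = 1e-12)
})
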
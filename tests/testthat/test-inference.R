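# Site-constrained permutation and bootstrap inference, block averaging,
# and FDR control.

test_that("within-site permutations only exchange rows sharing a site", {
  # every row its own site: identity forced
  expect_equal(permuteWithinSites(letters[1:5]), 1:5)
  # two sites of sizes 3 and 2: exactly 3! * 2! = 12 permutations reachable,
  # and 5,000 draws hit all of them
  sites <- c("a", "a", "a", "b", "b")
  set.seed(1)
  seen <- character(0)
  for (i in 1:5000) {
    p <- permuteWithinSites(sites)
    expect_equal(sites[p], sites)  # site labels preserved positionally
    seen <- union(seen, paste(p, collapse = ","))
  }
  expect_equal(length(seen), 12L)
  # one site: all rows exchangeable (spot-check support size over draws)
  set.seed(2)
  one <- replicate(2000, paste(permuteWithinSites(rep("s", 4)),
                               collapse = ","))
  expect_equal(length(unique(one)), factorial(4))
})

test_that("permutation p-values follow the add-one formula and saturate", {
  set.seed(3)
  n <- 60
  z <- rnorm(n)
  X <- zscoreColumns(cbind(z, rnorm(n)) + 0)
  Y <- zscoreColumns(cbind(z + 0.01 * rnorm(n), rnorm(n)))
  sites <- rep(c("s1", "s2"), each = n / 2)
  res <- permutationTest(X, Y, sites, nPerm = 99L, nComponents = 2L,
                         seed = 42L)
  # the planted shared column dominates every permuted draw
  expect_equal(res@pValues[1], 1 / 100)
  expect_true(all(res@pValues >= 1 / 100 & res@pValues <= 1))
  expect_error(permutationTest(X, Y, sites, nPerm = 0L), "at least 1")
})

test_that("permutation p-values are invariant to site relabeling", {
  set.seed(4)
  X <- zscoreColumns(matrix(rnorm(40 * 3), 40, 3))
  Y <- zscoreColumns(matrix(rnorm(40 * 3), 40, 3))
  sites <- rep(c("siteA", "siteB"), each = 20)
  r1 <- permutationTest(X, Y, sites, nPerm = 50L, seed = 7L)
  relabeled <- c(siteA = "x9", siteB = "k2")[sites]
  r2 <- permutationTest(X, Y, relabeled, nPerm = 50L, seed = 7L)
  expect_equal(r1@pValues, r2@pValues)
  expect_equal(r1@nullS, r2@nullS)
})

test_that("site-constrained bootstrap preserves site composition", {
  sites <- c("a", "b", "b", "c", "c", "c", "c")
  set.seed(5)
  for (i in 1:50) {
    idx <- bootstrapWithinSites(sites)
    expect_equal(sites[idx], sites)      # per-site counts preserved
    expect_equal(idx[1], 1L)             # singleton site always present
  }
  # expected unique fraction within one site: 1 - (1 - 1/n)^n
  n <- 8
  set.seed(6)
  fr <- replicate(4000, length(unique(bootstrapWithinSites(rep("s", n)))) / n)
  expect_equal(mean(fr), 1 - (1 - 1 / n)^n, tolerance = 0.01)
})

test_that("network block averaging yields K(K+1)/2 labeled blocks", {
  sc <- smallCohort()
  parc <- parcellation(sc)
  K <- nNetworks(parc)
  expect_equal(K, 18L)
  ne <- edgeCount(parc)
  blocks <- blockAverageFC(rep(2.5, ne), parc)
  expect_equal(nrow(blocks), 171L)  # 18 * 19 / 2
  expect_true(all(is.na(blocks) | abs(blocks - 2.5) < 1e-12))
  # blocks with at least one edge all equal the constant
  expect_true(any(!is.na(blocks)))
  expect_error(blockAverageFC(rep(1, ne - 1), parc), "edge count")
})

test_that("block means match a hand enumeration on a 3-network toy", {
  parc <- toyParcellation(
    centroids = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0)),
    networks = c(1, 1, 2, 3))
  einfo <- edgeInfo(parc)
  # edges in canonical lower-triangle order:
  # (2,1)=1-1, (3,1)=1-2, (4,1)=1-3, (3,2)=1-2, (4,2)=1-3, (4,3)=2-3
  vals <- c(10, 1, 2, 3, 4, 5)
  blocks <- blockAverageFC(vals, parc)
  expect_equal(unname(blocks["1-1", 1]), 10)
  expect_equal(unname(blocks["1-2", 1]), mean(c(1, 3)))
  expect_equal(unname(blocks["1-3", 1]), mean(c(2, 4)))
  expect_equal(unname(blocks["2-3", 1]), 5)
  expect_true(all(is.na(blocks[c("2-2", "3-3"), 1])))
  # named edges resolve through labels; unknown labels are rejected
  named <- setNames(vals, einfo$label)
  expect_equal(blockAverageFC(named, parc), blocks)
  names(named)[2] <- "nope-nope"
  expect_error(blockAverageFC(named, parc), "not resolvable")
})

test_that("Benjamini-Hochberg mask follows the step-up rule", {
  expect_equal(fdrBH(c(0.01, 0.5), 0.05), c(TRUE, FALSE))
  expect_equal(fdrBH(rep(1, 4)), rep(FALSE, 4))
  expect_equal(fdrBH(rep(0.001, 10)), rep(TRUE, 10))
  expect_equal(fdrBH(numeric(0)), logical(0))
  # direct step-up oracle on a mixed vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  m <- length(p)
  thresholds <- 0.05 * seq_len(m) / m
  kMax <- max(c(0, which(sort(p) <= thresholds)))
  oracle <- rank(p) <= kMax
  expect_equal(fdrBH(p, 0.05), oracle)
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
})

test_that("bootstrap loadings are stable on a noise-free low-rank fixture", {
  set.seed(16)
  n <- 40
  f <- rnorm(n)
  X <- cbind(f, 0.5 * f, rnorm(n) * 1e-6 + f)
  Y <- cbind(2 * f, -f)
  colnames(X) <- paste0("x", 1:3); colnames(Y) <- paste0("y", 1:2)
  rownames(X) <- rownames(Y) <- sprintf("s%02d", 1:n)
  feats <- X
  res <- bootstrapLoadings(X, Y, rep("one", n), list(struct = feats),
                           nBoot = 50L, nComponents = 1L, seed = 3L)
  expect_lt(max(res@sd$struct, na.rm = TRUE), 1e-3)
  expect_true(all(abs(res@z$struct) > 100, na.rm = TRUE))
  expect_true(all(res@fdrMask$struct))
  # nBoot = 2 still gives finite SDs (denominator n - 1)
  res2 <- bootstrapLoadings(X, Y, rep("one", n), list(struct = feats),
                            nBoot = 2L, nComponents = 1L, seed = 4L)
  expect_true(all(is.finite(res2@sd$struct)))
  expect_error(bootstrapLoadings(X, Y, rep("one", n), list(struct = feats),
                                 nBoot = 1L), "at least 2")
})

test_that("significant FC blocks recover the strongest planted block loadings", {
  sc <- smallCohort(seed = 21L)
  fit <- fitCohortPLS(sc)
  parc <- parcellation(sc)
  sites <- as.character(fit$cohort$site)
  res <- bootstrapLoadings(fit$X, fit$Y, sites, fit$modalities, parc,
                           nBoot = 100L, nComponents = 3L, seed = 9L)
  # align model components to planted columns by behavioral loadings
  gt <- groundTruth(sc)
  planted <- blockAverageFC(gt@edgeLoadings, parc)
  keep <- apply(behaviorMatrix(sc), 2, var) > 0
  A <- abs(cor(plsLoadings(fit$model, "behavior")[
    rownames(gt@itemLoadings)[keep], 1:3],
    gt@itemLoadings[keep, ]))
  for (l in 1:3) {
    comp <- which.max(A[, l])
    top <- which.max(abs(planted[, l]))
    expect_true(res@fdrMask$fc[top, comp])
  }
})

test_that("bootstrap z-scores of null FC block loadings are near standard normal", {
  # global null: independent blocks, one seed suite
  set.seed(17)
  n <- 300
  parc <- generateParcellation(synthConfig(
    nParticipants = 10L, nCorticalParcels = 24L, nSubcorticalParcels = 4L))
  ne <- edgeCount(parc)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  Y <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("y", 1:6)))
  FCmat <- matrix(rnorm(n * ne), n, ne)
  colnames(FCmat) <- edgeInfo(parc)$label
  sites <- rep(c("s1", "s2", "s3"), each = 100)
  res <- bootstrapLoadings(X, Y, sites, list(fc = FCmat), parc,
                           nBoot = 200L, nComponents = 1L, seed = 11L)
  z <- res@z$fc[is.finite(res@z$fc)]
  expect_lt(abs(mean(z)), 0.35)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.25)
})
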
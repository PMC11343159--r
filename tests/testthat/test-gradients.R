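# Gradient construction: group mean, thresholding, affinity, diffusion
# embedding against a dense oracle, and Procrustes alignment.

test_that("group-mean FC averages element-wise over participants", {
  M1 <- rbind(c(1, .2, .3, .1), c(.2, 1, .4, 0),
              c(.3, .4, 1, .5), c(.1, 0, .5, 1))
  M2 <- diag(4) * 0.5 + 0.5
  M3 <- rbind(c(1, -.2, .1, .3), c(-.2, 1, 0, .2),
              c(.1, 0, 1, -.1), c(.3, .2, -.1, 1))
  parc <- toyParcellation(diag(3)[c(1, 2, 3, 1), ] + 0,
                          networks = c(1, 1, 2, 2))
  gm <- groupMeanFC(list(M1, M2, M3), parc)
  expect_equal(unname(gm), (M1 + M2 + M3) / 3, tolerance = 1e-12)
  # identical matrices: the matrix itself
  expect_equal(unname(groupMeanFC(list(M1, M1), parc)), M1)
  # M and -M off-diagonal: zero off-diagonal, unit diagonal
  M4 <- M1; M4[upper.tri(M4) | lower.tri(M4)] <-
    -M1[upper.tri(M1) | lower.tri(M1)]
  z <- groupMeanFC(list(M1, M4), parc)
  expect_equal(unname(z), diag(4))
  # edge-vector input: mean of edges reassembled, cortical subset
  sc <- smallCohort()
  gm2 <- groupMeanFC(modalityMatrices(sc)$fc, parcellation(sc))
  ctx <- sum(isCortical(parcellation(sc)))
  expect_equal(dim(gm2), c(ctx, ctx))
  expect_equal(gm2, t(gm2))
  expect_equal(unname(diag(gm2)), rep(1, ctx))
})

test_that("row thresholding keeps ceil(density * (n-1)) entries and ties", {
  # 11 parcels at density 0.10: exactly 1 survivor per row
  set.seed(18)
  M <- matrix(runif(121), 11, 11); M <- (M + t(M)) / 2; diag(M) <- 1
  th <- rowThreshold(M, 0.10)
  expect_equal(unname(rowSums(th > 0)), rep(1L, 11), ignore_attr = TRUE)
  expect_true(all(diag(th) == 0))
  # surviving set matches a sort-based enumeration oracle on a 5x5 matrix
  M5 <- matrix(c(0, 9, 1, 4, 7,
                 9, 0, 8, 2, 3,
                 1, 8, 0, 6, 5,
                 4, 2, 6, 0, 9,
                 7, 3, 5, 9, 0), 5, 5, byrow = TRUE)
  th5 <- rowThreshold(M5, 0.5)
  for (i in 1:5) {
    keep <- ceiling(0.5 * 4)
    cutoff <- sort(M5[i, -i], decreasing = TRUE)[keep]
    expected <- M5[i, ] * (M5[i, ] >= cutoff)
    expected[i] <- 0
    expect_equal(th5[i, ], expected)
  }
  # ties at the cutoff are all kept
  Mt <- matrix(0, 4, 4); Mt[1, 2:4] <- c(5, 5, 1); Mt[2:4, 1] <- c(5, 5, 1)
  Mt[2, 3] <- Mt[3, 2] <- 2; Mt[2, 4] <- Mt[4, 2] <- 3; Mt[3, 4] <- Mt[4, 3] <- 4
  tht <- rowThreshold(Mt, 1 / 3)  # keep ceil(1) = 1 per row
  expect_equal(sum(tht[1, ] > 0), 2L)  # both tied 5s survive
  expect_error(rowThreshold(Mt, 0), "keeps no entries")
})

test_that("cosine affinity matches the dot/norm oracle and rejects zero rows", {
  r1 <- c(1, 0, 2); r2 <- c(2, 0, 4); r3 <- c(0, 3, 0)
  M <- rbind(r1, r2, r3)
  A <- cosineAffinity(M)
  cosOracle <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(A[1, 2], cosOracle(r1, r2), tolerance = 1e-12)  # identical: 1
  expect_equal(A[1, 2], 1, tolerance = 1e-12)
  expect_equal(A[1, 3], 0)  # orthogonal rows
  expect_equal(unname(diag(A)), rep(0, 3))
  expect_equal(A, t(A))
  # negative cosines are clipped to zero
  An <- cosineAffinity(rbind(c(1, 0), c(-1, 0), c(1, 1)))
  expect_equal(An[1, 2], 0)
  expect_error(cosineAffinity(rbind(r1, c(0, 0, 0))), "all-zero")
})

test_that("diffusion embedding matches a dense eigendecomposition oracle", {
  A <- rbind(c(0, .9, .2, .1),
             c(.9, 0, .3, .2),
             c(.2, .3, 0, .8),
             c(.1, .2, .8, 0))
  alpha <- 0.5
  g <- diffusionEmbedding(A, alpha = alpha, nComponents = 3L)
  # oracle: explicitly form the Markov operator P and eigendecompose it
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  d2 <- rowSums(W)
  P <- W / d2
  eg <- eigen(P)
  ord <- order(Re(eg$values), decreasing = TRUE)
  lam <- Re(eg$values)[ord]
  expect_equal(g@eigenvalues, lam[2:4], tolerance = 1e-8)
  for (l in 2:4) {
    v <- Re(eg$vectors[, ord[l]])
    # impose the package's normalization: unit norm under the d2 metric,
    # then rescale against the constant trivial eigenvector
    v <- v / sqrt(sum(d2 * v^2)) * sqrt(sum(d2))
    scale <- lam[l] / (1 - lam[l])
    expect_equal(abs(g@embedding[, l - 1]), abs(v * scale),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(sum(g@varianceExplained), 1, tolerance = 1e-12)
})

test_that("the first gradient sign-separates two weakly bridged blocks", {
  n <- 20
  A <- matrix(0.02, n, n)
  A[1:10, 1:10] <- 0.9
  A[11:20, 11:20] <- 0.9
  diag(A) <- 0
  g <- diffusionEmbedding(A, nComponents = 5L)
  g1 <- g@embedding[, 1]
  expect_true(all(sign(g1[1:10]) == sign(g1[1])))
  expect_true(all(sign(g1[11:20]) == -sign(g1[1])))
})

test_that("embedding is equivariant to parcel permutation and scale invariant", {
  set.seed(19)
  B <- matrix(runif(64, 0.1, 1), 8, 8); A <- (B + t(B)) / 2; diag(A) <- 0
  g <- diffusionEmbedding(A, nComponents = 4L)
  idx <- sample(8)
  gp <- diffusionEmbedding(A[idx, idx], nComponents = 4L)
  for (l in 1:4)
    expect_equal(abs(gp@embedding[, l]), abs(g@embedding[idx, l]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  gs <- diffusionEmbedding(3.7 * A, nComponents = 4L)
  for (l in 1:4)
    expect_equal(abs(gs@embedding[, l]), abs(g@embedding[, l]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues in (-1, 1); variance explained sums to one
  expect_true(all(g@eigenvalues < 1 & g@eigenvalues > -1))
})

test_that("degenerate affinities are rejected", {
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  expect_error(diffusionEmbedding(A), "disconnected")
  B <- matrix(runif(16), 4, 4)
  expect_error(diffusionEmbedding(B), "symmetric")
  C <- -diag(4) + 1
  expect_error(diffusionEmbedding(C - 2), "non-negative")
})

test_that("Procrustes alignment matches the SVD oracle and handles reflections", {
  set.seed(20)
  E <- matrix(rnorm(12), 6, 2)
  g <- new("GradientSet", embedding = E, eigenvalues = c(0.5, 0.4),
           varianceExplained = c(5 / 9, 4 / 9), alignment = diag(2))
  # reference = gradients: identity transform
  a1 <- procrustesAlign(g, E)
  expect_equal(a1@alignment, diag(2), tolerance = 1e-10)
  # sign-flipped reference: diagonal +/-1 transform
  a2 <- procrustesAlign(g, E %*% diag(c(-1, 1)))
  expect_equal(a2@alignment, diag(c(-1, 1)), tolerance = 1e-10)
  # random reference: transform matches the polar-decomposition oracle
  # Q = M (M'M)^{-1/2} with M = E'R, an independent eigendecomposition route
  R <- matrix(rnorm(12), 6, 2)
  a3 <- procrustesAlign(g, R)
  M <- t(E) %*% R
  eg <- eigen(t(M) %*% M, symmetric = TRUE)
  invSqrt <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  expect_equal(a3@alignment, M %*% invSqrt, tolerance = 1e-8)
  # and no orthogonal transform does better than the one found
  for (theta in seq(0, 2 * pi, length.out = 17)) {
    Q <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
    expect_lte(sum((a3@embedding - R)^2), sum((E %*% Q - R)^2) + 1e-10)
  }
  expect_error(procrustesAlign(g, R[, 1, drop = FALSE]), "dimensions")
})

test_that("gradients on the block-model cohort track the network structure", {
  sc <- defaultCohort()
  parc <- parcellation(sc)
  gm <- groupMeanFC(modalityMatrices(sc)$fc, parc)
  aff <- cosineAffinity(rowThreshold(gm, 0.10))
  g <- diffusionEmbedding(aff)
  # parcels of the same network cluster in embedding space: the first
  # gradient varies less within networks than across them
  net <- networks(parc)[isCortical(parc)]
  g1 <- g@embedding[, 1]
  withinVar <- mean(tapply(g1, net, var), na.rm = TRUE)
  expect_lt(withinVar, var(g1))
})
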
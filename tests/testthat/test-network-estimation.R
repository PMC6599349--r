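test_that("Kendall tau-b matches brute-force pair enumeration", {
  expect_equal(kendallTauB(1:8, 1:8), 1)
  expect_equal(kendallTauB(1:8, 8:1), -1)
  set.seed(201)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    x <- sample(0:3, n, replace = TRUE)  # ties guaranteed
    y <- sample(0:3, n, replace = TRUE)
    bt <- bruteTauB(x, y)
    if (is.na(bt)) {
      expect_warning(got <- kendallTauB(x, y), "constant")
      expect_equal(got, 0)
    } else {
      expect_equal(kendallTauB(x, y), bt, tolerance = 1e-12)
    }
  }
  # cross-check against the reference implementation on continuous data
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(kendallTauB(x, y), cor(x, y, method = "kendall"),
               tolerance = 1e-12)
})

test_that("SKEPTIC transform reproduces closed-form values", {
  # perfectly concordant columns: tau 1 -> r = sin(pi/2) = 1; the singular
  # matrix is then PSD-repaired, nudging r just below 1
  m <- cbind(1:6, 2 * (1:6), rnorm(6))
  sk <- skepticCorrelation(m)
  expect_true(sk$psdRepaired)
  expect_gt(sk$values[1, 2], 0.999)
  # tau = 1/3 -> r = sin(pi/6) = 0.5 (x = 1:3 vs y = c(1,3,2))
  expect_equal(kendallTauB(1:3, c(1, 3, 2)), 1 / 3)
  expect_equal(sin(pi / 2 * kendallTauB(1:3, c(1, 3, 2))), 0.5)
  # tau 0 -> r 0 for independent large samples
  set.seed(211)
  S <- skepticCorrelation(matrix(rnorm(4000), 1000, 4))$values
  expect_lt(max(abs(S[upper.tri(S)])), 0.1)
})

test_that("SKEPTIC is invariant under strictly monotone column transforms", {
  set.seed(221)
  m <- matrix(rnorm(300), 100, 3)
  S1 <- skepticCorrelation(m)$values
  m2 <- cbind(exp(m[, 1]), m[, 2]^3, atan(m[, 3]))
  expect_equal(skepticCorrelation(m2)$values, S1, tolerance = 1e-12)
})

test_that("indefinite rank-correlation matrices are repaired to PSD", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(R, symmetric = TRUE)$values), 0)  # genuinely indefinite
  fixed <- honosnet:::.repairPSD(R)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-8)
  expect_equal(diag(fixed), rep(1, 3))
})

test_that("graphical lasso solves the penalised likelihood problem", {
  set.seed(231)
  # full shrinkage: lambda >= max |off-diagonal| gives a diagonal precision
  X <- matrix(rnorm(600), 200, 3)
  S <- cor(X)
  lam <- max(abs(S[upper.tri(S)]))
  K <- graphicalLasso(S, lam + 0.01)$K
  expect_equal(K[upper.tri(K)], rep(0, 3))
  expect_equal(diag(K), 1 / diag(S), tolerance = 1e-8)

  # identity input at lambda 0
  expect_equal(graphicalLasso(diag(3), 0)$K, diag(3), tolerance = 1e-8)

  # lambda 0 recovers the inverse correlation matrix
  g0 <- graphicalLasso(S, 0)
  expect_lt(max(abs(g0$K - solve(S))), 1e-5)

  # duality gap certificate
  g <- graphicalLasso(S, 0.1)
  expect_lt(g$gap, 1e-6)

  # 3-variable objective within 1e-4 of a generic-optimiser oracle
  sigma <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.4, 0.2, 0.4, 1), 3, 3)
  set.seed(241)
  S3 <- cor(matrix(rnorm(3 * 200), 200, 3) %*% chol(sigma))
  for (lam in c(0.05, 0.1, 0.25)) {
    mine <- glassoObjective(graphicalLasso(S3, lam)$K, S3, lam)
    oracle <- gridGlassoOracle3(S3, lam)
    expect_lt(mine, oracle + 1e-4)   # never worse than the oracle optimum
    expect_lt(abs(mine - oracle), 1e-2)
  }
})

test_that("EBIC follows its closed form", {
  set.seed(251)
  S <- cor(matrix(rnorm(300), 100, 3))
  K <- graphicalLasso(S, 0.05)$K
  n <- 100
  # scalar re-evaluation oracle
  E <- sum(abs(K[upper.tri(K)]) > 1e-10)
  L <- n / 2 * (determinant(K)$modulus[1] - sum(S * K))
  for (g in c(0, 0.5)) {
    expect_equal(ebic(K, S, n, g),
                 -2 * L + E * log(n) + 4 * E * g * log(3), tolerance = 1e-10)
  }
  # gamma = 0 reduces to BIC; adding one edge at equal likelihood costs
  # log n + 4 gamma log p by the formula difference
  expect_equal(ebic(K, S, n, 0.5) - ebic(K, S, n, 0), 4 * E * 0.5 * log(3))
  expect_error(ebic(matrix(c(1, 1, 1, 1), 2, 2), diag(2), 50), "singular")
})

test_that("precision-to-partial conversion matches recursive formulas", {
  # diagonal precision: empty network
  expect_equal(networkWeights(precisionToPartial(diag(c(2, 3, 4)))),
               matrix(0, 3, 3), ignore_attr = TRUE)

  # bivariate identity: partial equals the correlation
  r <- 0.6
  S2 <- matrix(c(1, r, r, 1), 2, 2)
  w <- networkWeights(precisionToPartial(solve(S2)))
  expect_equal(w[1, 2], r, tolerance = 1e-12)

  # 3-variable recursion r12.3 = (r12 - r13 r23)/sqrt((1-r13^2)(1-r23^2))
  R <- matrix(c(1, 0.5, 0.3, 0.5, 1, -0.2, 0.3, -0.2, 1), 3, 3)
  w <- networkWeights(precisionToPartial(solve(R)))
  pc <- function(i, j, k)
    (R[i, j] - R[i, k] * R[j, k]) /
      sqrt((1 - R[i, k]^2) * (1 - R[j, k]^2))
  expect_equal(w[1, 2], pc(1, 2, 3), tolerance = 1e-12)
  expect_equal(w[1, 3], pc(1, 3, 2), tolerance = 1e-12)
  expect_equal(w[2, 3], pc(2, 3, 1), tolerance = 1e-12)

  expect_error(precisionToPartial(diag(c(1, -1, 2))), "positive")
})

test_that("network estimation is deterministic with sane path structure", {
  sim <- simulateDefaultCohort(n = 100, seed = 31)
  r <- residualizeOnDelay(baselineScores(sim$cohort), delayDays(sim$cohort))
  e1 <- suppressMessages(estimateNetwork(r))
  e2 <- suppressMessages(estimateNetwork(r))
  expect_identical(networkWeights(e1$network), networkWeights(e2$network))
  f <- e1$fit
  expect_s4_class(f, "GlassoFit")
  expect_true(all(diff(lambdaPath(f)) < 0))
  expect_equal(ebicValues(f)[f@selectedIndex], min(ebicValues(f)))
  # partials symmetric with zero diagonal at every path point
  for (i in seq(1, 100, by = 20)) {
    wn <- precisionToPartial(f@precisions[[i]])
    expect_s4_class(wn, "WeightedNetwork")
  }
})

test_that("empty generative networks yield nearly empty estimates", {
  spurious <- integer(20)
  for (s in 1:20) {
    tn <- makeTrueNetwork(12, 0, seed = s)
    cc <- sampleOrdinalCohort(tn, tn,
                              simConfig(nPatients = 500, seed = 100 + s,
                                        improvementShift = rep(0, 12)))
    est <- suppressMessages(estimateNetwork(baselineScores(cc$cohort)))
    spurious[s] <- sum(edgeVec(networkWeights(est$network)))
  }
  expect_gte(mean(spurious <= 2), 0.9)
})

test_that("a 3-edge network with strong partials is recovered", {
  edges <- cbind(c(1, 3, 5), c(2, 4, 6), 0.32)
  hits <- logical(20)
  for (s in 1:20) {
    tn <- fixedBundle(edges)
    cc <- sampleOrdinalCohort(tn, tn,
                              simConfig(nPatients = 1000, seed = 100 + s,
                                        improvementShift = rep(0, 12)))
    est <- suppressMessages(estimateNetwork(baselineScores(cc$cohort)))
    w <- networkWeights(est$network)
    hits[s] <- all(abs(w[cbind(edges[, 1], edges[, 2])]) > 0)
  }
  expect_gte(mean(hits), 0.9)
})
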
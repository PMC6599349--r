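test_that("ground-truth network construction is internally consistent", {
  # density 0 gives the identity model
  b0 <- makeTrueNetwork(12, 0, seed = 1)
  expect_equal(truePartials(b0), matrix(0, 12, 12))
  expect_equal(trueSigma(b0), diag(12))

  # density 1 keeps all 66 pairs connected (after any shrink)
  b1 <- makeTrueNetwork(12, 1, seed = 2)
  expect_true(all(abs(truePartials(b1)[upper.tri(diag(12))]) > 0))

  # p=3 single edge: sigma matches the closed-form inverse of the
  # 2x2-embedded precision [[1,-w],[-w,1]] (third variable independent)
  b3 <- fixedBundle(cbind(1, 2, 0.4), p = 3L)
  w <- 0.4
  sigmaExpect <- diag(3)
  sigmaExpect[1, 2] <- sigmaExpect[2, 1] <- w  # cov2cor of inv([[1,-w],[-w,1]])
  expect_equal(trueSigma(b3), sigmaExpect, tolerance = 1e-12)

  # partials are recoverable from sigma by inversion + sign flip
  bb <- makeTrueNetwork(12, 0.2, seed = 3)
  K <- solve(trueSigma(bb))
  d <- 1 / sqrt(diag(K))
  rec <- -K * tcrossprod(d); diag(rec) <- 0
  expect_equal(rec, truePartials(bb), tolerance = 1e-8)
})

test_that("threshold calibration hits target ordinal means", {
  expect_error(defaultMarginalThresholds(c(0, 2)), "strictly inside")
  expect_error(defaultMarginalThresholds(4), "strictly inside")

  # symmetric target: symmetric cutpoints and exact mean 2
  th <- defaultMarginalThresholds(2)
  expect_equal(as.numeric(th), -rev(as.numeric(th)), tolerance = 1e-7)
  expect_equal(impliedOrdinalMean(th[1, ]), 2, tolerance = 1e-7)

  # target 1.68: implied mean via independent numeric integration of the
  # categorised standard normal
  th <- defaultMarginalThresholds(1.68)
  category <- function(x) findInterval(x, th[1, ])
  quad <- integrate(function(x) category(x) * dnorm(x), -Inf, Inf,
                    subdivisions = 2000L, rel.tol = 1e-10,
                    stop.on.error = FALSE)
  expect_lt(abs(quad$value - 1.68), 0.05)
})

test_that("sampled cohorts respect marginals, bounds and determinism", {
  # same seed -> identical cohort
  s1 <- simulateDefaultCohort(n = 50, seed = 77)
  s2 <- simulateDefaultCohort(n = 50, seed = 77)
  expect_identical(baselineScores(s1$cohort), baselineScores(s2$cohort))
  expect_identical(endpointScores(s1$cohort), endpointScores(s2$cohort))
  expect_equal(delayDays(s1$cohort), delayDays(s2$cohort))

  # bounds
  expect_true(all(baselineScores(s1$cohort) %in% 0:4))
  expect_true(all(delayDays(s1$cohort) > 0))

  # thresholds pushing all mass to category 0 give all-zero scores
  b <- makeTrueNetwork(12, 0.1, seed = 4)
  bLow <- methods::new("TrueNetworkBundle", partials = truePartials(b),
                       sigma = trueSigma(b),
                       thresholds = matrix(rep(c(10, 11, 12, 13), each = 12),
                                           12, 4))
  s <- sampleOrdinalCohort(bLow, bLow,
                           simConfig(nPatients = 20, seed = 5,
                                     improvementShift = rep(0, 12)))
  expect_true(all(baselineScores(s$cohort) == 0L))

  # independent items: category frequencies match Phi(cutpoints) within 0.01
  bInd <- makeTrueNetwork(12, 0, seed = 6)
  s <- sampleOrdinalCohort(bInd, bInd,
                           simConfig(nPatients = 50000, seed = 7,
                                     improvementShift = rep(0, 12)))
  sc <- baselineScores(s$cohort)
  th <- trueThresholds(bInd)
  for (j in c(1L, 7L, 12L)) {
    pExp <- diff(c(0, pnorm(th[j, ]), 1))
    pObs <- tabulate(sc[, j] + 1L, nbins = 5L) / nrow(sc)
    expect_lt(max(abs(pObs - pExp)), 0.01)
  }

  # zero cross-occasion correlation: baseline/endpoint tau near 0
  s <- sampleOrdinalCohort(bInd, bInd,
                           simConfig(nPatients = 20000, seed = 8,
                                     crossOccasionCorrelation = 0,
                                     improvementShift = rep(0, 12)))
  taus <- vapply(1:12, function(j)
    kendallTauB(baselineScores(s$cohort)[, j],
                endpointScores(s$cohort)[, j]), numeric(1))
  expect_lt(max(abs(taus)), 0.03)
})

test_that("improvement shift reproduces the end-point mean profile", {
  th <- defaultMarginalThresholds(referenceItemMeans("baseline"))
  sh <- improvementShiftFor(th, referenceItemMeans("endpoint"))
  expect_equal(unname(impliedOrdinalMean(th, shift = 0)),
               unname(referenceItemMeans("baseline")), tolerance = 1e-6)
  got <- vapply(1:12, function(i) impliedOrdinalMean(th[i, ], sh[i]),
                numeric(1))
  expect_equal(got, unname(referenceItemMeans("endpoint")), tolerance = 1e-6)
  # every item except physical health (which worsens slightly) improves
  expect_true(all(sh[-5] > 0))
})
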
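test_that("paired Wilcoxon handles degenerate and maximal cases", {
  r <- pairedWilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_true(r$degenerate)
  expect_equal(r$V, 0)
  expect_equal(r$pValue, 1)

  # all-positive distinct differences give the maximal statistic
  r <- pairedWilcoxon(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$V, 6)
  expect_equal(r$nEffective, 3L)
})

test_that("exact Wilcoxon p matches full sign-flip enumeration", {
  cases <- list(
    c(3, -1, 2, 5, -4, 6),            # n_effective = 6, distinct
    c(1, 1, -2, 3, 3, -3, 4),         # ties in |d|
    c(2, 2, 2, -2, 1),                # heavy ties
    c(-1, -2, -3, 4, 5, 1, 1, -1, 2, 6))
  for (d in cases) {
    r <- pairedWilcoxon(d, rep(0, length(d)))
    expect_equal(r$method, "exact")
    expect_equal(r$pValue, enumSignedRankP(d), tolerance = 1e-12)
  }
})

test_that("large-sample Wilcoxon agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:10) {
    b <- sample(0:4, 137, replace = TRUE)
    e <- pmax(0, b - rbinom(137, 2, 0.3))
    r <- pairedWilcoxon(b, e)
    if (r$degenerate) next
    expect_equal(r$method, "normal")
    ref <- suppressWarnings(wilcox.test(b, e, paired = TRUE,
                                        correct = TRUE, exact = FALSE))
    expect_equal(r$V, unname(ref$statistic))
    expect_equal(r$pValue, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Wilcoxon p is invariant to shifting both members of each pair", {
  set.seed(31)
  b <- sample(0:4, 30, replace = TRUE)
  e <- sample(0:4, 30, replace = TRUE)
  r1 <- pairedWilcoxon(b, e)
  r2 <- pairedWilcoxon(b + 7, e + 7)
  expect_equal(r1$V, r2$V)
  expect_equal(r1$pValue, r2$pValue)
})

test_that("response status is the negation of severity on random profiles", {
  expect_equal(responseStatus(rep(2L, 12)), "responder")
  expect_equal(responseStatus(c(rep(0L, 11), 4L)), "non-responder")
  set.seed(41)
  profiles <- matrix(sample(0:4, 1000 * 12, replace = TRUE), 1000, 12)
  expect_equal(responseStatus(profiles) == "responder",
               classifySeverity(profiles) == "non-severe")
})

test_that("response proportion counts end-point non-severity", {
  all0 <- fixedCohort(nSevere = 5L, nResponders = 0L)
  expect_equal(responseProportion(all0)$proportion, 0)
  all1 <- fixedCohort(nSevere = 5L, nResponders = 5L)
  expect_equal(responseProportion(all1)$proportion, 1)
  some <- fixedCohort(nSevere = 10L, nResponders = 4L)
  expect_equal(responseProportion(some)$count, 4L)
  expect_equal(responseProportion(some)$proportion, 0.4)
})

# a cohort in which response depends only on a binary first baseline item,
# with the remaining predictors fully balanced across the four
# (item1, response) groups so their MLE coefficients are exactly zero
balancedLogisticCohort <- function(n00, n01, n10, n11, m = 20L,
                                   seed = 5L) {
  set.seed(seed)
  pat <- matrix(sample(0:2, m * 11, replace = TRUE), m, 11)
  ageP <- sample(20:60, m, replace = TRUE)
  genP <- rep(c("male", "female"), length.out = m)
  build <- function(a, y, cnt) {
    idx <- rep(seq_len(m), cnt / m)
    b <- cbind(rep(a, cnt), pat[idx, , drop = FALSE])
    e <- matrix(0L, cnt, 12)
    if (y == 0) e[, 2] <- 3L
    list(b = b, e = e, age = ageP[idx], gender = genP[idx])
  }
  parts <- list(build(0L, 0L, n00), build(0L, 1L, n01),
                build(1L, 0L, n10), build(1L, 1L, n11))
  HonosCohort(do.call(rbind, lapply(parts, `[[`, "b")),
              do.call(rbind, lapply(parts, `[[`, "e")),
              delay_days = rep(365, n00 + n01 + n10 + n11),
              age = unlist(lapply(parts, `[[`, "age")),
              gender = unlist(lapply(parts, `[[`, "gender")))
}

test_that("logistic slope equals the closed-form 2x2 log odds ratio", {
  ch <- balancedLogisticCohort(60L, 40L, 40L, 60L)
  fit <- fitResponseLogistic(ch)
  expect_true(fit$converged)
  expect_false(fit$separationFlag)
  # oracle: log OR of the collapsed 2x2 table
  expect_equal(unname(fit$coefficients["Agi"]),
               log((60 / 40) / (40 / 60)), tolerance = 1e-6)
  # balanced nuisance predictors have exactly-zero coefficients
  others <- setdiff(names(fit$coefficients), c("(Intercept)", "Agi"))
  expect_lt(max(abs(fit$coefficients[others])), 1e-6)
})

test_that("null logistic model estimates near-zero effects", {
  set.seed(51)
  n <- 500
  b <- matrix(sample(0:4, n * 12, replace = TRUE), n, 12)
  e <- matrix(0L, n, 12)
  e[sample(n, n / 2), 2] <- 3L  # response is a fair coin, independent of b
  ch <- HonosCohort(b, e, delay_days = rep(365, n),
                    age = sample(20:70, n, replace = TRUE),
                    gender = sample(c("male", "female"), n, replace = TRUE))
  fit <- fitResponseLogistic(ch)
  expect_true(fit$converged)
  z <- fit$coefficients / fit$standardErrors
  expect_true(all(abs(z) < 3))
})

test_that("logistic regression flags separation and rejects degenerate designs", {
  # perfect separation on item 1
  ch <- balancedLogisticCohort(40L, 0L, 0L, 40L) # y == item1 exactly
  fit <- suppressWarnings(fitResponseLogistic(ch))
  expect_true(fit$separationFlag)

  # single-class outcome
  all1 <- fixedCohort(nSevere = 30L, nResponders = 30L)
  expect_error(fitResponseLogistic(all1), "single class")

  # collinear design named
  set.seed(61)
  b <- matrix(sample(0:4, 40 * 12, replace = TRUE), 40, 12)
  b[, 2] <- b[, 1]
  e <- matrix(0L, 40, 12); e[1:20, 2] <- 3L
  ch <- HonosCohort(b, e, delay_days = rep(365, 40),
                    age = rep(30L, 40), gender = rep("male", 40))
  expect_error(fitResponseLogistic(ch), "collinear")
})

test_that("unknown-gender rows are dropped with a warning", {
  set.seed(71)
  n <- 60
  b <- matrix(sample(0:4, n * 12, replace = TRUE), n, 12)
  e <- matrix(0L, n, 12); e[1:30, 2] <- 3L
  gender <- sample(c("male", "female"), n, replace = TRUE)
  gender[1:3] <- "unknown"
  ch <- HonosCohort(b, e, delay_days = rep(365, n),
                    age = sample(20:70, n, replace = TRUE), gender = gender)
  expect_warning(fit <- fitResponseLogistic(ch), "unknown gender")
  expect_equal(fit$nUsed, n - 3L)
})

test_that("item summary table mirrors the per-item layout", {
  sim <- simulateDefaultCohort(n = 60, seed = 13)
  tab <- itemSummaryTable(sim$cohort)
  expect_equal(tab$item, honosItems())
  expect_equal(tab$baseline_mean, unname(colMeans(baselineScores(sim$cohort))))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  tabH <- itemSummaryTable(sim$cohort, adjust = "holm")
  expect_true(all(tabH$p_adjusted >= tabH$p - 1e-12))
})
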
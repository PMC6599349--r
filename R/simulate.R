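# Latent Gaussian copula cohort simulator.  Scores arise by thresholding a
# latent multivariate normal whose correlation matrix is implied by a known
# sparse partial-correlation network, so downstream network estimation has a
# recoverable ground truth; the SKEPTIC estimator is consistent exactly under
# this data-generating model, which makes recovery tests fair.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Reference HoNOS item-mean profiles for the simulator
#'
#' Default target marginal means per item: a severe community mental-health
#' cohort at entry to the service (`baseline`) and the same cohort roughly
#' one year into treatment (`endpoint`), with most items improved and
#' physical-health/living-conditions items nearly unchanged.
#'
#' @param occasion `"baseline"` or `"endpoint"`.
#' @return Named numeric vector of 12 target means, each in (0, 4).
#' @export
referenceItemMeans <- function(occasion = c("baseline", "endpoint")) {
  occasion <- match.arg(occasion)
  m <- switch(occasion,
    baseline = c(0.87, 0.69, 0.53, 0.61, 0.76, 1.01,
                 1.68, 1.96, 1.58, 0.99, 0.33, 0.92),
    endpoint = c(0.32, 0.33, 0.20, 0.30, 0.80, 0.48,
                 1.01, 1.61, 1.01, 0.77, 0.23, 0.51))
  names(m) <- honosItems()
  m
}

#' Ordinal mean implied by latent-normal thresholds
#'
#' For cutpoints `t1 < t2 < t3 < t4` applied to a standard normal latent
#' variable, the expected category is `sum_k (1 - pnorm(t_k))`.
#'
#' @param thresholds Numeric vector of 4 increasing cutpoints, or a p-by-4
#'   matrix of them.
#' @param shift Latent mean shift subtracted from the latent variable
#'   (equivalently added to the cutpoints).
#' @return Implied mean(s) in (0, 4).
#' @export
impliedOrdinalMean <- function(thresholds, shift = 0) {
  if (is.matrix(thresholds))
    return(apply(thresholds, 1L, impliedOrdinalMean, shift = shift))
  sum(1 - stats::pnorm(thresholds + shift))
}

#' Choose per-item thresholds matching target ordinal means
#'
#' Cutpoints are equally spaced (`spacing` apart) and shifted per item by a
#' monotone one-dimensional root search until the implied ordinal mean under
#' a standard normal latent equals the target (to far better than the 0.05
#' documentation tolerance).
#'
#' @param targetMeans Numeric vector of target means, each strictly inside
#'   (0, 4).
#' @param spacing Gap between consecutive cutpoints on the latent scale.
#' @return A `length(targetMeans)`-by-4 matrix of increasing cutpoints.
#' @examples
#' th <- defaultMarginalThresholds(c(2, 1.68))
#' impliedOrdinalMean(th)
#' @export
defaultMarginalThresholds <- function(targetMeans, spacing = 0.8) {
  stopifnot(spacing > 0)
  if (any(targetMeans <= 0 | targetMeans >= 4))
    stop("target means must lie strictly inside (0, 4)")
  base <- (0:3) * spacing
  t(vapply(targetMeans, function(m) {
    f <- function(c) sum(1 - stats::pnorm(base + c)) - m
    c0 <- stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
    base + c0
  }, numeric(4L)))
}

#' Latent mean shifts reproducing endpoint target means
#'
#' Given baseline-calibrated thresholds, finds the per-item latent mean
#' decrease such that the implied ordinal mean at end point matches the
#' target; improvement is encoded as a latent shift (not a threshold change)
#' so the network structure keeps its interpretation.
#'
#' @param thresholds p-by-4 threshold matrix (e.g. from
#'   [defaultMarginalThresholds()]).
#' @param targetMeans Target end-point means, each in (0, 4).
#' @return Numeric vector of shifts (positive = improvement).
#' @export
improvementShiftFor <- function(thresholds, targetMeans) {
  stopifnot(nrow(thresholds) == length(targetMeans))
  if (any(targetMeans <= 0 | targetMeans >= 4))
    stop("target means must lie strictly inside (0, 4)")
  vapply(seq_along(targetMeans), function(i) {
    f <- function(s) impliedOrdinalMean(thresholds[i, ], shift = s) -
      targetMeans[i]
    stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
  }, numeric(1L))
}

#' Generate a ground-truth partial-correlation network
#'
#' Draws a random graph with the requested edge density, assigns each edge a
#' uniform weight in `weightRange` with random sign, and builds the
#' corresponding precision matrix (unit diagonal, off-diagonal `-w`).  If the
#' precision is not positive definite, all weights are shrunk toward zero by
#' a fixed factor (0.9) until it is; the returned `partials` are the shrunk
#' values, so the bundle is always internally consistent
#' (`partials == -K_ij / sqrt(K_ii K_jj)` for the implied precision).
#'
#' @param p Node count (>= 2).
#' @param density Expected fraction of the `p(p-1)/2` node pairs carrying an
#'   edge, in `[0, 1]`.
#' @param weightRange Length-2 positive range of absolute edge weights.
#' @param seed Integer seed (the draw is reproducible).
#' @param targetMeans Target ordinal means for the threshold calibration;
#'   defaults to [referenceItemMeans()] for `p = 12`, else a flat 2.0.
#' @param maxShrink Maximum number of shrink iterations before giving up.
#' @return A [TrueNetworkBundle-class].
#' @export
makeTrueNetwork <- function(p = 12L, density, weightRange = c(0.2, 0.35),
                            seed = NULL, targetMeans = NULL,
                            maxShrink = 200L) {
  stopifnot(p >= 2L, density >= 0, density <= 1,
            length(weightRange) == 2L, all(weightRange > 0),
            weightRange[1] <= weightRange[2])
  .withSeed(seed, {
    npair <- p * (p - 1L) / 2L
    edge <- stats::rbinom(npair, 1L, density) == 1L
    w <- numeric(npair)
    w[edge] <- stats::runif(sum(edge), weightRange[1], weightRange[2]) *
      sample(c(-1, 1), sum(edge), replace = TRUE)
    W <- matrix(0, p, p)
    W[upper.tri(W)] <- w
    W <- W + t(W)
    shrink <- 1
    for (i in seq_len(maxShrink)) {
      K <- diag(p) - shrink * W
      if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) > 1e-3)
        break
      shrink <- shrink * 0.9
      if (i == maxShrink)
        stop("cannot reach a positive-definite precision within the ",
             "allowed shrink iterations; narrow the weight range")
    }
    K <- diag(p) - shrink * W
    sigma <- stats::cov2cor(solve(K))
    sigma <- (sigma + t(sigma)) / 2
    if (is.null(targetMeans))
      targetMeans <- if (p == .N_ITEMS) referenceItemMeans("baseline")
                     else rep(2, p)
    partials <- shrink * W
    diag(partials) <- 0
    methods::new("TrueNetworkBundle", partials = partials, sigma = sigma,
                 thresholds = defaultMarginalThresholds(targetMeans))
  })
}

#' Simulation settings for a paired ordinal cohort
#'
#' @param nPatients Number of paired patients (>= 2).
#' @param delayMean,delaySd Mean and SD (days) of the normal follow-up delay,
#'   truncated below at 1 day.  Defaults emulate a roughly one-year
#'   follow-up with substantial spread (462.1 and 170.3 days).
#' @param crossOccasionCorrelation Correlation in `[0, 1)` between the
#'   baseline and end-point latent noise of each patient (within-patient
#'   trait stability).
#' @param improvementShift Per-item latent mean decrease at end point;
#'   `NULL` means "derive from the reference end-point means via
#'   [improvementShiftFor()] at sampling time".
#' @param seed Integer seed.
#' @return Validated settings list of class `SimConfig`.
#' @export
simConfig <- function(nPatients = 137L, delayMean = 462.1, delaySd = 170.3,
                      crossOccasionCorrelation = 0.3,
                      improvementShift = NULL, seed = 1L) {
  stopifnot(nPatients >= 2L, delaySd >= 0, delayMean >= 1,
            crossOccasionCorrelation >= 0, crossOccasionCorrelation < 1)
  structure(list(nPatients = as.integer(nPatients), delayMean = delayMean,
                 delaySd = delaySd,
                 crossOccasionCorrelation = crossOccasionCorrelation,
                 improvementShift = improvementShift,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Sample a paired ordinal cohort from ground-truth networks
#'
#' Per patient, a 12-dimensional latent normal is drawn from the baseline
#' bundle's correlation matrix; the end-point latent reuses the same
#' standard-normal noise with weight `crossOccasionCorrelation` (plus fresh
#' noise) mapped through the end-point bundle's structure, then its mean is
#' lowered by the per-item improvement shift.  Scores are the category of
#' each latent value against the item's thresholds; delays are
#' normal(delayMean, delaySd) truncated at 1 day; age and gender are drawn
#' independently of everything else (so they are genuine null predictors of
#' response).
#'
#' @param bundleBase,bundleEnd [TrueNetworkBundle-class] objects with
#'   `p = 12`.
#' @param config A [simConfig()] list.
#' @return A list with `cohort` (a [HonosCohort-class]) and `truth` (the two
#'   bundles, the realized improvement shift, and the config).
#' @export
sampleOrdinalCohort <- function(bundleBase, bundleEnd, config = simConfig()) {
  stopifnot(methods::is(bundleBase, "TrueNetworkBundle"),
            methods::is(bundleEnd, "TrueNetworkBundle"),
            nrow(truePartials(bundleBase)) == .N_ITEMS,
            nrow(truePartials(bundleEnd)) == .N_ITEMS,
            inherits(config, "SimConfig"))
  shift <- config$improvementShift
  if (is.null(shift))
    shift <- improvementShiftFor(trueThresholds(bundleEnd),
                                 referenceItemMeans("endpoint"))
  stopifnot(length(shift) == .N_ITEMS)
  .withSeed(config$seed, {
    n <- config$nPatients
    p <- .N_ITEMS
    rho <- config$crossOccasionCorrelation
    Ub <- chol(trueSigma(bundleBase))
    Ue <- chol(trueSigma(bundleEnd))
    Z1 <- matrix(stats::rnorm(n * p), n, p)
    Z2 <- rho * Z1 + sqrt(1 - rho^2) * matrix(stats::rnorm(n * p), n, p)
    Xb <- Z1 %*% Ub
    Xe <- sweep(Z2 %*% Ue, 2L, shift)
    cut <- function(X, th) {
      s <- vapply(seq_len(p),
                  function(j) findInterval(X[, j], th[j, ]),
                  integer(nrow(X)))
      storage.mode(s) <- "integer"
      s
    }
    sb <- cut(Xb, trueThresholds(bundleBase))
    se <- cut(Xe, trueThresholds(bundleEnd))
    delays <- if (config$delaySd == 0) rep(config$delayMean, n) else {
      plo <- stats::pnorm(1, config$delayMean, config$delaySd)
      stats::qnorm(plo + stats::runif(n) * (1 - plo),
                   config$delayMean, config$delaySd)
    }
    age <- pmin(pmax(as.integer(round(stats::rnorm(n, 42, 12))), 18L), 90L)
    gender <- sample(c("male", "female"), n, replace = TRUE)
    cohort <- HonosCohort(baseline = sb, endpoint = se, delay_days = delays,
                          age = age, gender = gender)
    list(cohort = cohort,
         truth = list(baseline = bundleBase, endpoint = bundleEnd,
                      improvementShift = shift, config = config))
  })
}

#' Simulate a default study-like cohort
#'
#' Convenience wrapper: builds a sparse baseline truth and a denser
#' end-point truth (the qualitative regime of a cohort whose symptom network
#' tightens over treatment), calibrates marginals to the reference item
#' means, and samples a paired cohort.  Sub-seeds for the two network draws
#' and the cohort draw are derived deterministically from `seed`.
#'
#' @param n Number of patients.
#' @param seed Master integer seed.
#' @param densityBase,densityEnd Edge densities of the two ground-truth
#'   networks.
#' @param weightRange Absolute edge-weight range.
#' @param ... Further arguments passed to [simConfig()].
#' @return As [sampleOrdinalCohort()].
#' @export
simulateDefaultCohort <- function(n = 137L, seed = 1L,
                                  densityBase = 0.08, densityEnd = 0.30,
                                  weightRange = c(0.2, 0.35), ...) {
  seed <- as.integer(seed)
  base <- makeTrueNetwork(12L, densityBase, weightRange,
                          seed = (seed * 3L + 1L) %% 2147483629L)
  endb <- makeTrueNetwork(12L, densityEnd, weightRange,
                          seed = (seed * 3L + 2L) %% 2147483629L,
                          targetMeans = referenceItemMeans("baseline"))
  sampleOrdinalCohort(base, endb,
                      simConfig(nPatients = n, seed = seed, ...))
}
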
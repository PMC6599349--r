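#' Case-drop bootstrap stability of a centrality measure
#'
#' For each drop proportion, repeatedly subsamples the cases without
#' replacement, re-runs the full network estimation on the subsample, and
#' correlates (Pearson, across the 12 nodes) the subsample centrality with
#' the full-sample centrality.  The correlation-stability (CS) coefficient
#' is the largest drop proportion at which that correlation is at least
#' `corThreshold` in at least `confidence` of the subsamples; a measure
#' should only be interpreted when CS passes `passThreshold`.  A subsample
#' (or full sample) with a degenerate all-zero or constant centrality
#' contributes a correlation of 0.
#'
#' @param data n-by-12 residual matrix; n must leave at least 13 rows after
#'   the largest drop.
#' @param measure `"strength"` (default), `"closeness"` or `"betweenness"`.
#' @param nBoots Subsamples per drop proportion (default 1000).
#' @param dropProportions Fractions of cases dropped (default 0.1..0.7).
#' @param corThreshold,confidence CS definition constants (defaults 0.7 and
#'   0.95).
#' @param passThreshold Minimum CS for interpretability (default 0.25).
#' @param gamma,nLambda,lambdaMinRatio Passed to the network estimator.
#' @param seed Integer seed.
#' @return A [StabilityResult-class]; its `correlations` slot stores the
#'   full nBoots-by-length(dropProportions) draw matrix so the CS can be
#'   recomputed or re-thresholded.
#' @export
casedropStability <- function(data, measure = c("strength", "closeness",
                                                "betweenness"),
                              nBoots = 1000L,
                              dropProportions = seq(0.1, 0.7, by = 0.1),
                              corThreshold = 0.7, confidence = 0.95,
                              passThreshold = 0.25, gamma = 0,
                              nLambda = 100L, lambdaMinRatio = 0.01,
                              seed = 1L) {
  measure <- match.arg(measure)
  data <- as.matrix(data)
  n <- nrow(data)
  keepMin <- n - floor(max(dropProportions) * n)
  if (keepMin < 13L)
    stop("sample too small: the largest drop proportion must leave >= 13 rows")
  centr <- function(x) {
    S <- suppressWarnings(skepticCorrelation(x))$values
    est <- .estimateFromCorrelation(S, nrow(x), gamma, nLambda,
                                    lambdaMinRatio)
    K <- est$Ks[, , est$selected]
    d <- 1 / sqrt(diag(K))
    w <- -K * tcrossprod(d)
    diag(w) <- 0
    dimnames(w) <- dimnames(S)
    .centralityVector(w, measure)
  }
  full <- centr(data)
  safeCor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  }
  .withSeed(seed, {
    cors <- matrix(NA_real_, nBoots, length(dropProportions))
    for (j in seq_along(dropProportions)) {
      m <- n - floor(dropProportions[j] * n)
      for (b in seq_len(nBoots)) {
        sub <- data[sample.int(n, m), , drop = FALSE]
        ci <- tryCatch(centr(sub), error = function(e) rep(0, ncol(data)))
        cors[b, j] <- safeCor(full, ci)
      }
    }
    cs <- csFromCorrelations(cors, dropProportions, corThreshold,
                              confidence)
    methods::new("StabilityResult", measure = measure, csCoefficient = cs,
                 dropProportions = dropProportions, correlations = cors,
                 corThreshold = corThreshold, confidence = confidence,
                 passThreshold = passThreshold,
                 passes = cs >= passThreshold, seed = as.integer(seed))
  })
}

#' Recompute a CS-coefficient from stored bootstrap correlations
#'
#' @param cors nBoots-by-nDrops matrix of subsample/full-sample centrality
#'   correlations (e.g. the `correlations` slot of a
#'   [StabilityResult-class]).
#' @param dropProportions The drop proportion of each column.
#' @param corThreshold,confidence CS definition constants.
#' @return The CS-coefficient: the largest drop proportion whose column has
#'   at least `confidence` of its correlations `>= corThreshold`, or 0 if
#'   none does.
#' @export
csFromCorrelations <- function(cors, dropProportions, corThreshold = 0.7,
                                confidence = 0.95) {
  ok <- colMeans(cors >= corThreshold) >= confidence
  if (!any(ok)) 0 else max(dropProportions[ok])
}
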
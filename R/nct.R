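#' Permutation network-comparison test of global strength
#'
#' Two-tailed permutation test of the difference in overall connectivity
#' between two samples.  The observed statistic is the absolute difference
#' in global strength between the networks estimated on the two samples
#' (full pipeline: SKEPTIC correlation + EBIC-selected graphical lasso with
#' the same `gamma`).  The null distribution regroups the pooled
#' individuals at random into two groups of the original sizes and re-runs
#' the complete estimation on each regrouped sample.  The p-value uses the
#' add-one convention `(1 + #\{perm >= obs\}) / (1 + nPermutations)` so it
#' is never 0.
#'
#' The default scheme regroups individuals freely even when the two samples
#' are the two occasions of one paired cohort; `paired = TRUE` instead
#' swaps the two occasions within a random subset of patients (a
#' methodological variant that respects the pairing).
#'
#' @param dataA,dataB n-by-12 residual matrices (each n >= 3, same items).
#' @param nPermutations Number of regroupings (default 1000).
#' @param gamma,nLambda,lambdaMinRatio Passed to the network estimator.
#' @param paired Use within-patient occasion swapping (requires equal row
#'   counts) instead of free regrouping.
#' @param seed Integer seed for the permutations.
#' @return An [NctResult-class].
#' @export
nctGlobalStrength <- function(dataA, dataB, nPermutations = 1000L,
                              gamma = 0, nLambda = 100L,
                              lambdaMinRatio = 0.01, paired = FALSE,
                              seed = 1L) {
  dataA <- as.matrix(dataA)
  dataB <- as.matrix(dataB)
  stopifnot(ncol(dataA) == ncol(dataB), nrow(dataA) >= 3L,
            nrow(dataB) >= 3L, nPermutations >= 1L)
  if (paired && nrow(dataA) != nrow(dataB))
    stop("paired permutation requires equal sample sizes")
  gs <- function(x) {
    S <- suppressWarnings(skepticCorrelation(x))$values
    est <- .estimateFromCorrelation(S, nrow(x), gamma, nLambda,
                                    lambdaMinRatio)
    K <- est$Ks[, , est$selected]
    d <- 1 / sqrt(diag(K))
    w <- -K * tcrossprod(d)
    diag(w) <- 0
    sum(abs(w[upper.tri(w)]))
  }
  observed <- abs(gs(dataA) - gs(dataB))
  nA <- nrow(dataA)
  pooled <- rbind(dataA, dataB)
  nTot <- nrow(pooled)
  .withSeed(seed, {
    perms <- numeric(nPermutations)
    failures <- 0L
    for (b in seq_len(nPermutations)) {
      if (paired) {
        swap <- stats::runif(nA) < 0.5
        ia <- ifelse(swap, nA + seq_len(nA), seq_len(nA))
        ib <- ifelse(swap, seq_len(nA), nA + seq_len(nA))
      } else {
        ia <- sample.int(nTot, nA)
        ib <- setdiff(seq_len(nTot), ia)
      }
      perms[b] <- tryCatch(
        abs(gs(pooled[ia, , drop = FALSE]) -
              gs(pooled[ib, , drop = FALSE])),
        error = function(e) NA_real_)
      failures <- failures + is.na(perms[b])
      if (failures > 0.05 * nPermutations)
        stop("network estimation failed in more than 5% of permutations; ",
             "the samples are too degenerate for the comparison test")
    }
    perms[is.na(perms)] <- Inf  # conservative for the few allowed failures
    pv <- (1 + sum(perms >= observed)) / (1 + nPermutations)
    methods::new("NctResult", observedDifference = observed,
                 permutationDifferences = perms, pValue = pv,
                 nPermutations = as.integer(nPermutations),
                 seed = as.integer(seed))
  })
}
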
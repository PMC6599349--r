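# Sparse partial-correlation network estimation: SKEPTIC rank correlation,
# graphical-lasso path, EBIC model selection, precision -> partial
# conversion.

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected tau: `(C - D) / sqrt((n0 - n1)(n0 - n2))` with
#' `n0 = n(n-1)/2` and `n1`, `n2` the tied-pair counts of the two inputs
#' (computed by an O(n log n) merge-sort algorithm).
#'
#' @param x,y Numeric vectors of equal length (n >= 2).
#' @return tau-b in `[-1, 1]`; 0 with a warning when either input is
#'   constant (tau is undefined there).
#' @export
kendallTauB <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  t <- .kendallTauCpp(as.numeric(x), as.numeric(y))
  if (is.na(t)) {
    warning("constant input, Kendall's tau is undefined; returning 0")
    return(0)
  }
  t
}

# eigenvalue clipping at `floor`, then rescaling to unit diagonal
.repairPSD <- function(R, floor = 1e-4) {
  ee <- eigen(R, symmetric = TRUE)
  v <- pmax(ee$values, floor)
  out <- ee$vectors %*% (v * t(ee$vectors))
  out <- stats::cov2cor(out)
  (out + t(out)) / 2
}

#' Nonparanormal SKEPTIC correlation matrix
#'
#' Entrywise `r_ij = sin(pi/2 * tau_ij)` from pairwise Kendall tau-b, unit
#' diagonal: a rank-based estimator of the latent correlation matrix that is
#' consistent under a Gaussian copula without assuming normal margins.  A
#' result that is not positive semi-definite is repaired by clipping
#' eigenvalues at `1e-4` and rescaling to unit diagonal.
#'
#' @param residuals n-by-p numeric matrix (n >= 3); typically the output of
#'   [residualizeOnDelay()].
#' @return A list with `values` (the p-by-p correlation matrix) and
#'   `psdRepaired` (flag).  Correlations of constant columns are set to 0
#'   with a warning.
#' @export
skepticCorrelation <- function(residuals) {
  residuals <- as.matrix(residuals)
  stopifnot(nrow(residuals) >= 3L)
  tau <- .tauMatrixCpp(residuals)
  if (anyNA(tau)) {
    warning("constant column(s); their correlations are set to 0")
    tau[is.na(tau)] <- 0
  }
  R <- sin(pi / 2 * tau)
  diag(R) <- 1
  dimnames(R) <- list(colnames(residuals), colnames(residuals))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  repaired <- min(ev) < 1e-8
  if (repaired) {
    dn <- dimnames(R)
    R <- .repairPSD(R)
    dimnames(R) <- dn
  }
  list(values = R, psdRepaired = repaired)
}

#' Graphical lasso at a single penalty
#'
#' Maximizes `log det K - tr(SK) - lambda * sum_{i != j} |K_ij|` (penalty on
#' off-diagonal entries only) by block coordinate descent; errors if the
#' duality gap has not fallen below `gapTol` within `maxit` sweeps.
#'
#' @param S Positive-definite correlation/covariance matrix.
#' @param lambda Non-negative penalty.
#' @param gapTol Required duality gap at return (default 1e-6).
#' @param maxit Maximum coordinate-descent sweeps.
#' @return A list with the precision matrix `K` (symmetric PD), the duality
#'   `gap` and the sweep count `niter`.
#' @export
graphicalLasso <- function(S, lambda, gapTol = 1e-6, maxit = 1000L) {
  S <- as.matrix(S)
  stopifnot(isSymmetric(S, tol = 1e-8), lambda >= 0)
  fit <- .glassoCpp(S, lambda, tol = 1e-5, gap_tol = gapTol, maxit = maxit)
  if (!(fit$gap < gapTol))
    stop(sprintf("graphical lasso did not converge: duality gap %.2e after %d sweeps",
                 fit$gap, fit$niter))
  K <- fit$K
  dimnames(K) <- dimnames(S)
  list(K = K, gap = fit$gap, niter = fit$niter)
}

#' Extended Bayesian information criterion of a precision matrix
#'
#' `EBIC = -2 L + E log n + 4 E gamma log p` with Gaussian log-likelihood
#' `L = (n/2)(log det K - tr(SK))` and `E` the number of nonzero
#' off-diagonal upper-triangle entries (`|K_ij| > 1e-10`).  `gamma = 0`
#' reduces to the ordinary BIC.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @param S The correlation matrix the model was fit to.
#' @param n Sample size (>= 3).
#' @param gamma Model-space penalty hyperparameter (>= 0).
#' @return The EBIC value (finite for PD `K`).
#' @export
ebic <- function(K, S, n, gamma = 0) {
  stopifnot(n >= 3, gamma >= 0)
  cl <- tryCatch(chol(K), error = function(e)
    stop("precision matrix is singular or not positive definite"))
  logdet <- 2 * sum(log(diag(cl)))
  L <- n / 2 * (logdet - sum(S * K))
  E <- sum(abs(K[upper.tri(K)]) > 1e-10)
  -2 * L + E * log(n) + 4 * E * gamma * log(nrow(K))
}

#' Convert a precision matrix to a partial-correlation network
#'
#' `w_ij = -K_ij / sqrt(K_ii K_jj)` off the diagonal, 0 on it: the partial
#' correlation of each pair of variables given all remaining ones.
#'
#' @param K Symmetric precision matrix with positive diagonal.
#' @return A [WeightedNetwork-class].
#' @export
precisionToPartial <- function(K) {
  K <- as.matrix(K)
  stopifnot(isSymmetric(K, tol = 1e-8))
  if (any(diag(K) <= 0)) stop("precision diagonal must be positive")
  d <- 1 / sqrt(diag(K))
  w <- -K * tcrossprod(d)
  diag(w) <- 0
  dimnames(w) <- dimnames(K)
  WeightedNetwork((w + t(w)) / 2)
}

# internal: lambda path + EBIC selection on a ready correlation matrix;
# the hot loop of the NCT/bootstrap machinery, so it returns plain matrices
.estimateFromCorrelation <- function(S, n, gamma = 0, nLambda = 100L,
                                     lambdaMinRatio = 0.01,
                                     gapTol = 1e-6) {
  p <- nrow(S)
  lmax <- max(abs(S[upper.tri(S)]), 1e-3)  # floor guards all-zero S
  lambdas <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                     length.out = nLambda))
  path <- .glassoPathCpp(S, lambdas, tol = 1e-4, gap_tol = gapTol,
                         maxit = 1000L)
  if (any(!(path$gap < gapTol)))
    stop(sprintf("graphical lasso did not converge at lambda %.4g (gap %.2e)",
                 lambdas[which(!(path$gap < gapTol))[1L]],
                 max(path$gap)))
  E <- as.integer(path$E)
  ebicv <- -n * (as.numeric(path$logdet) - as.numeric(path$trSK)) +
    E * log(n) + 4 * E * gamma * log(p)
  sel <- which(ebicv <= min(ebicv) + 1e-9)[1L]  # ties -> larger lambda
  list(lambdas = lambdas, Ks = path$K, E = E, ebic = ebicv,
       selected = sel)
}

#' Estimate an EBIC-selected partial-correlation network
#'
#' The full estimation pipeline on a residual matrix: SKEPTIC correlation,
#' a log-spaced decreasing lambda path from `lambda_max` (the largest
#' absolute off-diagonal correlation) down to
#' `lambda_max * lambdaMinRatio`, one graphical-lasso fit per lambda
#' (warm-started), EBIC per fit, and selection of the EBIC-minimising model
#' (ties resolved toward the larger lambda, i.e. the sparser model).  The
#' procedure is deterministic.
#'
#' @param residuals n-by-12 numeric matrix (n >= 3).
#' @param gamma EBIC hyperparameter; the analysis preset for this pipeline
#'   is 0 (ordinary BIC) — higher values prune real edges at these sample
#'   sizes.
#' @param nLambda Number of path points (default 100).
#' @param lambdaMinRatio Smallest lambda as a fraction of `lambda_max`
#'   (default 0.01).
#' @return A list with `network` (a [WeightedNetwork-class]) and `fit`
#'   (a [GlassoFit-class]).
#' @export
estimateNetwork <- function(residuals, gamma = 0, nLambda = 100L,
                            lambdaMinRatio = 0.01) {
  sk <- skepticCorrelation(residuals)
  n <- nrow(as.matrix(residuals))
  est <- .estimateFromCorrelation(sk$values, n, gamma, nLambda,
                                  lambdaMinRatio)
  precisions <- lapply(seq_along(est$lambdas), function(i) {
    Ki <- est$Ks[, , i]
    dimnames(Ki) <- dimnames(sk$values)
    Ki
  })
  fit <- methods::new("GlassoFit", lambdaPath = est$lambdas,
                      precisions = precisions, ebicValues = est$ebic,
                      edgeCounts = as.integer(est$E), gamma = gamma,
                      selectedIndex = as.integer(est$selected),
                      n = as.integer(n), correlation = sk$values,
                      psdRepaired = sk$psdRepaired)
  # along the decreasing-lambda path the edge count should not drop
  if (any(diff(est$E) < 0L))
    message("note: edge count not monotone in lambda (",
            sum(diff(est$E) < 0L), " drop(s) along the path)")
  list(network = precisionToPartial(precisions[[est$selected]]),
       fit = fit)
}
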
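# Independent brute-force oracles used to freeze expected values.  Each is
# deliberately naive (loops, enumeration, generic optimisation) and shares
# no code with the implementation it checks.

# O(n^2) pair-count Kendall tau-b
bruteTauB <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
      s <- sign(dx) * sign(dy)
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) NA_real_ else (C - D) / den
}

# exact two-sided signed-rank p by full 2^m sign enumeration (midranks kept)
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  tot <- sum(r)
  lo <- min(vObs, tot - vObs)
  hi <- max(vObs, tot - vObs)
  vs <- vapply(seq_len(2^m) - 1L, function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0])
  }, numeric(1))
  min(1, mean(vs <= lo + 1e-9) + mean(vs >= hi - 1e-9))
}

# explicit normal-equation OLS residuals of each column on (1, delay)
bruteOLSResiduals <- function(scores, delays) {
  X <- cbind(1, delays)
  XtXinv <- solve(t(X) %*% X)
  apply(scores, 2L, function(y) y - X %*% (XtXinv %*% (t(X) %*% y)))
}

# all-pairs shortest-path distances with edge lengths 1/|w|, Floyd-Warshall
floydWarshallDistances <- function(w) {
  p <- nrow(w)
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  for (i in seq_len(p)) for (j in seq_len(p))
    if (i != j && w[i, j] != 0) D[i, j] <- 1 / abs(w[i, j])
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bruteCloseness <- function(w) {
  D <- floydWarshallDistances(w)
  p <- nrow(w)
  vapply(seq_len(p), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / mean(d)
  }, numeric(1))
}

# betweenness from shortest-path counts: sigma via distance-ordered DP,
# then pair-summed fractional contributions
bruteBetweenness <- function(w, tol = 1e-9) {
  p <- nrow(w)
  D <- floydWarshallDistances(w)
  len <- ifelse(w == 0, Inf, 1 / abs(w))
  sigma <- matrix(0, p, p)
  for (s in seq_len(p)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      for (v in seq_len(p)) {
        if (v != t && is.finite(len[v, t]) &&
            abs(D[s, v] + len[v, t] - D[s, t]) < tol)
          sigma[s, t] <- sigma[s, t] + sigma[s, v]
      }
    }
  }
  btw <- numeric(p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
    for (v in seq_len(p)) {
      if (v == s || v == t) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) < tol)
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  btw
}

# penalised glasso objective (minimisation form)
glassoObjective <- function(K, S, lambda) {
  -determinant(K, logarithm = TRUE)$modulus[1] + sum(S * K) +
    2 * lambda * sum(abs(K[upper.tri(K)]))
}

# generic-optimiser oracle for the 3-variable glasso: Nelder-Mead over the
# Cholesky factor, multi-start
gridGlassoOracle3 <- function(S, lambda, starts = 8L, seed = 1L) {
  obj <- function(par) {
    L <- matrix(0, 3, 3)
    diag(L) <- exp(par[1:3])
    L[lower.tri(L)] <- par[4:6]
    K <- L %*% t(L)
    glassoObjective(K, S, lambda)
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(starts)) {
    p0 <- c(rnorm(3, 0, 0.3), rnorm(3, 0, 0.3))
    for (i in 1:3) {
      o <- optim(p0, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
      p0 <- o$par
    }
    best <- min(best, o$value)
  }
  best
}
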
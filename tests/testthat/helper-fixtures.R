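# Small deterministic fixtures, built in code at test time.

# cohort with prescribed counts of baseline-severe / responder patients
fixedCohort <- function(nSevere, nNonSevere = 0L, nResponders = nSevere,
                        delay = 400) {
  n <- nSevere + nNonSevere
  stopifnot(nResponders <= nSevere)
  b <- matrix(1L, n, 12)
  b[seq_len(nSevere), 1L] <- 3L          # severe at baseline
  e <- matrix(1L, n, 12)
  if (nResponders < nSevere)             # non-responders keep a 3 at endpoint
    e[(nResponders + 1L):nSevere, 2L] <- 3L
  HonosCohort(b, e, delay_days = rep(delay, n),
              age = rep(40L, n),
              gender = rep(c("male", "female"), length.out = n))
}

# a TrueNetworkBundle with exactly the given edges (i, j, weight)
fixedBundle <- function(edges, p = 12L) {
  W <- matrix(0, p, p)
  for (k in seq_len(nrow(edges)))
    W[edges[k, 1], edges[k, 2]] <- W[edges[k, 2], edges[k, 1]] <- edges[k, 3]
  K <- diag(p) - W
  stopifnot(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) > 0)
  sigma <- cov2cor(solve(K))
  partials <- W; diag(partials) <- 0
  methods::new("TrueNetworkBundle", partials = partials,
               sigma = (sigma + t(sigma)) / 2,
               thresholds = defaultMarginalThresholds(
                 referenceItemMeans("baseline")[seq_len(p)]))
}

# random symmetric zero-diagonal weight matrix
randomWeights <- function(p = 12L, density = 0.3, seed = 1L) {
  set.seed(seed)
  w <- matrix(0, p, p)
  up <- upper.tri(w)
  vals <- runif(sum(up), -0.8, 0.8) * (runif(sum(up)) < density)
  w[up] <- vals
  w + t(w)
}

# upper-triangle edge indicator of a matrix
edgeVec <- function(m, tol = 1e-10) abs(m[upper.tri(m)]) > tol
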
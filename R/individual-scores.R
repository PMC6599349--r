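# The "individual scores" analysis arm: per-item paired Wilcoxon
# signed-rank tests, treatment-response classification, and a logistic
# regression of response on baseline items, age and gender.

#' Paired Wilcoxon signed-rank test
#'
#' Tests a location shift between paired ordinal ratings.  Differences are
#' taken as `baseline - endpoint` (so improvement gives a large statistic),
#' zero differences are dropped (the classic Wilcoxon treatment), absolute
#' differences are ranked with midranks under ties, and
#' `V = sum of ranks of positive differences`.  The two-sided p-value is
#' exact — from the generating-function distribution of V over all sign
#' assignments, valid under ties — when the number of non-zero pairs is at
#' most `exactLimit`; above it, the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param baseline,endpoint Equal-length numeric vectors (n >= 2).
#' @param exactLimit Largest `nEffective` for which the exact distribution
#'   is used (default 25).
#' @return A list with `V`, `pValue`, `nEffective`, `method`
#'   (`"exact"`/`"normal"`) and `degenerate` (TRUE when all differences are
#'   zero: then `V = 0`, `p = 1`).
#' @examples
#' pairedWilcoxon(c(3, 2, 4, 1), c(1, 1, 2, 1))
#' @export
pairedWilcoxon <- function(baseline, endpoint, exactLimit = 25L) {
  stopifnot(length(baseline) == length(endpoint), length(baseline) >= 2L)
  d <- as.numeric(baseline) - as.numeric(endpoint)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    return(list(V = 0, pValue = 1, nEffective = 0L, method = "exact",
                degenerate = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (m <= exactLimit) {
    p <- .wilcoxExactP(r2 = as.integer(round(2 * r)),
                       v2 = as.integer(round(2 * V)))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(ties^3 - ties) / 48
    cc <- sign(V - mu) * 0.5
    z <- (V - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(V = V, pValue = p, nEffective = m, method = method,
       degenerate = FALSE)
}

# Exact two-sided p for the signed-rank statistic with (mid)ranks r = r2/2.
# V2 = 2V = sum of r2 over positive signs; its null distribution is the
# convolution of fair coin flips weighted by r2, symmetric about T/2 with
# T = sum(r2).  p = P(V2 <= min(v2, T - v2)) + P(V2 >= max(v2, T - v2)),
# capped at 1 at the centre.
.wilcoxExactP <- function(r2, v2) {
  T <- sum(r2)
  f <- numeric(T + 1L)
  f[1L] <- 1
  for (w in r2) {
    g <- f
    g[(w + 1L):(T + 1L)] <- g[(w + 1L):(T + 1L)] + f[1L:(T + 1L - w)]
    f <- g
  }
  f <- f / sum(f)
  lo <- min(v2, T - v2)
  hi <- max(v2, T - v2)
  min(1, sum(f[seq_len(lo + 1L)]) + sum(f[(hi + 1L):(T + 1L)]))
}

#' Treatment-response status of an end-point profile
#'
#' A patient responds iff the end-point profile reaches the non-severity
#' level: no item rated 3 or above (the negation of [classifySeverity()]).
#'
#' @param endpoint Integer vector of 12 scores, or an n-by-12 matrix.
#' @return `"responder"`/`"non-responder"` per profile.
#' @export
responseStatus <- function(endpoint) {
  ifelse(classifySeverity(endpoint) == "non-severe",
         "responder", "non-responder")
}

#' Count and proportion of treatment responders
#'
#' @param cohort A [HonosCohort-class] (n >= 1).
#' @return List with `count` and `proportion` of patients whose end-point
#'   profile is non-severe.
#' @export
responseProportion <- function(cohort) {
  stopifnot(methods::is(cohort, "HonosCohort"), ncol(cohort) >= 1L)
  resp <- responseStatus(endpointScores(cohort)) == "responder"
  list(count = sum(resp), proportion = mean(resp))
}

#' Logistic regression of treatment response
#'
#' Maximum-likelihood logistic regression (IRLS, via [stats::glm()]) of
#' responder status on the 12 baseline item scores, age (years,
#' untransformed) and gender (a single male indicator).  Unknown-gender and
#' missing-age rows are dropped with a warning.  Separation is flagged when
#' any coefficient exceeds 15 on the log-odds scale, in which case the Wald
#' p-values are unreliable.
#'
#' @param cohort A [HonosCohort-class].
#' @return A list with `coefficients`, `standardErrors`, `waldPValues`
#'   (named per predictor), `converged`, `separationFlag` and `nUsed`.
#' @export
fitResponseLogistic <- function(cohort) {
  stopifnot(methods::is(cohort, "HonosCohort"))
  cd <- SummarizedExperiment::colData(cohort)
  y <- responseStatus(endpointScores(cohort)) == "responder"
  X <- baselineScores(cohort)
  colnames(X) <- make.names(colnames(X))
  keep <- cd$gender %in% c("male", "female") & !is.na(cd$age)
  if (!all(keep))
    warning(sprintf("dropping %d row(s) with unknown gender or missing age from the logistic regression",
                    sum(!keep)))
  y <- y[keep]
  df <- data.frame(response = y, X[keep, , drop = FALSE],
                   age = as.numeric(cd$age[keep]),
                   male = as.numeric(cd$gender[keep] == "male"))
  if (nrow(df) <= ncol(df) - 1L)
    stop("need more observations than predictors")
  if (length(unique(df$response)) < 2L)
    stop("outcome has a single class; the logistic model is undefined")
  mm <- stats::model.matrix(response ~ ., df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1L):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::glm(response ~ ., data = df, family = stats::binomial(),
                    control = list(epsilon = 1e-10, maxit = 100L))
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- est / se
  sep <- any(abs(est[-1L]) > 15)
  list(coefficients = est, standardErrors = se,
       waldPValues = 2 * stats::pnorm(-abs(z)),
       converged = fit$converged, separationFlag = sep,
       nUsed = nrow(df))
}

#' Per-item summary and test table
#'
#' One row per HoNOS item: baseline and end-point mean (SD) and the paired
#' Wilcoxon signed-rank V and p-value, plus an optional multiplicity
#' adjustment column (`p.adjust`; off by default because the raw per-item
#' p-values are the conventional report for this instrument).
#'
#' @param cohort A [HonosCohort-class].
#' @param adjust A [stats::p.adjust()] method, or `"none"`.
#' @return A data.frame with columns `item`, `baseline_mean`, `baseline_sd`,
#'   `endpoint_mean`, `endpoint_sd`, `V`, `p` (and `p_adjusted` unless
#'   `adjust = "none"`).
#' @export
itemSummaryTable <- function(cohort, adjust = "none") {
  b <- baselineScores(cohort)
  e <- endpointScores(cohort)
  tests <- lapply(seq_len(.N_ITEMS),
                  function(j) pairedWilcoxon(b[, j], e[, j]))
  out <- data.frame(
    item = honosItems(),
    baseline_mean = colMeans(b), baseline_sd = apply(b, 2L, stats::sd),
    endpoint_mean = colMeans(e), endpoint_sd = apply(e, 2L, stats::sd),
    V = vapply(tests, `[[`, numeric(1L), "V"),
    p = vapply(tests, `[[`, numeric(1L), "pValue"),
    row.names = NULL)
  if (!identical(adjust, "none"))
    out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  out
}
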
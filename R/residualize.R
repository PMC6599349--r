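#' Residualize item scores on the between-measurement delay
#'
#' Per item, an ordinary least-squares regression of score on (intercept,
#' delay); the returned residuals carry no linear delay trend and have
#' column means of exactly zero (to numerical precision), which is what
#' makes the per-item baseline-vs-endpoint paired t statistics on residuals
#' vanish.  Apply it separately to the baseline and the end-point score
#' matrix with the same per-patient delays.  When all delays are identical
#' the slope is undefined and the scores are simply centered.
#'
#' @param scores n-by-12 numeric matrix of ordinal scores (n >= 3).
#' @param delays n positive delays in days.
#' @return n-by-12 matrix of residuals (dimnames preserved).
#' @examples
#' s <- matrix(rep(1:3, 12), 3, 12)
#' residualizeOnDelay(s, c(1, 2, 3))  # perfect fit -> all zero
#' @export
residualizeOnDelay <- function(scores, delays) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(length(delays) == n, all(delays > 0))
  if (n < 3L) stop("residualization needs at least 3 patients")
  constant <- apply(scores, 2L, function(x) length(unique(x)) == 1L)
  if (any(constant))
    warning("constant item column(s), residuals are all zero: ",
            paste(colnames(scores)[constant], collapse = ", "))
  if (length(unique(delays)) == 1L) {
    res <- scale(scores, center = TRUE, scale = FALSE)
    attr(res, "scaled:center") <- NULL
    return(res)
  }
  X <- cbind(1, as.numeric(delays))
  fit <- stats::lm.fit(X, scores)
  res <- scores - X %*% fit$coefficients
  dimnames(res) <- dimnames(scores)
  res
}
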
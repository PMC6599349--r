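#' @name honosnet-accessors
#' @title Accessors for honosnet S4 objects
#'
#' @description Small accessor generics: score matrices and covariates of a
#' [HonosCohort], the weight matrix and labels of a [WeightedNetwork], the
#' ground-truth slots of a [TrueNetworkBundle], and the headline numbers of
#' fit/test/stability objects.
#'
#' @param x,object An object of the documented class.
#' @param ... Unused.
#' @return The documented component.
NULL

#' @rdname honosnet-accessors
#' @export
setGeneric("baselineScores", function(x, ...) standardGeneric("baselineScores"))
#' @rdname honosnet-accessors
#' @export
setGeneric("endpointScores", function(x, ...) standardGeneric("endpointScores"))
#' @rdname honosnet-accessors
#' @export
setGeneric("delayDays", function(x, ...) standardGeneric("delayDays"))
#' @rdname honosnet-accessors
#' @export
setGeneric("networkWeights", function(x, ...) standardGeneric("networkWeights"))
#' @rdname honosnet-accessors
#' @export
setGeneric("nodeLabels", function(x, ...) standardGeneric("nodeLabels"))
#' @rdname honosnet-accessors
#' @export
setGeneric("truePartials", function(x, ...) standardGeneric("truePartials"))
#' @rdname honosnet-accessors
#' @export
setGeneric("trueSigma", function(x, ...) standardGeneric("trueSigma"))
#' @rdname honosnet-accessors
#' @export
setGeneric("trueThresholds", function(x, ...) standardGeneric("trueThresholds"))
#' @rdname honosnet-accessors
#' @export
setGeneric("selectedPrecision", function(x, ...)
  standardGeneric("selectedPrecision"))
#' @rdname honosnet-accessors
#' @export
setGeneric("lambdaPath", function(x, ...) standardGeneric("lambdaPath"))
#' @rdname honosnet-accessors
#' @export
setGeneric("ebicValues", function(x, ...) standardGeneric("ebicValues"))
#' @rdname honosnet-accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))
#' @rdname honosnet-accessors
#' @export
setGeneric("observedDifference", function(x, ...)
  standardGeneric("observedDifference"))
#' @rdname honosnet-accessors
#' @export
setGeneric("csCoefficient", function(x, ...) standardGeneric("csCoefficient"))
#' @rdname honosnet-accessors
#' @export
setGeneric("stabilityPasses", function(x, ...)
  standardGeneric("stabilityPasses"))

#' Global strength of a weighted network
#'
#' Overall connectivity: the sum of absolute edge weights over all node
#' pairs, `sum_{i<j} |w_ij|`.
#'
#' @param x A [WeightedNetwork] (or a bare symmetric weight matrix).
#' @return A single non-negative number.
#' @examples
#' w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' w[1, 2] <- w[2, 1] <- 0.5
#' globalStrength(WeightedNetwork(w))
#' @export
setGeneric("globalStrength", function(x) standardGeneric("globalStrength"))

#' Node-strength centrality
#'
#' Per node, the weighted number of connections `s_i = sum_{j != i} |w_ij|`,
#' plus its z-standardization across the nodes.
#'
#' @param x A [WeightedNetwork].
#' @return A data.frame with columns `node`, `strength`, `z` (the z column is
#'   `NA` with a warning for an all-zero network).
#' @export
setGeneric("nodeStrength", function(x) standardGeneric("nodeStrength"))

#' @rdname honosnet-accessors
#' @export
setMethod("baselineScores", "HonosCohort", function(x, ...)
  t(SummarizedExperiment::assay(x, "baseline")))
#' @rdname honosnet-accessors
#' @export
setMethod("endpointScores", "HonosCohort", function(x, ...)
  t(SummarizedExperiment::assay(x, "endpoint")))
#' @rdname honosnet-accessors
#' @export
setMethod("delayDays", "HonosCohort", function(x, ...)
  SummarizedExperiment::colData(x)$delay_days)
#' @rdname honosnet-accessors
#' @export
setMethod("networkWeights", "WeightedNetwork", function(x, ...) x@weights)
#' @rdname honosnet-accessors
#' @export
setMethod("nodeLabels", "WeightedNetwork", function(x, ...)
  rownames(x@weights))
#' @rdname honosnet-accessors
#' @export
setMethod("truePartials", "TrueNetworkBundle", function(x, ...) x@partials)
#' @rdname honosnet-accessors
#' @export
setMethod("trueSigma", "TrueNetworkBundle", function(x, ...) x@sigma)
#' @rdname honosnet-accessors
#' @export
setMethod("trueThresholds", "TrueNetworkBundle", function(x, ...)
  x@thresholds)
#' @rdname honosnet-accessors
#' @export
setMethod("selectedPrecision", "GlassoFit", function(x, ...)
  x@precisions[[x@selectedIndex]])
#' @rdname honosnet-accessors
#' @export
setMethod("lambdaPath", "GlassoFit", function(x, ...) x@lambdaPath)
#' @rdname honosnet-accessors
#' @export
setMethod("ebicValues", "GlassoFit", function(x, ...) x@ebicValues)
#' @rdname honosnet-accessors
#' @export
setMethod("pValue", "NctResult", function(x, ...) x@pValue)
#' @rdname honosnet-accessors
#' @export
setMethod("observedDifference", "NctResult", function(x, ...)
  x@observedDifference)
#' @rdname honosnet-accessors
#' @export
setMethod("csCoefficient", "StabilityResult", function(x, ...)
  x@csCoefficient)
#' @rdname honosnet-accessors
#' @export
setMethod("stabilityPasses", "StabilityResult", function(x, ...) x@passes)

setMethod("show", "HonosCohort", function(object) {
  cat(sprintf("HonosCohort: %d patients x %d items (paired baseline/endpoint)\n",
              ncol(object), nrow(object)))
  d <- delayDays(object)
  cat(sprintf("  delay_days: mean %.1f, sd %.1f\n", mean(d), sd(d)))
  sev <- sum(apply(baselineScores(object), 1L, max) >= 3)
  cat(sprintf("  severe at baseline: %d/%d\n", sev, ncol(object)))
})

setMethod("show", "WeightedNetwork", function(object) {
  w <- object@weights
  e <- sum(abs(w[upper.tri(w)]) > 0)
  cat(sprintf("WeightedNetwork: %d nodes, %d edges, global strength %.3f\n",
              nrow(w), e, sum(abs(w[upper.tri(w)]))))
})

setMethod("show", "GlassoFit", function(object) {
  cat(sprintf(
    "GlassoFit: %d lambdas, gamma = %g, n = %d; selected lambda %.4f (%d edges)\n",
    length(object@lambdaPath), object@gamma, object@n,
    object@lambdaPath[object@selectedIndex],
    object@edgeCounts[object@selectedIndex]))
})

setMethod("show", "NctResult", function(object) {
  cat(sprintf(
    "NCT (global strength): observed |diff| = %.4f, p = %.4f (%d permutations)\n",
    object@observedDifference, object@pValue, object@nPermutations))
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf(
    "Case-drop stability (%s): CS = %.2f (threshold %.2f) -> %s\n",
    object@measure, object@csCoefficient, object@passThreshold,
    if (object@passes) "interpretable" else "NOT interpretable"))
})
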
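#' HonosCohort: paired per-patient HoNOS item profiles with covariates
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the two
#' paired 12-items-by-n-patients score matrices (assays `baseline` and
#' `endpoint`, each entry an integer severity rating in 0..4) together with
#' per-patient covariates in `colData`: `age` (years), `gender`
#' (`male`/`female`/`unknown`) and `delay_days` (positive delay in days
#' between the two ratings).  Column names are the unique patient ids; row
#' names are the fixed item labels of [honosItems()].
#'
#' @seealso [HonosCohort()], [readCohortCsv()], [classifySeverity()]
#' @export
setClass("HonosCohort", contains = "SummarizedExperiment")

.validHonosCohort <- function(object) {
  msg <- character()
  if (!identical(rownames(object), honosItems()))
    msg <- c(msg, "rownames must be the 12 fixed HoNOS item labels")
  if (!all(c("baseline", "endpoint") %in%
           SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'baseline' and 'endpoint' are required")
  for (a in c("baseline", "endpoint")) {
    if (a %in% SummarizedExperiment::assayNames(object)) {
      v <- SummarizedExperiment::assay(object, a)
      if (anyNA(v) || !all(v %in% 0:4))
        msg <- c(msg, sprintf("assay '%s' must contain scores in {0,..,4}", a))
    }
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("age", "gender", "delay_days")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, "colData must contain age, gender, delay_days")
  } else {
    if (any(cd$delay_days <= 0)) msg <- c(msg, "delay_days must be > 0")
    if (any(!is.na(cd$age) & cd$age <= 0)) msg <- c(msg, "age must be > 0")
    if (!all(cd$gender %in% c("male", "female", "unknown")))
      msg <- c(msg, "gender must be male/female/unknown")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "patient ids (column names) must be unique")
  if (length(msg)) msg else TRUE
}
setValidity("HonosCohort", .validHonosCohort)

#' TrueNetworkBundle: ground-truth network used by the cohort simulator
#'
#' Holds a ground-truth partial-correlation matrix (`partials`: symmetric,
#' zero diagonal, entries in (-1, 1)), the implied positive-definite latent
#' correlation matrix (`sigma`, unit diagonal), and per-item ordered
#' cutpoints (`thresholds`: a p-by-4 matrix, strictly increasing within each
#' row) mapping a latent standard normal to the ordinal categories 0..4.
#' The partials are recoverable from `solve(sigma)` by the usual sign-flip
#' and normalization, which is what the network-recovery tests exploit.
#'
#' @seealso [makeTrueNetwork()], [sampleOrdinalCohort()]
#' @export
setClass("TrueNetworkBundle",
  representation(partials = "matrix", sigma = "matrix", thresholds = "matrix"))

setValidity("TrueNetworkBundle", function(object) {
  msg <- character()
  p <- nrow(object@partials)
  if (!isSymmetric(object@partials, tol = 1e-8) ||
      any(abs(diag(object@partials)) > 1e-12))
    msg <- c(msg, "partials must be symmetric with zero diagonal")
  if (any(abs(object@partials) >= 1))
    msg <- c(msg, "partials must lie in (-1, 1)")
  if (!isSymmetric(object@sigma, tol = 1e-8) ||
      any(abs(diag(object@sigma) - 1) > 1e-8))
    msg <- c(msg, "sigma must be a correlation matrix (unit diagonal)")
  ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) msg <- c(msg, "sigma must be positive definite")
  if (nrow(object@thresholds) != p || ncol(object@thresholds) != 4L)
    msg <- c(msg, "thresholds must be a p x 4 matrix")
  if (any(apply(object@thresholds, 1L, function(t) any(diff(t) <= 0))))
    msg <- c(msg, "thresholds must be strictly increasing per item")
  if (length(msg)) msg else TRUE
})

#' WeightedNetwork: a partial-correlation symptom network
#'
#' Symmetric p-by-p matrix of partial correlations with zero diagonal and
#' labelled nodes; the output of [estimateNetwork()] and the input to the
#' strength/centrality machinery.
#'
#' @seealso [estimateNetwork()], [globalStrength()], [nodeStrength()]
#' @export
setClass("WeightedNetwork", representation(weights = "matrix"))

setValidity("WeightedNetwork", function(object) {
  w <- object@weights
  msg <- character()
  if (!isSymmetric(w, tol = 1e-8)) msg <- c(msg, "weights must be symmetric")
  if (any(abs(diag(w)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (any(abs(w) >= 1)) msg <- c(msg, "|weights| must be < 1")
  if (is.null(rownames(w))) msg <- c(msg, "nodes must be labelled")
  if (length(msg)) msg else TRUE
})

#' GlassoFit: the graphical-lasso model-selection record
#'
#' Stores the decreasing lambda path, one precision matrix per lambda, the
#' EBIC value and edge count per lambda, the EBIC hyperparameter gamma, the
#' sample size, the SKEPTIC correlation matrix the path was fit to, and the
#' index of the selected (EBIC-minimising) model.
#'
#' @seealso [estimateNetwork()], [ebic()]
#' @export
setClass("GlassoFit",
  representation(lambdaPath = "numeric", precisions = "list",
                 ebicValues = "numeric", edgeCounts = "integer",
                 gamma = "numeric", selectedIndex = "integer",
                 n = "integer", correlation = "matrix",
                 psdRepaired = "logical"))

setValidity("GlassoFit", function(object) {
  msg <- character()
  m <- length(object@lambdaPath)
  if (any(diff(object@lambdaPath) >= 0))
    msg <- c(msg, "lambdaPath must be strictly decreasing")
  if (length(object@precisions) != m || length(object@ebicValues) != m ||
      length(object@edgeCounts) != m)
    msg <- c(msg, "path components must have equal length")
  if (any(!is.finite(object@ebicValues)))
    msg <- c(msg, "EBIC values must be finite")
  if (object@selectedIndex < 1L || object@selectedIndex > m)
    msg <- c(msg, "selectedIndex out of range")
  else if (abs(object@ebicValues[object@selectedIndex] -
               min(object@ebicValues)) > 1e-9)
    msg <- c(msg, "selectedIndex must minimise EBIC")
  if (length(msg)) msg else TRUE
})

#' NctResult: permutation network-comparison test of global strength
#'
#' Observed absolute difference in global strength between two samples, the
#' permutation null distribution obtained by regrouping pooled individuals,
#' and the add-one two-tailed p-value
#' `(1 + #\{perm >= observed\}) / (1 + nPermutations)`.
#'
#' @seealso [nctGlobalStrength()]
#' @export
setClass("NctResult",
  representation(observedDifference = "numeric",
                 permutationDifferences = "numeric",
                 pValue = "numeric", nPermutations = "integer",
                 seed = "integer"))

setValidity("NctResult", function(object) {
  msg <- character()
  p0 <- (1 + sum(object@permutationDifferences >=
                   object@observedDifference)) /
    (1 + object@nPermutations)
  if (abs(object@pValue - p0) > 1e-12)
    msg <- c(msg, "pValue inconsistent with stored permutation differences")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(object@permutationDifferences) != object@nPermutations)
    msg <- c(msg, "permutation vector length must equal nPermutations")
  if (length(msg)) msg else TRUE
})

#' StabilityResult: case-drop bootstrap stability of a centrality measure
#'
#' Per drop proportion, the correlations between subsample and full-sample
#' centrality across nodes; the CS-coefficient (largest drop proportion whose
#' correlation stays above `corThreshold` in at least `confidence` of
#' subsamples) and whether it passes the interpretability threshold.
#'
#' @seealso [casedropStability()]
#' @export
setClass("StabilityResult",
  representation(measure = "character", csCoefficient = "numeric",
                 dropProportions = "numeric", correlations = "matrix",
                 corThreshold = "numeric", confidence = "numeric",
                 passThreshold = "numeric", passes = "logical",
                 seed = "integer"))

setValidity("StabilityResult", function(object) {
  msg <- character()
  if (!all(object@dropProportions > 0 & object@dropProportions < 1))
    msg <- c(msg, "drop proportions must lie in (0, 1)")
  if (ncol(object@correlations) != length(object@dropProportions))
    msg <- c(msg, "one correlation column per drop proportion required")
  if (object@csCoefficient < 0 || object@csCoefficient > 0.75)
    msg <- c(msg, "CS-coefficient must lie in [0, 0.75]")
  if (length(msg)) msg else TRUE
})
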
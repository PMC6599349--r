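# End-to-end orchestration of the two-arm analysis, reproducible from a
# single config (R list or YAML file).

#' Build / validate an analysis configuration
#'
#' A config drives [runFullAnalysis()].  Exactly one of `input` (cohort CSV
#' path) or `simulate` (a list of [simulateDefaultCohort()] arguments) must
#' be supplied.  All stage settings have documented defaults and bounds;
#' the seed is recorded in every output artifact.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param simulate List of arguments for [simulateDefaultCohort()] (used
#'   when `input` is `NULL`).
#' @param gamma EBIC hyperparameter (>= 0; the pipeline preset is 0).
#' @param nLambda,lambdaMinRatio Lambda path settings.
#' @param nPermutations NCT permutations (>= 1).
#' @param nBoots,dropProportions Stability bootstrap settings.
#' @param stabilityMeasures Centrality measures to bootstrap (default
#'   strength only; closeness/betweenness are computed descriptively but
#'   rarely stable at these sample sizes).
#' @param residualizeBaseline Residualize the baseline matrix on delay too
#'   (default TRUE; FALSE merely centers it).
#' @param seed Master seed.
#' @param outputDir Directory for the report bundle, or `NULL` for none.
#' @return Validated config list of class `AnalysisConfig`.
#' @export
analysisConfig <- function(input = NULL, simulate = list(), gamma = 0,
                           nLambda = 100L, lambdaMinRatio = 0.01,
                           nPermutations = 1000L, nBoots = 1000L,
                           dropProportions = seq(0.1, 0.7, by = 0.1),
                           stabilityMeasures = "strength",
                           residualizeBaseline = TRUE,
                           seed = 1L, outputDir = NULL) {
  stopifnot(gamma >= 0, nLambda >= 2L, lambdaMinRatio > 0,
            lambdaMinRatio < 1, nPermutations >= 1L, nBoots >= 1L,
            all(dropProportions > 0 & dropProportions < 1),
            all(stabilityMeasures %in% c("strength", "closeness",
                                         "betweenness")),
            is.logical(residualizeBaseline))
  structure(list(input = input, simulate = simulate, gamma = gamma,
                 nLambda = as.integer(nLambda),
                 lambdaMinRatio = lambdaMinRatio,
                 nPermutations = as.integer(nPermutations),
                 nBoots = as.integer(nBoots),
                 dropProportions = dropProportions,
                 stabilityMeasures = stabilityMeasures,
                 residualizeBaseline = residualizeBaseline,
                 seed = as.integer(seed), outputDir = outputDir),
            class = "AnalysisConfig")
}

#' Read an analysis configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [analysisConfig()].
#'
#' @param path YAML file.
#' @return An `AnalysisConfig` list.
#' @export
readAnalysisConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 would read a bare key `n` as a boolean, so the patient count
  # in the simulate block is spelled `nPatients`
  if (!is.null(raw$simulate$nPatients)) {
    raw$simulate$n <- raw$simulate$nPatients
    raw$simulate$nPatients <- NULL
  }
  known <- names(formals(analysisConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(analysisConfig, raw)
}

#' Run the complete two-arm analysis
#'
#' Executes, in order: cohort loading (or simulation), baseline-severity
#' filter, the individual-scores arm (per-item table, response proportion,
#' logistic regression), delay residualization per occasion, per-occasion
#' network estimation, the global-strength NCT between occasions, and
#' node-strength centrality with case-drop stability.  With an `outputDir`,
#' writes a machine-readable `report.json` plus per-stage CSVs; identical
#' config and seed give identical outputs.  A stage failure raises an error
#' naming the stage (partial in-memory results are not silently degraded).
#'
#' @param config An [analysisConfig()] list.
#' @return The report bundle as a nested list (also serialized to JSON when
#'   `outputDir` is set).
#' @export
runFullAnalysis <- function(config = analysisConfig()) {
  stopifnot(inherits(config, "AnalysisConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort0 <- stage("load", {
    if (!is.null(config$input)) readCohortCsv(config$input)
    else do.call(simulateDefaultCohort,
                 c(config$simulate,
                   if (is.null(config$simulate$seed))
                     list(seed = config$seed)))$cohort
  })

  filt <- stage("severity_filter", filterBaselineSevere(cohort0))
  cohort <- filt$cohort
  if (ncol(cohort) < 13L)
    stop("stage 'severity_filter': fewer than 13 severe-at-baseline ",
         "patients remain; the network arm is not estimable", call. = FALSE)

  scoresArm <- stage("individual_scores", {
    lf <- tryCatch(fitResponseLogistic(cohort), error = function(e)
      list(error = conditionMessage(e)))
    list(itemTable = itemSummaryTable(cohort),
         response = responseProportion(cohort),
         logistic = lf)
  })

  resid <- stage("residualize", {
    d <- delayDays(cohort)
    rb <- if (config$residualizeBaseline)
      residualizeOnDelay(baselineScores(cohort), d)
    else scale(baselineScores(cohort), center = TRUE, scale = FALSE)
    re <- residualizeOnDelay(endpointScores(cohort), d)
    list(baseline = rb, endpoint = re)
  })

  nets <- stage("network_estimation", {
    lapply(resid, function(r)
      estimateNetwork(r, gamma = config$gamma, nLambda = config$nLambda,
                      lambdaMinRatio = config$lambdaMinRatio))
  })

  nct <- stage("nct", nctGlobalStrength(
    resid$baseline, resid$endpoint, nPermutations = config$nPermutations,
    gamma = config$gamma, nLambda = config$nLambda,
    lambdaMinRatio = config$lambdaMinRatio, seed = config$seed))

  centrStab <- stage("centrality_stability", {
    lapply(stats::setNames(nm = names(resid)), function(occ) {
      net <- nets[[occ]]$network
      stab <- lapply(stats::setNames(nm = config$stabilityMeasures),
                     function(m)
        casedropStability(resid[[occ]], measure = m,
                          nBoots = config$nBoots,
                          dropProportions = config$dropProportions,
                          gamma = config$gamma, nLambda = config$nLambda,
                          lambdaMinRatio = config$lambdaMinRatio,
                          seed = config$seed))
      list(strength = suppressWarnings(nodeStrength(net)),
           pathCentrality = suppressWarnings(closenessBetweenness(net)),
           stability = stab)
    })
  })

  report <- list(
    schema = "honosnet-report/1",
    seed = config$seed,
    settings = config[c("gamma", "nLambda", "lambdaMinRatio",
                        "nPermutations", "nBoots", "residualizeBaseline")],
    flow = list(screened = ncol(cohort0), excluded_not_severe = filt$excluded,
                analysed = ncol(cohort)),
    individual_scores = list(
      item_table = scoresArm$itemTable,
      response = scoresArm$response,
      logistic = scoresArm$logistic),
    networks = lapply(nets, function(x) list(
      weights = networkWeights(x$network),
      selected_lambda = x$fit@lambdaPath[x$fit@selectedIndex],
      edges = x$fit@edgeCounts[x$fit@selectedIndex],
      global_strength = globalStrength(x$network))),
    nct = list(observed_difference = observedDifference(nct),
               p_value = pValue(nct),
               n_permutations = nct@nPermutations, seed = nct@seed),
    centrality = lapply(centrStab, function(x) list(
      strength = x$strength,
      path_centrality = x$pathCentrality,
      stability = lapply(x$stability, function(s) list(
        measure = s@measure, cs = csCoefficient(s),
        passes = stabilityPasses(s),
        prop_above_threshold = colMeans(s@correlations >= s@corThreshold))))))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(scoresArm$itemTable,
                     file.path(config$outputDir, "item_scores.csv"),
                     row.names = FALSE)
    for (occ in names(nets))
      utils::write.csv(networkWeights(nets[[occ]]$network),
                       file.path(config$outputDir,
                                 paste0("network_", occ, ".csv")))
  }
  invisible(report)
}
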
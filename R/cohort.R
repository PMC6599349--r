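#' Construct a HonosCohort from paired score matrices
#'
#' @param baseline,endpoint n-by-12 matrices of ordinal scores (rows =
#'   patients, columns = items in the [honosItems()] order), each entry in
#'   0..4.
#' @param delay_days Positive per-patient delay (days) between the two
#'   ratings.
#' @param age Per-patient age in years (positive; `NA` allowed).
#' @param gender Character vector with values `male`, `female` or `unknown`.
#' @param patient_id Unique patient identifiers; defaults to `P1..Pn`.
#' @return A validated [HonosCohort-class] object.
#' @examples
#' b <- matrix(3L, 2, 12); e <- matrix(0L, 2, 12)
#' HonosCohort(b, e, delay_days = c(400, 500))
#' @export
HonosCohort <- function(baseline, endpoint, delay_days,
                        age = rep(NA_integer_, nrow(baseline)),
                        gender = rep("unknown", nrow(baseline)),
                        patient_id = paste0("P", seq_len(nrow(baseline)))) {
  baseline <- as.matrix(baseline)
  endpoint <- as.matrix(endpoint)
  stopifnot(ncol(baseline) == .N_ITEMS, ncol(endpoint) == .N_ITEMS,
            nrow(baseline) == nrow(endpoint))
  b <- t(baseline); e <- t(endpoint)
  dimnames(b) <- dimnames(e) <- list(honosItems(), patient_id)
  storage.mode(b) <- storage.mode(e) <- "integer"
  cd <- S4Vectors::DataFrame(age = age, gender = gender,
                             delay_days = as.numeric(delay_days),
                             row.names = patient_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(baseline = b, endpoint = e), colData = cd)
  methods::validObject(obj <- methods::new("HonosCohort", se))
  obj
}

#' Construct a WeightedNetwork from a weight matrix
#'
#' @param weights Symmetric matrix of partial correlations, zero diagonal,
#'   `|weights| < 1`.  Unlabelled matrices of size 12 get [honosItems()]
#'   labels; other sizes get `V1..Vp`.
#' @return A validated [WeightedNetwork-class].
#' @export
WeightedNetwork <- function(weights) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) {
    lab <- if (nrow(weights) == .N_ITEMS) honosItems()
           else paste0("V", seq_len(nrow(weights)))
    dimnames(weights) <- list(lab, lab)
  }
  methods::validObject(obj <- methods::new("WeightedNetwork",
                                           weights = weights))
  obj
}

#' Classify a HoNOS profile as severe or non-severe
#'
#' A profile is severe iff at least one of its 12 items is rated 3 or above;
#' it is non-severe iff no item reaches 3.
#'
#' @param profile Integer vector of 12 scores in 0..4, or an n-by-12 matrix
#'   (one row per profile).
#' @return `"severe"`/`"non-severe"` per profile.
#' @examples
#' classifySeverity(rep(2L, 12))        # non-severe
#' classifySeverity(c(rep(0L, 11), 3L)) # severe
#' @export
classifySeverity <- function(profile) {
  m <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1L)
  if (ncol(m) != .N_ITEMS)
    stop("a HoNOS profile has exactly 12 items")
  if (anyNA(m) || !all(m %in% 0:4))
    stop("scores must be integers in {0,..,4}")
  ifelse(apply(m, 1L, max) >= 3, "severe", "non-severe")
}

#' Restrict a cohort to patients severe at baseline
#'
#' Mirrors the study inclusion rule: patients whose baseline profile does not
#' reach the severity criterion (no item rated 3 or above) are excluded from
#' all downstream analysis.
#'
#' @param cohort A [HonosCohort-class].
#' @return A list with `cohort` (the filtered [HonosCohort-class]) and
#'   `excluded` (number of records removed).  An empty result triggers a
#'   warning, not an error.
#' @export
filterBaselineSevere <- function(cohort) {
  stopifnot(methods::is(cohort, "HonosCohort"))
  keep <- classifySeverity(baselineScores(cohort)) == "severe"
  if (!any(keep))
    warning("no patient reaches the severity criterion at baseline")
  list(cohort = cohort[, keep], excluded = sum(!keep))
}
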
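#' Default column mapping for cohort CSV files
#'
#' The long cohort format has one row per patient per occasion.  The mapping
#' can be overridden entry-wise (e.g. from a YAML config block) as long as
#' all keys are present: `patient_id`, `occasion`, `delay_days`, `age`,
#' `gender`, and `items` (a character vector of the 12 item column names, in
#' the [honosItems()] order).
#'
#' @param ... Named overrides of individual entries.
#' @return Named list describing the column layout.
#' @export
cohortColumnDefaults <- function(...) {
  cols <- list(patient_id = "patient_id", occasion = "occasion",
               delay_days = "delay_days", age = "age", gender = "gender",
               items = paste0("item_", 1:12))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cols))
    if (length(bad)) stop("unknown column-mapping keys: ",
                          paste(bad, collapse = ", "))
    cols[names(over)] <- over
  }
  if (length(cols$items) != 12L) stop("exactly 12 item columns are required")
  cols
}

#' Read a cohort CSV into a HonosCohort
#'
#' Expects a header row and one row per patient per occasion, with the
#' occasion column equal to `"baseline"` or `"endpoint"`.  Validation is
#' complete-case: rows with missing or out-of-range scores and patients with
#' only one occasion are dropped with a warning naming them; structural
#' problems (missing columns, scores outside 0..4, mismatching delays within
#' a patient, duplicated occasions) are errors naming row and column.
#'
#' @param path CSV file path (RFC 4180, UTF-8).
#' @param columns Column mapping, see [cohortColumnDefaults()].
#' @return A [HonosCohort-class].
#' @seealso [writeCohortCsv()]
#' @export
readCohortCsv <- function(path, columns = cohortColumnDefaults()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(unlist(columns[c("patient_id", "occasion", "delay_days",
                             "age", "gender")]), columns$items)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  occ <- df[[columns$occasion]]
  if (!all(occ %in% c("baseline", "endpoint")))
    stop("occasion column must contain only 'baseline'/'endpoint'; offending row(s): ",
         paste(which(!occ %in% c("baseline", "endpoint")), collapse = ", "))

  scores <- as.matrix(df[, columns$items])
  storage.mode(scores) <- "integer"
  ok_range <- is.na(scores) | (scores >= 0L & scores <= 4L)
  if (!all(ok_range)) {
    bad <- which(!ok_range, arr.ind = TRUE)[1L, ]
    stop(sprintf("score outside {0,..,4} at row %d, column '%s'",
                 bad[["row"]], columns$items[bad[["col"]]]))
  }
  incomplete <- apply(scores, 1L, anyNA)
  if (any(incomplete)) {
    warning(sprintf("dropping %d row(s) with missing item scores (complete-case): rows %s",
                    sum(incomplete),
                    paste(which(incomplete), collapse = ", ")))
    df <- df[!incomplete, , drop = FALSE]
    scores <- scores[!incomplete, , drop = FALSE]
    occ <- occ[!incomplete]
  }

  ids <- as.character(df[[columns$patient_id]])
  paired <- vapply(unique(ids), function(id) {
    o <- occ[ids == id]
    length(o) == 2L && setequal(o, c("baseline", "endpoint"))
  }, logical(1L))
  dup <- vapply(unique(ids), function(id) {
    anyDuplicated(occ[ids == id]) > 0L
  }, logical(1L))
  if (any(dup))
    stop("duplicated occasion rows for patient(s): ",
         paste(unique(ids)[dup], collapse = ", "))
  if (any(!paired))
    warning(sprintf("excluding %d patient(s) with a single occasion (complete-case): %s",
                    sum(!paired),
                    paste(unique(ids)[!paired], collapse = ", ")))
  keep_ids <- unique(ids)[paired]
  if (!length(keep_ids)) stop("no complete baseline/endpoint pairs in file")

  ib <- match(paste(keep_ids, "baseline"), paste(ids, occ))
  ie <- match(paste(keep_ids, "endpoint"), paste(ids, occ))
  delay_b <- as.numeric(df[[columns$delay_days]])[ib]
  delay_e <- as.numeric(df[[columns$delay_days]])[ie]
  if (any(abs(delay_b - delay_e) > 1e-8))
    stop("delay_days differs between the two rows of patient(s): ",
         paste(keep_ids[abs(delay_b - delay_e) > 1e-8], collapse = ", "))
  gender <- as.character(df[[columns$gender]])[ib]
  gender[is.na(gender) | !gender %in% c("male", "female")] <- "unknown"

  HonosCohort(baseline = scores[ib, , drop = FALSE],
              endpoint = scores[ie, , drop = FALSE],
              delay_days = delay_b,
              age = as.integer(df[[columns$age]])[ib],
              gender = gender,
              patient_id = keep_ids)
}

#' Write a HonosCohort to CSV
#'
#' Inverse of [readCohortCsv()]: emits the long format (two rows per
#' patient) under the given column mapping, so that a write/read round trip
#' reproduces the cohort exactly.
#'
#' @param cohort A [HonosCohort-class].
#' @param path Output CSV path.
#' @param columns Column mapping, see [cohortColumnDefaults()].
#' @return `path`, invisibly.
#' @export
writeCohortCsv <- function(cohort, path, columns = cohortColumnDefaults()) {
  stopifnot(methods::is(cohort, "HonosCohort"))
  cd <- SummarizedExperiment::colData(cohort)
  one <- function(occasion, m) {
    out <- data.frame(id = colnames(cohort), occ = occasion,
                      delay = cd$delay_days, age = cd$age,
                      gender = cd$gender, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(m))
    names(out) <- c(columns$patient_id, columns$occasion,
                    columns$delay_days, columns$age, columns$gender,
                    columns$items)
    out
  }
  long <- rbind(one("baseline", baselineScores(cohort)),
                one("endpoint", endpointScores(cohort)))
  long <- long[order(match(long[[columns$patient_id]], colnames(cohort)),
                     long[[columns$occasion]]), ]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
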
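#' Assemble a longitudinal cohort
#'
#' Combines a one-row-per-subject outcome table with a long-format table of
#' time-stamped covariate measurements into a validated cohort object, the
#' input expected by [build_stack()].
#'
#' @param outcomes data frame with columns `id`, `time` (event or censoring
#'   time, nonnegative), and `status` (integer code: 0 = censored, 1..J =
#'   cause of the event).
#' @param measurements data frame with columns `id`, `obs_time` and one
#'   column per covariate.  Each subject needs at least one measurement, all
#'   measurement times must be strictly increasing within subject and no
#'   later than the subject's outcome time.
#' @param n_causes number of competing causes J.  Defaults to the largest
#'   status code observed.
#'
#' @return An object of class `lm_cohort`: a list with elements `outcomes`,
#'   `measurements`, `covariates` (covariate column names) and `n_causes`.
#' @seealso [read_cohort()] to build a cohort from delimited files.
#' @export
as_cohort <- function(outcomes, measurements, n_causes = NULL) {
  req_out <- c("id", "time", "status")
  if (!all(req_out %in% names(outcomes)))
    stop("outcomes must have columns: ", paste(req_out, collapse = ", "))
  req_meas <- c("id", "obs_time")
  if (!all(req_meas %in% names(measurements)))
    stop("measurements must have columns: ", paste(req_meas, collapse = ", "))

  outcomes <- as.data.frame(outcomes)[c("id", "time", "status")]
  measurements <- as.data.frame(measurements)
  covs <- setdiff(names(measurements), req_meas)
  if (length(covs) == 0L) stop("measurements contain no covariate columns")

  if (anyDuplicated(outcomes$id))
    stop("duplicate subject id in outcomes: ",
         paste(unique(outcomes$id[duplicated(outcomes$id)])[1:3], collapse = ", "))
  if (any(!is.finite(outcomes$time)) || any(outcomes$time < 0))
    stop("outcome times must be finite and nonnegative")
  st <- outcomes$status
  if (any(st != as.integer(st)) || any(st < 0))
    stop("status codes must be nonnegative integers (0 = censored)")
  if (is.null(n_causes)) n_causes <- max(1L, max(as.integer(st)))
  if (any(st > n_causes))
    stop("status code exceeds n_causes = ", n_causes)

  unknown <- setdiff(measurements$id, outcomes$id)
  if (length(unknown))
    stop("measurement rows for unknown subject id: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  missing_meas <- setdiff(outcomes$id, measurements$id)
  if (length(missing_meas))
    stop("no covariate measurements for subject id: ",
         paste(utils::head(missing_meas, 3), collapse = ", "))

  o <- order(match(measurements$id, outcomes$id), measurements$obs_time)
  measurements <- measurements[o, , drop = FALSE]
  rownames(measurements) <- NULL

  # within-subject checks, vectorized over the sorted table
  same_subj <- duplicated(measurements$id)
  dt <- diff(measurements$obs_time)
  bad <- which(same_subj[-1L] & dt <= 0)
  if (length(bad))
    stop("measurement times not strictly increasing for subject id ",
         measurements$id[bad[1L] + 1L])
  ev_time <- outcomes$time[match(measurements$id, outcomes$id)]
  late <- which(measurements$obs_time > ev_time)
  if (length(late))
    stop("measurement after outcome time for subject id ",
         measurements$id[late[1L]], " (obs_time ",
         measurements$obs_time[late[1L]], " > ", ev_time[late[1L]], ")")
  if (anyNA(measurements[covs]))
    stop("missing covariate values in measurements are not allowed")

  structure(
    list(outcomes = outcomes, measurements = measurements,
         covariates = covs, n_causes = as.integer(n_causes)),
    class = "lm_cohort")
}

#' @export
print.lm_cohort <- function(x, ...) {
  cat("Longitudinal cohort: ", nrow(x$outcomes), " subjects, ",
      nrow(x$measurements), " measurements, J = ", x$n_causes,
      ifelse(x$n_causes > 1, " competing causes\n", " cause\n"), sep = "")
  ev <- table(factor(x$outcomes$status, levels = 0:x$n_causes))
  cat("  status counts:", paste(sprintf("%s=%d", names(ev), ev), collapse = ", "), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Read a cohort from delimited text files
#'
#' @param outcomes_file CSV with columns `id,time,status`.
#' @param measurements_file CSV with columns `id,obs_time,<covariates...>`.
#' @param n_causes passed to [as_cohort()].
#' @return An `lm_cohort` object.
#' @export
read_cohort <- function(outcomes_file, measurements_file, n_causes = NULL) {
  for (f in c(outcomes_file, measurements_file))
    if (!file.exists(f)) stop("file not found: ", f)
  out <- utils::read.csv(outcomes_file)
  meas <- utils::read.csv(measurements_file)
  as_cohort(out, meas, n_causes = n_causes)
}

#' Write a cohort back to delimited text files
#'
#' Inverse of [read_cohort()]; useful for exporting simulated cohorts.
#'
#' @param cohort an `lm_cohort`.
#' @param outcomes_file,measurements_file destination paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, outcomes_file, measurements_file) {
  stopifnot(inherits(cohort, "lm_cohort"))
  utils::write.csv(cohort$outcomes, outcomes_file, row.names = FALSE)
  utils::write.csv(cohort$measurements, measurements_file, row.names = FALSE)
  invisible(cohort)
}

#' Last-observation-carried-forward covariates at a landmark
#'
#' Returns, for each requested subject, the covariate vector of their latest
#' measurement at or before time `s` (the boundary is inclusive: a
#' measurement exactly at `s` is used at `s`).
#'
#' @param cohort an `lm_cohort`.
#' @param s landmark time.
#' @param ids subjects to evaluate; defaults to all subjects.
#' @return data frame with column `id` followed by the covariate columns.
#' @export
locf_covariates <- function(cohort, s, ids = NULL) {
  stopifnot(inherits(cohort, "lm_cohort"), is.numeric(s), length(s) == 1L)
  m <- cohort$measurements
  if (is.null(ids)) ids <- cohort$outcomes$id
  keep <- m$obs_time <= s & m$id %in% ids
  mm <- m[keep, , drop = FALSE]
  # measurements are sorted by (id, obs_time): the last row per id is the LOCF row
  mm <- mm[!duplicated(mm$id, fromLast = TRUE), , drop = FALSE]
  miss <- setdiff(ids, mm$id)
  if (length(miss))
    stop("no covariate measurement at or before s = ", s,
         " for subject id ", paste(utils::head(miss, 3), collapse = ", "))
  res <- mm[match(ids, mm$id), c("id", cohort$covariates), drop = FALSE]
  rownames(res) <- NULL
  res
}
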
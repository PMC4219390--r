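#' Read a long-format longitudinal biomarker file
#'
#' Expects a comma-separated file with a header and at least the columns
#' `id`, `time`, `value`; any further columns are treated as baseline
#' covariates (constant within subject).
#'
#' @param path path to a CSV file.
#' @return a validated `data.frame` (see [validate_long]).
#' @export
read_long_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_long(d)
}

#' Read a one-row-per-subject survival file
#'
#' Expects columns `id`, `time`, `event`; optional `baseline_obs` (the first
#' observed biomarker value) and covariate columns.
#'
#' @param path path to a CSV file.
#' @return a validated `data.frame` (see [validate_surv]).
#' @export
read_surv_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_surv(d)
}

#' @rdname read_long_csv
#' @param data data.frame to validate/write.
#' @export
validate_long <- function(data) {
  need <- c("id", "time", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("longitudinal data: missing column(s) ", paste(miss, collapse = ", "))
  for (cn in setdiff(names(data), "id"))
    if (!is.numeric(data[[cn]]))
      stop("longitudinal data: column '", cn, "' must be numeric")
  if (anyNA(data$value) || anyNA(data$time))
    stop("longitudinal data: missing values in 'time'/'value'")
  if (any(data$time < 0)) stop("longitudinal data: negative measurement times")
  # order by subject then time (times within subject non-decreasing)
  data <- data[order(match(data$id, unique(data$id)), data$time), , drop = FALSE]
  rownames(data) <- NULL
  data
}

#' @rdname read_surv_csv
#' @param data data.frame to validate/write.
#' @export
validate_surv <- function(data) {
  need <- c("id", "time", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("survival data: missing column(s) ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$id)) {
    dup <- unique(data$id[duplicated(data$id)])
    stop("survival data: duplicate rows for subject(s) ", paste(utils::head(dup, 5), collapse = ", "))
  }
  for (cn in setdiff(names(data), "id"))
    if (!is.numeric(data[[cn]]))
      stop("survival data: column '", cn, "' must be numeric")
  if (any(data$time <= 0)) stop("survival data: observation times must be positive")
  if (!all(data$event %in% c(0, 1))) stop("survival data: 'event' must be 0/1")
  rownames(data) <- NULL
  data
}

#' Cross-validate a longitudinal / survival dataset pair
#'
#' Checks that every survival subject has at least one longitudinal record and
#' that no measurement time exceeds the subject's observed time (the data
#' model assumes biomarker observation stops at the event or censoring time).
#'
#' @param long,surv data.frames as returned by [read_long_csv] / [read_surv_csv].
#' @return invisibly, `list(long, surv)` with both tables validated.
#' @export
validate_joint_data <- function(long, surv) {
  long <- validate_long(long)
  surv <- validate_surv(surv)
  missing_long <- setdiff(surv$id, long$id)
  if (length(missing_long))
    stop("subject(s) without longitudinal records: ",
         paste(utils::head(missing_long, 5), collapse = ", "))
  orphan <- setdiff(long$id, surv$id)
  if (length(orphan))
    stop("longitudinal subject(s) without a survival row: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  tmax <- surv$time[match(long$id, surv$id)]
  bad <- long$time > tmax
  if (any(bad))
    stop("measurement after the observed time for subject(s) ",
         paste(utils::head(unique(long$id[bad]), 5), collapse = ", "))
  invisible(list(long = long, surv = surv))
}

#' Write datasets as CSV
#'
#' Plain comma-separated UTF-8 with header and "." decimal mark.
#'
#' @param data data.frame.
#' @param path output path.
#' @export
write_joint_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
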
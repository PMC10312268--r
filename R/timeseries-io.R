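#' ROI time-series container
#'
#' Holds one subject's endogenous node series (T x p) together with the
#' exogenous task regressors (T x q, possibly zero columns) and the
#' repetition time.
#'
#' @param values Numeric T x p matrix of endogenous signals; column names
#'   are the node names.
#' @param exogenous Numeric T x q matrix of exogenous regressors (or
#'   `NULL` for none); column names are the regressor names.
#' @param subject_id Character scalar identifier.
#' @param tr_seconds Repetition time in seconds.
#' @param min_length_factor Minimum usable length, expressed as a multiple
#'   of the total number of series (default 3).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, exogenous = NULL, subject_id = "subject",
                           tr_seconds = 2, min_length_factor = 3) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("roi%02d", seq_len(ncol(values)))
  if (!is.null(exogenous) && ncol(as.matrix(exogenous)) > 0L) {
    exogenous <- as.matrix(exogenous)
    storage.mode(exogenous) <- "double"
    if (is.null(colnames(exogenous)))
      colnames(exogenous) <- sprintf("exo%d", seq_len(ncol(exogenous)))
    if (nrow(exogenous) != nrow(values))
      stop("exogenous and endogenous series differ in length")
  } else {
    exogenous <- matrix(0, nrow(values), 0L)
  }
  obj <- structure(
    list(subject_id = as.character(subject_id), values = values,
         exogenous = exogenous, tr_seconds = as.numeric(tr_seconds)),
    class = "roi_timeseries")
  validate_roi_timeseries(obj, min_length_factor = min_length_factor)
  obj
}

validate_roi_timeseries <- function(x, min_length_factor = 3) {
  if (anyNA(x$values) || anyNA(x$exogenous))
    stop("time series contains missing values")
  nn <- colnames(x$values); en <- colnames(x$exogenous)
  if (anyDuplicated(c(nn, en)))
    stop("node and exogenous names must be unique and disjoint")
  total <- ncol(x$values) + ncol(x$exogenous)
  if (nrow(x$values) < min_length_factor * total)
    stop(sprintf("series too short: T=%d < %d x (p+q)=%d",
                 nrow(x$values), min_length_factor,
                 min_length_factor * total))
  invisible(x)
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject '%s': T=%d, %d nodes, %d exogenous, TR=%gs\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              ncol(x$exogenous), x$tr_seconds))
  invisible(x)
}

detect_delimiter <- function(header_line) {
  if (grepl("\t", header_line)) "\t"
  else if (grepl(",", header_line)) ","
  else ""
}

#' Read a delimited ROI time-series table
#'
#' Expects a header row of node names and a numeric body; the delimiter is
#' auto-detected among tab, comma and whitespace. Columns whose names match
#' `exo_regex` are treated as exogenous regressors.
#'
#' @param path File path.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Identifier; defaults to the file name without
#'   extension.
#' @param exo_regex Regular expression selecting exogenous columns by name
#'   (default matches `anticipation`/`outcome`/`exo*` style names).
#' @param min_length_factor Passed to [roi_timeseries()].
#' @return A [roi_timeseries()] object.
#' @export
read_timeseries <- function(path, tr_seconds = 2, subject_id = NULL,
                            exo_regex = "^(exo|anticipation|outcome)",
                            min_length_factor = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- detect_delimiter(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  if (anyDuplicated(names(df)))
    stop("duplicate column headers in ", path, ": ",
         paste(names(df)[duplicated(names(df))], collapse = ", "))
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing value at row %d, column '%s' of %s",
                   bad[1L], names(df)[j], path))
    mat[, j] <- v
  }
  is_exo <- grepl(exo_regex, colnames(mat), ignore.case = TRUE)
  roi_timeseries(values = mat[, !is_exo, drop = FALSE],
                 exogenous = if (any(is_exo)) mat[, is_exo, drop = FALSE],
                 subject_id = subject_id %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 tr_seconds = tr_seconds,
                 min_length_factor = min_length_factor)
}

#' Write an ROI time series to delimited text
#'
#' One header row (endogenous node names followed by exogenous names) and
#' one row per timepoint.
#'
#' @param series A [roi_timeseries()].
#' @param path Output file path.
#' @param sep Field delimiter (default tab).
#' @export
write_timeseries <- function(series, path, sep = "\t") {
  mat <- cbind(series$values, series$exogenous)
  utils::write.table(mat, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a task event table (BIDS events dialect)
#'
#' Tab- or comma-separated with columns `onset`, `duration`, `trial_type`.
#'
#' @param path File path.
#' @return A `task_events` data.frame sorted by onset.
#' @export
read_events <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- detect_delimiter(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("event table must have columns onset, duration, trial_type")
  task_events(df$onset, df$duration, df$trial_type)
}

#' Construct a task event table
#'
#' @param onset,duration Numeric vectors in seconds.
#' @param trial_type Character vector of event labels.
#' @return A `data.frame` of class `task_events`, sorted by onset.
#' @export
task_events <- function(onset = numeric(), duration = numeric(),
                        trial_type = character()) {
  ev <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   trial_type = as.character(trial_type),
                   stringsAsFactors = FALSE)
  if (any(ev$onset < 0)) stop("event onsets must be non-negative")
  if (any(ev$duration < 0)) stop("event durations must be non-negative")
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("task_events", "data.frame")
  ev
}

#' Standardize a time series to zero mean and unit variance
#'
#' Each endogenous column is centered and scaled; exogenous columns are
#' standardized likewise by default.
#'
#' @param series A [roi_timeseries()].
#' @param include_exogenous Standardize exogenous columns too (default
#'   `TRUE`).
#' @return A standardized [roi_timeseries()].
#' @export
standardize <- function(series, include_exogenous = TRUE) {
  zscale <- function(mat, what) {
    if (!ncol(mat)) return(mat)
    sds <- apply(mat, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance ", what, " column: ",
           paste(colnames(mat)[sds == 0], collapse = ", "))
    scale(mat, center = TRUE, scale = sds)[, , drop = FALSE]
  }
  series$values <- zscale(series$values, "node")
  if (include_exogenous) series$exogenous <- zscale(series$exogenous,
                                                   "exogenous")
  attr(series$values, "scaled:center") <- NULL
  attr(series$values, "scaled:scale") <- NULL
  series
}
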
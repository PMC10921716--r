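#' Cohort data container
#'
#' The exchange object used throughout the package: one row per subject with
#' chronological age, a marker matrix, and (optionally) the simulated truth
#' (divergence `delta`, biological age `bioage`, nuisance component `lambda`)
#' and survival fields (`sex`, `entry_age`, `exit_age`, `event`). Internally a
#' `data.frame` subclass; marker columns are tracked by name in the
#' `"markers"` attribute so that marker labels are free-form.
#'
#' Invariants enforced on construction: no missing values; at least one
#' marker; where truth is present, `bioage == age + delta` row-wise; where
#' survival is present, `exit_age > entry_age` and `event` is 0/1.
#'
#' @param age numeric vector of chronological ages (years).
#' @param markers numeric matrix or data.frame of marker values, one column
#'   per marker. Column names are kept; unnamed columns get `marker_1..m`.
#' @param delta,bioage,lambda optional numeric truth columns (years).
#' @param sex optional 0/1 vector (0 = female, 1 = male).
#' @param entry_age,exit_age,event optional survival fields: age at study
#'   entry, age at death/censoring, event indicator (1 = died).
#'
#' @return an object of class `cohort_data` (also a `data.frame`).
#' @export
cohort_data <- function(age, markers, delta = NULL, bioage = NULL,
                        lambda = NULL, sex = NULL, entry_age = NULL,
                        exit_age = NULL, event = NULL) {
  age <- as.numeric(age)
  n <- length(age)
  if (n < 1L) stop("`age` must be non-empty", call. = FALSE)
  markers <- as.matrix(markers)
  storage.mode(markers) <- "double"
  if (nrow(markers) != n) stop("`markers` must have one row per subject", call. = FALSE)
  if (ncol(markers) < 1L) stop("at least one marker column is required", call. = FALSE)
  if (is.null(colnames(markers))) {
    colnames(markers) <- paste0("marker_", seq_len(ncol(markers)))
  }
  df <- data.frame(id = seq_len(n), age = age)
  df <- cbind(df, as.data.frame(markers))

  opt <- list(delta = delta, bioage = bioage, lambda = lambda, sex = sex,
              entry_age = entry_age, exit_age = exit_age, event = event)
  for (nm in names(opt)) {
    v <- opt[[nm]]
    if (!is.null(v)) {
      if (length(v) != n) stop(sprintf("`%s` must have length n", nm), call. = FALSE)
      df[[nm]] <- as.numeric(v)
    }
  }
  out <- structure(df, markers = colnames(markers),
                   class = c("cohort_data", "data.frame"))
  validate_cohort_data(out)
}

validate_cohort_data <- function(x) {
  if (anyNA(x)) stop("cohort data must not contain missing values", call. = FALSE)
  if (!is.null(x$bioage)) {
    if (is.null(x$delta)) stop("`bioage` requires `delta`", call. = FALSE)
    if (max(abs(x$bioage - (x$age + x$delta))) > 1e-8) {
      stop("truth columns violate bioage == age + delta", call. = FALSE)
    }
  }
  has_surv <- !is.null(x$exit_age) || !is.null(x$event)
  if (has_surv) {
    if (is.null(x$entry_age) || is.null(x$exit_age) || is.null(x$event)) {
      stop("survival requires entry_age, exit_age and event", call. = FALSE)
    }
    if (any(x$exit_age <= x$entry_age)) {
      stop("exit_age must exceed entry_age for every subject", call. = FALSE)
    }
    if (!all(x$event %in% c(0, 1))) stop("`event` must be 0/1", call. = FALSE)
  }
  x
}

#' Extract the marker matrix of a cohort
#'
#' @param data a [cohort_data] object.
#' @param subset optional character or integer vector selecting markers
#'   (integers index into the marker set, not data-frame columns).
#' @return numeric matrix, subjects in rows.
#' @export
marker_matrix <- function(data, subset = NULL) {
  stopifnot(inherits(data, "cohort_data"))
  cols <- attr(data, "markers")
  if (!is.null(subset)) {
    cols <- if (is.character(subset)) subset else cols[subset]
    missing <- setdiff(cols, attr(data, "markers"))
    if (length(missing)) {
      stop("unknown marker(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  as.matrix(as.data.frame(data)[, cols, drop = FALSE])
}

#' Marker names of a cohort
#' @param data a [cohort_data] object.
#' @return character vector of marker column names.
#' @export
marker_names <- function(data) {
  stopifnot(inherits(data, "cohort_data"))
  attr(data, "markers")
}

#' @export
print.cohort_data <- function(x, ...) {
  m <- attr(x, "markers")
  cat(sprintf("<cohort_data> %d subjects, %d markers\n", nrow(x), length(m)))
  cat("  markers:", paste(utils::head(m, 6), collapse = ", "),
      if (length(m) > 6) "..." else "", "\n")
  extras <- intersect(c("delta", "bioage", "lambda", "sex", "entry_age",
                        "exit_age", "event"), names(x))
  if (length(extras)) cat("  extra columns:", paste(extras, collapse = ", "), "\n")
  if (!is.null(x$event)) cat(sprintf("  events: %d\n", sum(x$event)))
  invisible(x)
}

#' Read / write cohort tables as CSV
#'
#' Plain-text round trip of [cohort_data]. The header uses the column names
#' as stored (`id, age, [sex, entry_age, exit_age, event,] <markers...>,
#' [delta, bioage, lambda]`); on reading, every column that is not one of the
#' reserved names is treated as a marker.
#'
#' @param data a [cohort_data] object.
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns a [cohort_data].
#' @export
write_cohort_csv <- function(data, path) {
  stopifnot(inherits(data, "cohort_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  reserved <- c("id", "age", "sex", "entry_age", "exit_age", "event",
                "delta", "bioage", "lambda")
  if (!"age" %in% names(df)) stop("CSV must contain an `age` column", call. = FALSE)
  mk <- setdiff(names(df), reserved)
  if (!length(mk)) stop("CSV contains no marker columns", call. = FALSE)
  cohort_data(age = df$age,
              markers = as.matrix(df[, mk, drop = FALSE]),
              delta = df$delta, bioage = df$bioage, lambda = df$lambda,
              sex = df$sex, entry_age = df$entry_age, exit_age = df$exit_age,
              event = df$event)
}
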
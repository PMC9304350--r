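#' Construct a subject time-course record
#'
#' A record holds one subject's multivariate time courses as a numeric
#' matrix with components in rows and time points in columns (the layout
#' of ICA intrinsic-network time courses), plus an optional binary label.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param data Numeric matrix, components x time points.  All values must
#'   be finite.
#' @param label Optional class label, `0` (control) or `1` (patient); `NA`
#'   or `NULL` for unlabeled subjects (e.g. a pretraining pool).
#' @param cohort_tag Optional character tag naming the cohort.
#' @return An object of class `timecourse_record` with elements
#'   `subject_id`, `data`, `label`, `cohort_tag`.
#' @examples
#' rec <- timecourse_record("s1", matrix(rnorm(53 * 140), 53, 140), label = 1)
#' dim(rec$data)
#' @export
timecourse_record <- function(subject_id, data, label = NA_integer_,
                              cohort_tag = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("need at least 2 components, got ", nrow(data))
  if (!all(is.finite(data))) stop("non-finite values in time courses of ",
                                  subject_id)
  if (is.null(label)) label <- NA_integer_
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("label must be 0, 1 or NA, got ", label)
  }
  structure(list(subject_id = as.character(subject_id), data = data,
                 label = as.integer(label), cohort_tag = cohort_tag),
            class = "timecourse_record")
}

#' @export
print.timecourse_record <- function(x, ...) {
  cat(sprintf("<timecourse_record %s: %d components x %d time points, label=%s>\n",
              x$subject_id, nrow(x$data), ncol(x$data),
              ifelse(is.na(x$label), "-", x$label)))
  invisible(x)
}

#' Load a cohort of subject time courses from a CSV directory
#'
#' Expects one CSV file per subject (rows = components, columns = time
#' points, no header; filename minus extension is the subject id) and an
#' optional `labels.csv` with columns `subject_id,label`.
#'
#' @param path Directory containing per-subject CSV matrices.
#' @return List of [timecourse_record] objects, all with the same number of
#'   components.
#' @seealso [save_cohort()]
#' @export
load_cohort <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "labels.csv"]
  if (length(files) == 0L) stop("no subject CSV files under ", path)

  labfile <- file.path(path, "labels.csv")
  labels <- NULL
  if (file.exists(labfile)) {
    lab <- utils::read.csv(labfile, colClasses = c("character", "integer"))
    labels <- stats::setNames(lab$label, lab$subject_id)
  }

  records <- lapply(files, function(f) {
    m <- as.matrix(utils::read.csv(f, header = FALSE))
    if (!is.numeric(m)) stop("non-numeric cells in ", f)
    dimnames(m) <- NULL
    id <- sub("\\.csv$", "", basename(f))
    lab <- if (!is.null(labels) && id %in% names(labels)) labels[[id]]
           else NA_integer_
    timecourse_record(id, m, label = lab)
  })

  ncomp <- vapply(records, function(r) nrow(r$data), integer(1))
  if (length(unique(ncomp)) != 1L) {
    stop("inconsistent component counts across cohort: ",
         paste(unique(ncomp), collapse = ", "))
  }
  records
}

#' Save a cohort to a CSV directory
#'
#' Inverse of [load_cohort()]: one headerless CSV per subject plus a
#' `labels.csv` for any labeled subjects.  The round trip preserves values
#' to better than 1e-12 (full double precision is written).
#'
#' @param records List of [timecourse_record] objects.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
save_cohort <- function(records, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (r in records) {
    utils::write.table(format(r$data, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(path, paste0(r$subject_id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  labs <- Filter(function(r) !is.na(r$label), records)
  if (length(labs) > 0L) {
    utils::write.csv(data.frame(
      subject_id = vapply(labs, `[[`, "", "subject_id"),
      label = vapply(labs, `[[`, 0L, "label")),
      file.path(path, "labels.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Z-score each component time course
#'
#' Standardizes every component row to mean 0 and unit variance (population
#' convention, i.e. dividing by the root mean squared deviation).  Constant
#' rows cannot be scaled and are mapped to all zeros with a warning.
#'
#' @param record A [timecourse_record].
#' @return A new record with standardized rows.
#' @export
normalize_timecourses <- function(record) {
  x <- record$data
  if (ncol(x) < 2L) stop("need at least 2 time points to standardize")
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowMeans(xc^2))
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " constant component row(s) mapped to zero in ",
            record$subject_id)
    sdv[flat] <- 1
  }
  record$data <- xc / sdv
  record
}

#' Sliding-window specification
#'
#' @param window_length Window length in time steps (default 20, the
#'   pretraining window size).
#' @param stride Step between consecutive window starts; 10 is used for
#'   pretraining and 1 for downstream classification.
#' @return A `sliding_window_spec` list.
#' @export
sliding_window_spec <- function(window_length = 20L, stride = 10L) {
  window_length <- as.integer(window_length)
  stride <- as.integer(stride)
  stopifnot(window_length >= 1L, stride >= 1L)
  structure(list(window_length = window_length, stride = stride),
            class = "sliding_window_spec")
}

#' Extract sliding windows from a record
#'
#' Cuts the time axis into `floor((T - window_length) / stride) + 1`
#' contiguous windows.  Start indices are 0-based and windows are the
#' half-open intervals `[s, s + window_length)`; trailing time points not
#' covered by a full window are dropped.
#'
#' @param record A [timecourse_record].
#' @param spec A [sliding_window_spec].
#' @return A `window_tensor`: list with `windows` (array
#'   `n_windows x C x window_length`) and `start_indices` (0-based).
#' @examples
#' rec <- timecourse_record("s", matrix(rnorm(53 * 140), 53, 140))
#' wt <- make_windows(rec, sliding_window_spec(20, 10))
#' dim(wt$windows)   # 13 x 53 x 20
#' @export
make_windows <- function(record, spec = sliding_window_spec()) {
  x <- record$data
  Tn <- ncol(x)
  w <- spec$window_length
  if (Tn < w) stop("record has T=", Tn, " < window_length=", w)
  starts <- seq.int(0L, Tn - w, by = spec$stride)
  n <- length(starts)
  arr <- array(0, dim = c(n, nrow(x), w))
  for (j in seq_len(n)) {
    arr[j, , ] <- x[, (starts[j] + 1L):(starts[j] + w)]
  }
  structure(list(windows = arr, start_indices = starts,
                 window_length = w, stride = spec$stride, T = Tn),
            class = "window_tensor")
}
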
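#' ROI time-series object
#'
#' Container for one fMRI scan: an M x N matrix of BOLD signals with rows as
#' time points and columns as regions of interest (ROIs), plus scan/subject
#' identifiers and an optional binary class label.
#'
#' @param values Numeric matrix, M time points x N ROIs. All entries must be
#'   finite, with M >= 3 and N >= 2.
#' @param scan_id Character scalar identifying the scan.
#' @param subject_id Character scalar identifying the subject (a subject may
#'   own several scans).
#' @param label Optional class label (character scalar), e.g. `"MCI"`.
#' @param check_variance If `TRUE` (default), reject columns with zero sample
#'   variance; constant ROI signals carry no correlation information.
#' @return An object of class `roi_timeseries`.
#' @export
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(30), 10, 3), scan_id = "s1",
#'                      subject_id = "sub1")
#' dim(ts$values)
roi_timeseries <- function(values, scan_id = "scan", subject_id = "subject",
                           label = NULL, check_variance = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop_validation("time-series matrix contains non-finite entries")
  }
  if (nrow(values) < 3L) {
    stop_validation("need at least 3 time points, got ", nrow(values))
  }
  if (ncol(values) < 2L) {
    stop_validation("need at least 2 ROIs, got ", ncol(values))
  }
  if (check_variance) {
    v <- apply(values, 2L, stats::var)
    bad <- which(v <= 0)
    if (length(bad)) {
      stop_degenerate("ROI column(s) with zero variance: ",
                      paste(bad, collapse = ", "))
    }
  }
  structure(
    list(values = values,
         scan_id = as.character(scan_id),
         subject_id = as.character(subject_id),
         label = if (is.null(label)) NULL else as.character(label)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> scan '%s', subject '%s'%s: %d time points x %d ROIs\n",
              x$scan_id, x$subject_id,
              if (is.null(x$label)) "" else sprintf(" [%s]", x$label),
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Center and normalize ROI signals
#'
#' Subtracts the temporal mean from each ROI signal and scales it to unit
#' Euclidean norm, so that the Pearson correlation between two ROIs reduces
#' to the plain inner product of their standardized signals.
#'
#' @param ts An [roi_timeseries()].
#' @return An `roi_timeseries` whose columns each have mean 0 and norm 1.
#' @export
standardize_signals <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- ts$values
  X <- sweep(X, 2L, colMeans(X), "-")
  nrm <- sqrt(colSums(X^2))
  bad <- which(nrm <= 0)
  if (length(bad)) {
    stop_degenerate("constant ROI signal at column(s): ",
                    paste(bad, collapse = ", "))
  }
  out <- ts
  out$values <- sweep(X, 2L, nrm, "/")
  out
}
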
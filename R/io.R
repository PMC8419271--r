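#' Read an ROI time-series file
#'
#' Reads a delimited text matrix with rows as time points and columns as
#' ROIs (tab-separated by default; comma accepted). An optional single
#' header row of ROI names is detected by its non-numeric cells; there must
#' be no index column.
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the first line.
#' @param scan_id,subject_id,label Metadata for the resulting object;
#'   `scan_id` defaults to the file name.
#' @return An [roi_timeseries()].
#' @export
read_timeseries <- function(path, sep = NULL, scan_id = NULL,
                            subject_id = "subject", label = NULL) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop_validation("empty file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  cells <- strsplit(first, sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells)))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          check.names = FALSE)
  nc <- vapply(df, is.numeric, logical(1))
  if (!all(nc)) {
    stop_validation("non-numeric cells in column(s): ",
                    paste(which(!nc), collapse = ", "))
  }
  X <- as.matrix(df)
  if (!has_header) colnames(X) <- NULL
  roi_timeseries(X, scan_id = scan_id %||% basename(path),
                 subject_id = subject_id, label = label)
}

#' Write / read an adjacency matrix
#'
#' `write_adjacency()` writes the full square matrix as TSV with 17
#' significant digits (lossless for doubles) plus a JSON sidecar
#' (`<path>.json`) carrying the order, degenerate nodes and, when present,
#' the convergence report. `read_adjacency()` restores and validates the
#' object; an asymmetric or out-of-range matrix is a validation error.
#'
#' @param R An [adjacency_matrix()].
#' @param path Output TSV path.
#' @return `write_adjacency()` returns `path` invisibly; `read_adjacency()`
#'   returns the [adjacency_matrix()].
#' @export
write_adjacency <- function(R, path) {
  stopifnot(inherits(R, "adjacency_matrix"))
  lines <- apply(R$values, 1L, function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = "\t")
  })
  writeLines(lines, path)
  meta <- list(order = R$order, degenerate_nodes = R$degenerate_nodes)
  rep <- attr(R, "report")
  if (!is.null(rep)) {
    meta$tol <- rep$tol
    meta$converged <- rep$converged
    meta$n_converged <- if (is.na(rep$n_converged)) NULL else rep$n_converged
    meta$step_deltas <- rep$step_deltas
    meta$binariness <- rep$binariness
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_adjacency
#' @param order Override the order when no sidecar is present.
#' @export
read_adjacency <- function(path, order = NULL) {
  X <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(X) <- NULL
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  adjacency_matrix(X,
                   order = order %||% meta$order %||% 1L,
                   degenerate_nodes = unlist(meta$degenerate_nodes) %||%
                     integer(0))
}

#' Read a scan manifest
#'
#' A manifest is a CSV with columns `scan_path`, `subject_id`, `label`
#' mapping time-series files (paths relative to the manifest's directory,
#' or absolute) to subjects and class labels.
#'
#' @param path Manifest CSV path.
#' @return Data frame with columns `scan_path` (absolute), `subject_id`,
#'   `label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_path", "subject_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_validation("manifest missing column(s): ", paste(miss, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$scan_path)
  df$scan_path[rel] <- file.path(dirname(path), df$scan_path[rel])
  df[need]
}

#' Load a labeled dataset from a manifest
#'
#' Reads every scan listed in the manifest, computes its networks at the
#' requested orders and assembles a [labeled_dataset()].
#'
#' @param path Manifest CSV path (see [read_manifest()]).
#' @param orders Order tags to compute per scan (numbers and/or `"conv"`).
#' @param tol,max_iter Convergence settings for `"conv"`.
#' @param positive_class Positive class; defaults to the first label in the
#'   manifest.
#' @return A [labeled_dataset()].
#' @export
load_dataset <- function(path, orders = c("1", "conv"), tol = 1e-6,
                         max_iter = 30L, positive_class = NULL) {
  man <- read_manifest(path)
  scans <- lapply(seq_len(nrow(man)), function(i) {
    ts <- read_timeseries(man$scan_path[i], subject_id = man$subject_id[i],
                          label = man$label[i])
    list(networks = compute_orders(ts, orders, tol = tol, max_iter = max_iter),
         scan_id = basename(man$scan_path[i]),
         subject_id = man$subject_id[i], label = man$label[i])
  })
  labeled_dataset(scans, positive_class = positive_class %||% man$label[1L])
}

#' Write a simulated dataset to disk
#'
#' Materializes a [synthetic_spec()] as one TSV per scan plus a
#' `manifest.csv`, and echoes the generating spec to `spec.json`, so the
#' files can be consumed by [load_dataset()] or the command-line interface.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_simulated_scans <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  idx <- 0L
  for (group in c("negative", "positive")) {
    for (s in seq_len(spec$n_subjects_per_group)) {
      subject_id <- sprintf("%s_sub%03d", group, s)
      for (r in seq_len(spec$scans_per_subject)) {
        idx <- idx + 1L
        subject_seed <- (if (group == "positive") 1000000L else 0L) +
          s * 100L + r
        ts <- simulate_scan(spec, group, subject_seed = subject_seed,
                            subject_id = subject_id, label = group)
        fn <- sprintf("%s_r%02d.tsv", subject_id, r)
        utils::write.table(
          formatC(ts$values, digits = 17, format = "g"),
          file.path(out_dir, fn), sep = "\t", quote = FALSE,
          row.names = FALSE, col.names = FALSE)
        rows[[idx]] <- data.frame(scan_path = fn, subject_id = subject_id,
                                  label = group)
      }
    }
  }
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  spec_out <- spec
  spec_out$differing_edges <- as.list(spec$differing_edges)
  jsonlite::write_json(unclass(spec_out), file.path(out_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Serialize an experiment result to JSON
#'
#' Writes the per-condition pooled and per-fold metrics, feature counts and
#' selected fusion weights of an [run_experiment()] result as a single JSON
#' document for machine consumption.
#'
#' @param res An `experiment_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_experiment_json <- function(res, path) {
  stopifnot(inherits(res, "experiment_result"))
  strip <- function(m) m[c("TP", "TN", "FP", "FN", "ACC", "SEN", "SPE")]
  out <- list(
    seed = attr(res, "seed"), k = attr(res, "k"), mode = attr(res, "mode"),
    orders = attr(res, "orders"), p_grid = attr(res, "p_grid"),
    results = lapply(res, function(entry) {
      e <- list(metrics = strip(entry$metrics),
                per_fold = lapply(entry$per_fold, strip),
                n_features_selected = entry$n_features_selected)
      if (!is.null(entry$lambda_selected)) {
        e$lambda_selected <- entry$lambda_selected
      }
      e
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
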
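#' Adjacency matrix of a brain functional network
#'
#' An N x N symmetric correlation matrix with unit diagonal, tagged with the
#' order n of the iterated-correlation operator that produced it (n = 1 is
#' ordinary Pearson correlation of the ROI signals).
#'
#' @param values Numeric N x N matrix; must be symmetric to within 1e-12,
#'   have diagonal exactly 1 and all entries in \[-1, 1\].
#' @param order Positive integer order n.
#' @param degenerate_nodes Integer vector of ROI indices whose correlation
#'   profile was constant at this order (only non-empty under the
#'   `"zero"` degeneracy policy).
#' @return An object of class `adjacency_matrix`.
#' @export
adjacency_matrix <- function(values, order = 1L, degenerate_nodes = integer(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (ncol(values) != n) stop_validation("adjacency matrix must be square")
  if (max(abs(values - t(values))) > 1e-12) {
    stop_validation("adjacency matrix is not symmetric (tolerance 1e-12)")
  }
  if (any(diag(values) != 1)) {
    stop_validation("adjacency matrix diagonal must be exactly 1")
  }
  if (any(values < -1 | values > 1)) {
    stop_validation("adjacency entries must lie in [-1, 1]")
  }
  order <- as.integer(order)
  if (is.na(order) || order < 1L) stop_validation("order must be a positive integer")
  structure(
    list(values = values, order = order,
         degenerate_nodes = as.integer(sort(unique(degenerate_nodes)))),
    class = "adjacency_matrix"
  )
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("<adjacency_matrix> %d x %d, order %d%s\n",
              nrow(x$values), ncol(x$values), x$order,
              if (length(x$degenerate_nodes))
                sprintf(" (%d degenerate nodes)", length(x$degenerate_nodes))
              else ""))
  invisible(x)
}

# Enforce exact symmetry, unit diagonal and [-1, 1] range after a
# floating-point update; the exact-arithmetic properties of the iteration
# must survive round-off. Entries within 1e-14 of +/-1 are rounded to the
# exact limit so that sign-matrix fixed points and perfectly (anti)correlated
# pairs keep their closed-form values under fused-multiply-add BLAS kernels.
sanitize_correlation <- function(R) {
  R <- (R + t(R)) / 2
  snap <- abs(abs(R) - 1) < 1e-14
  R[snap] <- sign(R[snap])
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

#' Centering matrix
#'
#' Returns the symmetric idempotent matrix C = I - E/N (E all-ones) that
#' subtracts the mean from every length-N vector it multiplies. This is the
#' constant matrix of the iterated-correlation update.
#'
#' @param N Dimension, at least 2.
#' @return N x N numeric matrix.
#' @export
#' @examples
#' centering_matrix(2)
centering_matrix <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop_validation("N must be an integer >= 2")
  diag(N) - matrix(1 / N, N, N)
}

#' First-order Pearson correlation network
#'
#' Estimates the PC^1 brain functional network: the edge weight between ROIs
#' i and j is the Pearson correlation coefficient of their signals, i.e.
#' R = X'X for the column-standardized data matrix X.
#'
#' @param ts An [roi_timeseries()].
#' @return An [adjacency_matrix()] with `order = 1`.
#' @export
pearson_bfn <- function(ts) {
  Z <- standardize_signals(ts)
  R <- crossprod(Z$values)
  adjacency_matrix(sanitize_correlation(R), order = 1L)
}

#' One step of the iterated-correlation update
#'
#' Maps R to D^(-1/2) (R C R) D^(-1/2), where C is the [centering_matrix()]
#' and D = diag(R C R). Because C is symmetric idempotent, R C R =
#' (CR)'(CR), so the update is exactly the Pearson correlation matrix of the
#' rows of R treated as new "signals": each ROI's correlation profile
#' becomes its signal at the next order.
#'
#' @param R An [adjacency_matrix()] at order n.
#' @param policy What to do when a row of `R` is (numerically) constant so
#'   that its centered profile has zero norm: `"error"` (default) raises a
#'   degenerate-node error; `"zero"` zero-fills that node's off-diagonal
#'   entries and records its index in `degenerate_nodes`.
#' @param eps Degeneracy threshold on the diagonal of R C R (default 1e-12).
#' @return An [adjacency_matrix()] at order n + 1.
#' @export
pcn_step <- function(R, policy = c("error", "zero"), eps = 1e-12) {
  stopifnot(inherits(R, "adjacency_matrix"))
  policy <- match.arg(policy)
  V <- R$values
  N <- nrow(V)
  # multiply by the explicit centering matrix (rather than subtracting
  # column means) so that sign symmetries of V survive in floating point;
  # with C idempotent this equals (CV)'(CV), the rows-as-signals Gram matrix
  M <- V %*% centering_matrix(N) %*% V
  d <- diag(M)
  degenerate <- which(d < eps)
  if (length(degenerate) && policy == "error") {
    stop_degenerate("degenerate node(s) with constant correlation profile: ",
                    paste(degenerate, collapse = ", "))
  }
  d_safe <- ifelse(d < eps, 1, d)
  Rn <- M / sqrt(outer(d_safe, d_safe))
  if (length(degenerate)) {
    Rn[degenerate, ] <- 0
    Rn[, degenerate] <- 0
  }
  adjacency_matrix(sanitize_correlation(Rn), order = R$order + 1L,
                   degenerate_nodes = union(R$degenerate_nodes, degenerate))
}

# Fraction-of-binariness diagnostic: 1 when every off-diagonal entry is at
# +/-1, 0 when all are at 0. Mean over the off-diagonal of 1 - (1 - |r|).
binariness_score <- function(V) {
  off <- V[upper.tri(V)]
  if (!length(off)) return(NA_real_)
  mean(abs(off))
}

#' Generate the PC^n network sequence
#'
#' Computes the first-order Pearson network and repeatedly applies
#' [pcn_step()], recording per-step max-abs differences and binariness
#' scores. Iteration stops at `n_max`, or earlier when consecutive matrices
#' differ by less than `tol` (max-abs elementwise) and `stop_on_convergence`
#' is set.
#'
#' @param ts An [roi_timeseries()].
#' @param n_max Maximum order to compute (>= 1).
#' @param tol Convergence tolerance on the max-abs elementwise difference
#'   between consecutive matrices (default 1e-6).
#' @param stop_on_convergence Stop at the first converged order (default
#'   `TRUE`).
#' @param policy Degenerate-node policy passed to [pcn_step()].
#' @return An object of class `bfn_sequence`: a list with `matrices` (the
#'   [adjacency_matrix()] objects at orders 1..n) and `report`, a
#'   `convergence_report` with fields `converged`, `n_converged`,
#'   `step_deltas`, `binariness`, `tol` and `max_iter`.
#' @export
pcn_sequence <- function(ts, n_max = 30L, tol = 1e-6,
                         stop_on_convergence = TRUE,
                         policy = c("error", "zero")) {
  policy <- match.arg(policy)
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop_validation("n_max must be >= 1")
  if (!is.numeric(tol) || tol <= 0) stop_validation("tol must be positive")

  matrices <- vector("list", n_max)
  matrices[[1L]] <- pearson_bfn(ts)
  deltas <- numeric(0)
  binar <- binariness_score(matrices[[1L]]$values)
  converged <- FALSE
  n_converged <- NA_integer_
  n_done <- 1L
  while (n_done < n_max) {
    nxt <- tryCatch(
      pcn_step(matrices[[n_done]], policy = policy),
      pcn_degenerate_error = function(e) {
        stop_degenerate(conditionMessage(e), " (arising at order ",
                        n_done + 1L, ")")
      }
    )
    n_done <- n_done + 1L
    matrices[[n_done]] <- nxt
    delta <- max(abs(nxt$values - matrices[[n_done - 1L]]$values))
    deltas <- c(deltas, delta)
    binar <- c(binar, binariness_score(nxt$values))
    if (!converged && delta < tol) {
      converged <- TRUE
      n_converged <- n_done
      if (stop_on_convergence) break
    }
  }
  structure(
    list(
      matrices = matrices[seq_len(n_done)],
      report = structure(
        list(converged = converged, n_converged = n_converged,
             step_deltas = deltas, binariness = binar,
             tol = tol, max_iter = n_max),
        class = "convergence_report"
      )
    ),
    class = "bfn_sequence"
  )
}

#' @export
print.bfn_sequence <- function(x, ...) {
  r <- x$report
  cat(sprintf("<bfn_sequence> %d matrices (N = %d), %s\n",
              length(x$matrices), nrow(x$matrices[[1L]]$values),
              if (r$converged)
                sprintf("converged at order %d (tol %g)", r$n_converged, r$tol)
              else sprintf("not converged within %d orders (tol %g)",
                           r$max_iter, r$tol)))
  invisible(x)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> converged: %s; iterations: %d; tol: %g\n",
              x$converged, length(x$step_deltas) + 1L, x$tol))
  if (x$converged) cat(sprintf("  n_converged: %d\n", x$n_converged))
  cat(sprintf("  final step delta: %s; final binariness: %.4f\n",
              if (length(x$step_deltas))
                format(x$step_deltas[length(x$step_deltas)]) else "NA",
              x$binariness[length(x$binariness)]))
  invisible(x)
}

#' Empirically converged network
#'
#' Iterates the correlation operator until consecutive matrices agree to
#' `tol`, capped at `max_iter` orders (default 30). Non-convergence within
#' the cap is not an error; it is recorded in the attached report.
#'
#' @inheritParams pcn_sequence
#' @param max_iter Iteration cap (default 30).
#' @return The final [adjacency_matrix()] with the sequence's
#'   `convergence_report` attached as attribute `"report"`.
#' @export
converged_bfn <- function(ts, tol = 1e-6, max_iter = 30L,
                          policy = c("error", "zero")) {
  seq <- pcn_sequence(ts, n_max = max_iter, tol = tol,
                      stop_on_convergence = TRUE, policy = match.arg(policy))
  out <- seq$matrices[[length(seq$matrices)]]
  attr(out, "report") <- seq$report
  out
}
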
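#' Numerical rank along a network sequence
#'
#' Counts, for each matrix in the sequence, the singular values exceeding
#' `rel_tol` times the largest one. The rank sequence is expected to be
#' non-increasing, because each update is a congruence-like product whose
#' rank cannot exceed that of its factors; a violation raises a warning
#' naming the offending pair rather than an error, since the property is
#' checked in floating point.
#'
#' @param seq A `bfn_sequence` from [pcn_sequence()].
#' @param rel_tol Relative singular-value threshold in (0, 1), default 1e-8.
#' @return Integer vector of numerical ranks, one per order.
#' @export
rank_sequence <- function(seq, rel_tol = 1e-8) {
  stopifnot(inherits(seq, "bfn_sequence"), length(seq$matrices) >= 1L)
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol >= 1) {
    stop_validation("rel_tol must lie in (0, 1)")
  }
  ranks <- vapply(seq$matrices, function(A) {
    s <- svd(A$values, nu = 0L, nv = 0L)$d
    sum(s > rel_tol * s[1L])
  }, integer(1))
  drops <- which(diff(ranks) > 0L)
  if (length(drops)) {
    warning(sprintf(
      "numerical rank increased between orders %s; expected non-increasing",
      paste(sprintf("%d->%d", drops, drops + 1L), collapse = ", ")))
  }
  ranks
}

#' Off-diagonal sign changes between consecutive orders
#'
#' For each consecutive pair of matrices, counts the strict upper-triangle
#' entries whose sign differs (zero counts as its own sign). Near
#' convergence a small number of entries is expected to flip sign once and
#' then stabilize.
#'
#' @param seq A `bfn_sequence` with at least two matrices.
#' @return Integer vector of length `length(seq$matrices) - 1`.
#' @export
sign_change_count <- function(seq) {
  stopifnot(inherits(seq, "bfn_sequence"))
  if (length(seq$matrices) < 2L) {
    stop_validation("need at least two matrices to count sign changes")
  }
  vapply(seq_len(length(seq$matrices) - 1L), function(k) {
    a <- seq$matrices[[k]]$values
    b <- seq$matrices[[k + 1L]]$values
    ut <- upper.tri(a)
    sum(sign(a[ut]) != sign(b[ut]))
  }, integer(1))
}

#' Fixed-point residual of the iterated-correlation map
#'
#' Returns max |step(R) - R|. The residual is zero (<= 1e-12) exactly when R
#' is a fixed point of the map; any sign-vector outer product s s' with both
#' signs present is one.
#'
#' @param R An [adjacency_matrix()].
#' @param policy Degenerate-node policy passed to [pcn_step()].
#' @return Non-negative scalar.
#' @export
fixed_point_residual <- function(R, policy = c("error", "zero")) {
  stopifnot(inherits(R, "adjacency_matrix"))
  nxt <- pcn_step(R, policy = match.arg(policy))
  max(abs(nxt$values - R$values))
}

#' Full diagnostics for a network sequence
#'
#' Bundles [rank_sequence()], [sign_change_count()], per-order
#' [fixed_point_residual()] and the binariness scores into one report.
#'
#' @param seq A `bfn_sequence`.
#' @param rel_tol Relative rank threshold, see [rank_sequence()].
#' @return An object of class `sequence_diagnostics`: list with `ranks`,
#'   `sign_changes`, `fixed_point_residual` and `binariness`, all aligned
#'   with the sequence orders (`sign_changes` one shorter).
#' @export
sequence_diagnostics <- function(seq, rel_tol = 1e-8) {
  stopifnot(inherits(seq, "bfn_sequence"))
  structure(
    list(
      ranks = rank_sequence(seq, rel_tol),
      sign_changes = if (length(seq$matrices) >= 2L) sign_change_count(seq)
                     else integer(0),
      fixed_point_residual = vapply(seq$matrices, fixed_point_residual,
                                    numeric(1), policy = "zero"),
      binariness = seq$report$binariness
    ),
    class = "sequence_diagnostics"
  )
}

#' @export
print.sequence_diagnostics <- function(x, ...) {
  cat("<sequence_diagnostics>\n")
  cat("  ranks:        ", paste(x$ranks, collapse = " "), "\n")
  cat("  sign changes: ", paste(x$sign_changes, collapse = " "), "\n")
  cat("  fp residuals: ", paste(signif(x$fixed_point_residual, 3),
                                collapse = " "), "\n")
  cat("  binariness:   ", paste(round(x$binariness, 4), collapse = " "), "\n")
  invisible(x)
}
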
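# Independent oracles and small fixture builders used across the suite.

# Scalar Pearson coefficient computed directly from its definition.
pearson_scalar <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Brute-force pairwise correlation of the COLUMNS of X via the scalar formula.
pearson_matrix_oracle <- function(X) {
  N <- ncol(X)
  R <- diag(N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      R[i, j] <- R[j, i] <- pearson_scalar(X[, i], X[, j])
    }
  }
  R
}

# Rows-as-signals oracle for one iteration step: correlate the rows of R.
row_pearson_oracle <- function(R) {
  pearson_matrix_oracle(t(R))
}

# A random correlation matrix of size N (sample correlation of Gaussian data).
random_correlation <- function(N, M = 4 * N) {
  stats::cor(matrix(stats::rnorm(M * N), M, N))
}

# Wrap a plain correlation matrix as an order-1 adjacency object.
as_adj <- function(V, order = 1L) {
  diag(V) <- 1
  V[V > 1] <- 1; V[V < -1] <- -1
  adjacency_matrix((V + t(V)) / 2, order = order)
}

# Random sign vector with both signs guaranteed.
random_sign_vector <- function(N) {
  s <- sample(c(-1, 1), N, replace = TRUE)
  s[1] <- 1
  s[2] <- -1
  s
}

# Assemble a bfn_sequence object from bare matrices (for diagnostics tests).
make_sequence <- function(mats) {
  matrices <- lapply(seq_along(mats), function(k) as_adj(mats[[k]], order = k))
  structure(
    list(matrices = matrices,
         report = structure(
           list(converged = FALSE, n_converged = NA_integer_,
                step_deltas = numeric(length(mats) - 1),
                binariness = vapply(matrices,
                                    function(m) mean(abs(m$values[upper.tri(m$values)])),
                                    numeric(1)),
                tol = 1e-6, max_iter = length(mats)),
           class = "convergence_report")),
    class = "bfn_sequence"
  )
}

# A quick Gaussian scan without planted structure.
gaussian_scan <- function(M, N, seed) {
  set.seed(seed)
  roi_timeseries(matrix(rnorm(M * N), M, N),
                 scan_id = paste0("g", seed), subject_id = paste0("g", seed))
}

# Small planted-signal study spec used by several classification tests.
small_study_spec <- function(seed, n_per_group = 14, N = 40, M = 80,
                             n_edges = 12) {
  synthetic_spec(N_rois = N, M_timepoints = M,
                 n_subjects_per_group = n_per_group,
                 block_sizes = rep(8, N / 8),
                 n_differing_edges = n_edges, delta_rho = 0.3,
                 ar1_coef = 0.3, seed = seed, preset = "none")
}
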
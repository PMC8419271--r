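#' Specification of a synthetic two-group ROI time-series study
#'
#' Defines the generating conditions for a balanced two-class dataset of
#' Gaussian ROI time series with block-structured correlation. The two
#' groups share a block-diagonal base correlation; the positive group
#' additionally receives planted edge differences (`differing_edges`), so
#' the class signal lives entirely in the first-order correlation structure.
#'
#' The `"adni"` preset emulates the shape of a resting-state cohort with 116
#' atlas ROIs and 137 retained volumes per scan and plants 30 edge
#' differences of size 0.3; the `"hcp"` preset emulates 100 ICA ROIs with
#' 1,200 volumes per session.
#'
#' @param N_rois Number of ROIs.
#' @param M_timepoints Time points per scan.
#' @param n_subjects_per_group Subjects per group.
#' @param scans_per_subject Scans per subject (all scans of a subject share
#'   its group label and generating covariance).
#' @param block_sizes Integer vector partitioning the ROIs into correlated
#'   blocks; must sum to `N_rois`.
#' @param within_block_rho Within-block correlation, either one value shared
#'   by both groups or a length-2 vector `(negative, positive)`. |rho| < 1.
#' @param differing_edges Data frame with columns `i`, `j`, `delta_rho`:
#'   edges whose correlation in the positive group is shifted by
#'   `delta_rho`. `NULL` plants `n_differing_edges` random edges.
#' @param n_differing_edges Number of random planted edges when
#'   `differing_edges` is `NULL`.
#' @param delta_rho Correlation shift for randomly planted edges.
#' @param ar1_coef Temporal AR(1) coefficient in \[0, 1) applied per ROI.
#' @param noise_sd Innovation standard deviation; must be positive.
#' @param heavy_tails If `TRUE`, scale each scan's innovations by an
#'   inverse-chi draw so the signals are multivariate-t-like rather than
#'   Gaussian (probes sensitivity of the moment-based estimator to
#'   non-Gaussianity).
#' @param seed Master seed; drives the planted-edge draw and all scans.
#' @param preset `"adni"`, `"hcp"` or `"none"`; presets fill defaults which
#'   explicit arguments then override.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(preset = "adni", n_subjects_per_group = 5, seed = 1)
#' spec$N_rois
synthetic_spec <- function(N_rois = NULL, M_timepoints = NULL,
                           n_subjects_per_group = NULL,
                           scans_per_subject = 1L,
                           block_sizes = NULL,
                           within_block_rho = 0.3,
                           differing_edges = NULL,
                           n_differing_edges = 30L,
                           delta_rho = 0.3,
                           ar1_coef = 0.3,
                           noise_sd = 1,
                           heavy_tails = FALSE,
                           seed = 7L,
                           preset = c("adni", "hcp", "none")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    adni = list(N_rois = 116L, M_timepoints = 137L, n_subjects_per_group = 72L),
    hcp  = list(N_rois = 100L, M_timepoints = 1200L, n_subjects_per_group = 50L),
    none = list(N_rois = 20L, M_timepoints = 60L, n_subjects_per_group = 20L))
  N_rois <- as.integer(N_rois %||% defaults$N_rois)
  M_timepoints <- as.integer(M_timepoints %||% defaults$M_timepoints)
  n_subjects_per_group <- as.integer(n_subjects_per_group %||%
                                       defaults$n_subjects_per_group)
  if (is.null(block_sizes)) {
    b <- rep(8L, N_rois %/% 8L)
    if (N_rois %% 8L) b <- c(b, N_rois %% 8L)
    block_sizes <- b
  }
  block_sizes <- as.integer(block_sizes)
  if (sum(block_sizes) != N_rois) {
    stop_validation("block_sizes must sum to N_rois")
  }
  if (length(within_block_rho) == 1L) {
    within_block_rho <- rep(within_block_rho, 2L)
  }
  if (any(abs(within_block_rho) >= 1)) {
    stop_validation("|within_block_rho| must be < 1")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop_validation("noise_sd must be positive (zero would give constant, ",
                    "rank-deficient ROI signals)")
  }
  if (ar1_coef < 0 || ar1_coef >= 1) {
    stop_validation("ar1_coef must lie in [0, 1)")
  }
  seed <- as.integer(seed)
  if (is.null(differing_edges)) {
    differing_edges <- if (n_differing_edges < 1L) {
      data.frame(i = integer(0), j = integer(0), delta_rho = numeric(0))
    } else {
      with_seed(seed, {
        pairs <- which(upper.tri(matrix(0, N_rois, N_rois)), arr.ind = TRUE)
        take <- sample.int(nrow(pairs), min(n_differing_edges, nrow(pairs)))
        data.frame(i = pairs[take, 1L], j = pairs[take, 2L],
                   delta_rho = delta_rho)
      })
    }
  }
  differing_edges <- as.data.frame(differing_edges)
  stopifnot(all(c("i", "j", "delta_rho") %in% names(differing_edges)))
  spec <- structure(
    list(N_rois = N_rois, M_timepoints = M_timepoints,
         n_subjects_per_group = n_subjects_per_group,
         scans_per_subject = as.integer(scans_per_subject),
         block_sizes = block_sizes,
         within_block_rho = within_block_rho,
         differing_edges = differing_edges,
         ar1_coef = ar1_coef, noise_sd = noise_sd,
         heavy_tails = isTRUE(heavy_tails), seed = seed),
    class = "synthetic_spec"
  )
  # fail fast if the requested correlation targets are not positive definite
  for (g in c("negative", "positive")) make_group_covariance(spec, g)
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d ROIs x %d time points; %d subjects/group x %d scan(s); %d planted edges; AR(1) %.2f; seed %d\n",
    x$N_rois, x$M_timepoints, x$n_subjects_per_group, x$scans_per_subject,
    nrow(x$differing_edges), x$ar1_coef, x$seed))
  invisible(x)
}

#' Group-specific generating correlation matrix
#'
#' Builds the block-diagonal compound-symmetry correlation for the given
#' group, applies the planted edge shifts for the positive group, and if the
#' edits make the target indefinite, repairs it to the nearest correlation
#' matrix by eigenvalue clipping followed by diagonal renormalization
#' (repair flagged via attribute `"repaired"`).
#'
#' @param spec A [synthetic_spec()].
#' @param group `"negative"` or `"positive"`.
#' @return N x N positive-definite correlation matrix.
#' @export
make_group_covariance <- function(spec, group = c("negative", "positive")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  group <- match.arg(group)
  rho <- spec$within_block_rho[if (group == "negative") 1L else 2L]
  N <- spec$N_rois
  S <- matrix(0, N, N)
  at <- 0L
  for (b in spec$block_sizes) {
    idx <- at + seq_len(b)
    S[idx, idx] <- rho
    at <- at + b
  }
  diag(S) <- 1
  if (group == "positive" && nrow(spec$differing_edges)) {
    de <- spec$differing_edges
    for (k in seq_len(nrow(de))) {
      v <- max(min(S[de$i[k], de$j[k]] + de$delta_rho[k], 0.99), -0.99)
      S[de$i[k], de$j[k]] <- v
      S[de$j[k], de$i[k]] <- v
    }
  }
  repaired <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 1e-8) {
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(S))
    S <- S / outer(d, d)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    repaired <- TRUE
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
      stop_validation("planted edge differences give a non-repairable ",
                      "indefinite correlation target")
    }
  }
  attr(S, "repaired") <- repaired
  S
}

# Stationary AR(1) filtering of an innovations matrix, column-wise, with
# variance renormalization so the marginal SD stays at the innovation SD.
ar1_filter <- function(E, phi) {
  if (phi == 0) return(E)
  Z <- apply(E, 2L, function(e) as.numeric(stats::filter(e, phi,
                                                         method = "recursive")))
  Z * sqrt(1 - phi^2)
}

#' Simulate one ROI scan
#'
#' Draws an M x N Gaussian matrix with the group's generating correlation:
#' innovations are AR(1)-filtered per ROI (restandardized to keep unit
#' marginal variance) and then mixed by the Cholesky factor of the group
#' correlation. Deterministic given `(spec$seed, subject_seed)`.
#'
#' @param spec A [synthetic_spec()].
#' @param group `"negative"` or `"positive"`.
#' @param subject_seed Integer distinguishing scans; combined with the
#'   master seed.
#' @param scan_id,subject_id,label Metadata forwarded to the result.
#' @return An [roi_timeseries()].
#' @export
simulate_scan <- function(spec, group = c("negative", "positive"),
                          subject_seed = 1L,
                          scan_id = NULL, subject_id = NULL, label = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  group <- match.arg(group)
  S <- make_group_covariance(spec, group)
  L <- chol(S)
  scan_seed <- (as.numeric(spec$seed) * 2654435761 + as.numeric(subject_seed)) %%
    (.Machine$integer.max - 1)
  X <- with_seed(as.integer(scan_seed), {
    E <- matrix(stats::rnorm(spec$M_timepoints * spec$N_rois, sd = spec$noise_sd),
                spec$M_timepoints, spec$N_rois)
    if (spec$heavy_tails) {
      # multivariate-t style scale mixing, df = 8
      w <- sqrt(8 / stats::rchisq(spec$M_timepoints, df = 8))
      E <- E * w
    }
    ar1_filter(E, spec$ar1_coef) %*% L
  })
  roi_timeseries(X,
                 scan_id = scan_id %||% sprintf("%s_scan%03d", group, subject_seed),
                 subject_id = subject_id %||% sprintf("%s_sub%03d", group, subject_seed),
                 label = label %||% group)
}

#' Simulate a labeled two-group dataset
#'
#' Generates the full balanced dataset defined by the spec and computes the
#' network matrices at the requested orders for every scan, producing a
#' classification-ready [labeled_dataset()].
#'
#' @param spec A [synthetic_spec()].
#' @param orders Character or integer vector of orders to compute per scan;
#'   numbers give PC^n at that exact order, `"conv"` the empirically
#'   converged network (see [converged_bfn()]).
#' @param tol,max_iter Convergence settings for order `"conv"`.
#' @param positive_class Name of the positive class label (default
#'   `"positive"`).
#' @return A [labeled_dataset()].
#' @export
simulate_dataset <- function(spec, orders = c("1", "conv"),
                             tol = 1e-6, max_iter = 30L,
                             positive_class = "positive") {
  stopifnot(inherits(spec, "synthetic_spec"))
  orders <- as.character(orders)
  scans <- list()
  idx <- 0L
  for (group in c("negative", "positive")) {
    for (s in seq_len(spec$n_subjects_per_group)) {
      subject_id <- sprintf("%s_sub%03d", group, s)
      for (r in seq_len(spec$scans_per_subject)) {
        idx <- idx + 1L
        subject_seed <- (if (group == "positive") 1000000L else 0L) +
          s * 100L + r
        ts <- simulate_scan(spec, group, subject_seed = subject_seed,
                            scan_id = sprintf("%s_r%02d", subject_id, r),
                            subject_id = subject_id, label = group)
        nets <- compute_orders(ts, orders, tol = tol, max_iter = max_iter)
        scans[[idx]] <- list(networks = nets, scan_id = ts$scan_id,
                             subject_id = subject_id, label = group)
      }
    }
  }
  labeled_dataset(scans, positive_class = positive_class)
}

# Compute the requested orders for one scan. Numeric orders reuse one pass
# of the iteration; "conv" runs to empirical convergence.
compute_orders <- function(ts, orders, tol = 1e-6, max_iter = 30L) {
  orders <- as.character(orders)
  num <- suppressWarnings(as.integer(orders[orders != "conv"]))
  if (anyNA(num)) stop_validation("orders must be integers or \"conv\"")
  nets <- list()
  if (length(num)) {
    seq_plain <- pcn_sequence(ts, n_max = max(num), tol = tol,
                              stop_on_convergence = FALSE)
    for (n in num) nets[[as.character(n)]] <- seq_plain$matrices[[n]]
  }
  if ("conv" %in% orders) {
    nets[["conv"]] <- converged_bfn(ts, tol = tol, max_iter = max_iter)
  }
  nets[orders]
}
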
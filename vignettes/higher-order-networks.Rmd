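---
title: "Iterated-correlation brain networks: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterated-correlation brain networks: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcn)
```

## The model

A brain functional network (BFN) represents each region of interest (ROI)
as a node and the statistical dependence between two ROIs' fMRI signals as
an edge weight. The simplest estimator is the Pearson correlation of the
ROI signals: for a scan $X \in \mathbb{R}^{M \times N}$ (M time points, N
ROIs) whose columns are centered and scaled to unit norm, the first-order
network is $R_1 = X^\top X$.

The package's core object is the *iterated* correlation sequence. Each row
of $R_1$ — ROI $i$'s correlation profile against all other ROIs — is
treated as a new "signal", and correlating those profiles gives a
second-order network $R_2$; repeating the operation yields $R_n$. With the
centering matrix $C = I - E/N$ ($E$ all-ones; symmetric and idempotent) one
application is

$$R_n = D^{-1/2} \, (R_{n-1} C R_{n-1}) \, D^{-1/2},
  \qquad D = \mathrm{diag}(R_{n-1} C R_{n-1}),$$

which `pcn_step()` implements. Because $C = C^\top C$, the product
$R C R = (CR)^\top (CR)$ is exactly the Gram matrix of the centered rows,
so the algebraic update and the rows-as-signals reading coincide; the test
suite asserts their agreement to $10^{-10}$ against a brute-force
row-by-row Pearson oracle.

Empirically the sequence converges, typically in 10–20 iterations for
Gaussian scans of realistic size, to a **binary sign matrix**: every
off-diagonal entry at $\pm 1$. Three structural facts instrumented by the
`diagnostics` functions make this plausible without a proof:

* the numerical rank of $R_n$ never increases (a product's rank is bounded
  by its factors'), and the observed limits have rank 1;
* the count of off-diagonal sign flips between consecutive orders falls to
  zero as the sequence settles;
* every sign-vector outer product $ss^\top$, $s \in \{-1,+1\}^N$ with both
  signs present, is an *exact* fixed point of the map (for such a matrix
  row $i$ equals $s_i \cdot s$, so row correlations are $s_i s_j$), and
  `fixed_point_residual()` of an empirically converged network is at the
  convergence tolerance.

No claim is made that convergence always occurs or that the limit is
unique; `pcn_sequence()` records non-convergence in its report rather than
failing.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `tol` | `1e-6` | convergence threshold on the max-abs elementwise difference between consecutive matrices (correlation units). The criterion is max-abs rather than a norm so a single drifting edge cannot hide. |
| `max_iter` | `30` | iteration cap for `converged_bfn()`; chosen because the empirical limit is reliably reached well inside 30 orders at realistic N, M. |
| `policy` | `"error"` | what to do when an ROI's correlation profile becomes constant (zero-variance row): refuse, or zero-fill that node's edges and record it (`"zero"`). |
| `p_threshold` / `p_grid` | `0.05, 0.01, 0.005, 0.001` | two-sample t-test edge-selection thresholds; selection always precedes the classifier because edges (N(N−1)/2, e.g. 6,670 at N = 116) far outnumber scans. |
| `C` (SVM cost) | `1` | the linear SVM's regularization constant, fixed at its default; no hyperparameter search by design. |
| `lambda_grid` | `0.1 … 0.9` | candidate weights for late fusion $\lambda O_1 + (1-\lambda) O_2$ of the low-order and higher-order classifiers' probabilities, chosen per outer fold by an inner 5-fold CV. |
| `k`, `inner_k` | `5` | outer and inner cross-validation folds, assigned at the **subject** level. |

## Numerical choices

* After every update the matrix is re-symmetrized, clipped to $[-1, 1]$ and
  its diagonal forced to 1, so round-off cannot push entries outside the
  correlation range. Additionally, entries within $10^{-14}$ of $\pm 1$ are
  rounded to the exact limit: fused multiply-add BLAS kernels otherwise
  leave sign-matrix fixed points and the two-ROI closed form ($[[1, r], [r,
  1]] \mapsto [[1, -1], [-1, 1]]$ for any $|r| < 1$) one ulp short of their
  exact-arithmetic values. At $10^{-14}$ the snap is far below any
  statistical resolution.
* The step multiplies by the explicit centering matrix rather than
  subtracting column means; the two are algebraically identical, but the
  explicit product preserves sign symmetries of the input in floating
  point.
* Numerical rank counts singular values above `rel_tol = 1e-8` times the
  largest; exact rank is meaningless in floating point.
* Degeneracy of a node is declared when its diagonal entry of $R C R$ falls
  below $10^{-12}$. A converged off-diagonal entry numerically at 0 is
  reported as-is; no sign is forced.
* An entry of the binariness diagnostic (mean off-diagonal $|r|$, in
  $[0,1]$) is attached per order; it is a descriptive score, not a test
  statistic.

## The classification protocol

Edge weights (strict upper triangle, row-major) are the features. The
protocol mirrors standard connectome-classification practice and is
strictly leakage-free:

1. **Subject-level folds.** Subjects — not scans — are shuffled by seed,
   stratified by (majority) label, and dealt into k folds whose sizes
   differ by at most one subject. All scans of a subject share a fold.
2. **Per-training-fold selection.** Two-sample pooled-variance t-tests
   (Welch optional) on training scans only; edges with $p$ below the
   threshold enter the classifier. `selection_scope = "global"` reproduces
   whole-dataset selection for feature-count audits but is flagged as
   leaking.
3. **Linear SVM, C = 1**, with Platt-style sigmoid calibration (soft
   targets, fitted on training decision values) mapping margins to
   positive-class probabilities. With an empty selection the classifier
   degrades to the training prior, with a warning.
4. **Fusion mode.** Two classifiers — low-order and higher-order — are
   trained per fold; $\lambda$ is chosen from the grid by an inner
   subject-level 5-fold CV of the whole pipeline on the training fold
   (ties break toward 0.5, then the smaller value), and the fused
   probability $\lambda O_1 + (1-\lambda) O_2$ scores the test fold.
5. **Metrics.** ACC, SEN, SPE from pooled test-fold confusion counts
   (positive class configurable; multiple scans of a subject are scored
   independently, so counts are per-scan). Zero-denominator metrics are
   reported as `NaN`, never silently dropped.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` draws Gaussian scans with block-diagonal
compound-symmetry correlation (blocks of 8 ROIs at within-block rho 0.3 by
default, emulating functional modules), per-ROI AR(1) temporal smoothing
(coefficient 0.3, restandardized), and a positive group whose generating
correlation differs on a fixed set of planted edges. The `"adni"` preset
uses the shapes of a clinical resting-state cohort (116 ROIs × 137
volumes, 72 subjects per group, one scan each, 30 planted edges of
Δρ = 0.3); `"hcp"` uses 100 ROIs × 1,200 volumes at desk scale (50
subjects/group). Gaussianity is chosen deliberately: the estimator is
moment-based, so planted correlations are exact population targets; a
Student-t scale-mixing flag (`heavy_tails`) probes non-Gaussian signals.

The generator does **not** model hemodynamics, scanner drift, motion
artifacts, spatially varying noise, or site effects. Passing tests
therefore demonstrate the estimator's and protocol's mathematical
behavior — convergence, rank decay, leakage-freedom, trend direction — not
clinical performance; accuracies on real cohorts are outside what synthetic
data can certify.

Because the class signal is planted in *first-order* correlations, the
package's headline property reproduces on synthetic data: classification
on converged-network features collapses toward chance (the binary limit
washes out graded group differences), and the number of t-test-selected
edges at $p = 0.001$ decays from order 1 to the converged order. The test
suite checks both trends over 10 seeds at desk scale (40 ROIs × 80 time
points, 16 subjects/group), allowing one inversion; the acceptance script
measures the chance-level collapse at the full preset scale (problem
sizes: 144 scans of 137 × 116 per master seed, 10 seeds).

## Known limitations

* Convergence is instrumented, not proved; `max_iter` guards pathological
  inputs, and sequences that have not converged are reported as such.
* The degenerate-node zero-fill policy makes the affected matrix leave the
  strict correlation manifold (zero off-diagonals are not correlations of
  anything); it exists to keep batch runs alive and is off by default.
* Lambda selection consumes one more CV layer than the sample sizes of
  small synthetic studies comfortably support; with very few subjects per
  inner fold the inner accuracy surface is noisy and the tie-break toward
  0.5 matters.
* With `selection_scope = "global"` the reported accuracies are optimistic
  by construction; the option exists only to mirror feature-count
  bookkeeping of whole-dataset workflows.
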
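# pcn — higher-order brain functional networks by iterated Pearson correlation

Functional connectomics usually summarizes a resting-state fMRI scan as a
Pearson-correlation matrix over brain regions (ROIs): nodes are regions,
edge weights are the correlations of their BOLD signals. `pcn` studies what
happens when the correlation operation is **iterated**: the first-order
network `R1 = XᵀX` (columns of `X` centered, unit norm) is itself treated
as a data matrix whose rows are new "signals", giving a second-order
network, then a third, and so on. One step of the iteration is

```
R_n = D^(-1/2) (R_{n-1} C R_{n-1}) D^(-1/2),   C = I - E/N,   D = diag(R_{n-1} C R_{n-1})
```

with `E` the all-ones matrix — algebraically identical to Pearson
correlation of the previous network's rows. The package is for researchers
who want to (a) compute and inspect this PC^n sequence, (b) instrument its
striking empirical behavior — the matrices converge, usually within 10–20
iterations, to a **binary sign matrix** with off-diagonal entries ±1, with
non-increasing numerical rank along the way and sign-vector outer products
`ssᵀ` as exact fixed points — and (c) quantify how much discriminative
information survives at each order, via a leakage-free subject-level
cross-validated classification protocol (two-sample t-test edge selection,
linear SVM with C = 1, ACC/SEN/SPE, and late fusion `λO1 + (1−λ)O2` of
low- and higher-order classifiers with λ chosen by inner cross-validation).

A synthetic generator produces balanced two-group cohorts of Gaussian ROI
time series with block covariance, AR(1) temporal smoothing and planted
edge differences, so the whole pipeline runs end to end without clinical
data.

## Worked example

```r
library(pcn)

spec <- synthetic_spec(preset = "none", n_subjects_per_group = 20, seed = 42)
ds   <- simulate_dataset(spec, orders = c("1", "2", "conv"))

seq <- pcn_sequence(simulate_scan(spec, "negative", 1), tol = 1e-6)
seq
#> <bfn_sequence> 8 matrices (N = 20), converged at order 8 (tol 1e-06)
sequence_diagnostics(seq)
#> <sequence_diagnostics>
#>   ranks:         20 19 19 11 4 2 1 1
#>   sign changes:  23 8 0 0 0 0 0
#>   fp residuals:  0.627 0.549 0.542 0.298 0.0196 5.12e-05 3.4e-10 0
#>   binariness:    0.2101 0.5101 0.8047 0.9498 0.9972 1 1 1

run_experiment(ds, orders = c("1", "2", "conv"), p_grid = c(0.05, 0.001),
               mode = "single", k = 5, seed = 42)
#> <experiment_result> mode 'single', k = 5, seed = 42
#>   order=1,p=0.05           ACC 1.000  SEN 1.000  SPE 1.000
#>   order=2,p=0.05           ACC 0.975  SEN 0.950  SPE 1.000
#>   order=conv,p=0.05        ACC 0.675  SEN 0.700  SPE 0.650
#>   order=1,p=0.001          ACC 1.000  SEN 1.000  SPE 1.000
#>   order=2,p=0.001          ACC 0.950  SEN 0.950  SPE 0.950
#>   order=conv,p=0.001       ACC 0.525  SEN 0.900  SPE 0.150
```

Reading the output: the one-scan sequence converges at order 8 — rank
decays 20 → 1, sign flips stop, the fixed-point residual reaches 0 and the
binariness score reaches 1 (all off-diagonal entries at ±1). The
experiment shows the package's central finding on data whose group
difference is planted in first-order correlations: order-1 edge features
classify perfectly, order-2 nearly so, and the converged binary network
has lost most of the signal — accuracy falls toward chance (0.525 at
p = 0.001). Each `ACC/SEN/SPE` row pools test predictions from a 5-fold
subject-level cross-validation with per-training-fold t-test selection at
the stated p-threshold.

See the vignette (`vignettes/higher-order-networks.Rmd`) for the model,
the protocol's leakage guarantees, and all numerical design choices.

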
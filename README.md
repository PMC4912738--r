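# svtcomplete

Predicts complete gene expression matrices from a sparse subset of measured
**checkpoint** values by low-rank matrix completion.

Expression matrices are strongly correlated across genes and samples —
genes act in concert — so a genes-by-samples matrix
`M (m × n)` is well approximated by a low-rank matrix, and its unmeasured
entries can be recovered from a random fraction of measured ones. This
matters to anyone producing or imputing expression data: microarray and
RNA-seq profiling is expensive per sample, classical imputation methods
degrade beyond ~15 % missing values, and this approach recovers matrices
accurately even with 50–90 % of entries unmeasured.

## Method

Rank minimisation subject to agreeing with the measured cells is NP-hard;
the solver minimises the tightest convex relaxation, the nuclear norm
`‖X‖* = Σᵢ σᵢ(X)`:

```
min ‖X‖*   s.t.  X_ij = M_ij  for (i,j) ∈ Ω
```

via singular value thresholding (SVT). With `P_Ω` the projection onto the
observed set `Ω` and `shrink(X, τ) = Σᵢ max(σᵢ − τ, 0) uᵢ vᵢᵀ`, iterate
from `Y⁰ = 0`:

```
Xᵏ = shrink(Yᵏ⁻¹, τ)
Yᵏ = Yᵏ⁻¹ + δ · P_Ω(M − Xᵏ)
```

with defaults `τ = 5√(mn)`, `δ = 1.2·mn/|Ω|`, stopping when the **omega
error** `‖P_Ω(Xᵏ − M)‖_F / ‖P_Ω(M)‖_F` reaches 1e-8 (or at 750
iterations). The omega error is the only error observable in practice and
is also a reliable indicator of full-matrix recovery quality. Recovery is
assessed by Frobenius and spectral relative errors `‖M − X‖/‖M‖`.

The package also provides the synthetic generators (Gaussian-factor
low-rank matrices, additive white-noise perturbations with a specified
noise-deviation ratio `σ_ε/σ_x`, two-class data with planted differential
genes), the noise-robustness and parameter-sweep studies, and a
differential-expression concordance evaluation (limma moderated t,
Benjamini–Hochberg) comparing recovered matrices against the originals.

## Worked example

```r
library(svtcomplete)

truth <- generate_low_rank(200, 100, rank = 5, seed = 1)    # ground truth
mask  <- sample_mask(200, 100, observability = 0.5, seed = 2)
fit   <- svt_complete(truth, mask)                          # 50% unmeasured
fit
#> SVT matrix completion: 200 x 100, O = 0.500
#>   322 iterations, converged (final omega error 9.98e-09), effective rank 5
error_report(truth, fitted(fit), mask)
#>   frobenius_relative spectral_relative omega_relative observability
#> 1       1.532859e-08      2.581087e-08              0           0.5
```

From half of the entries, the full 200 × 100 rank-5 matrix is recovered to
a relative error of ~1.5e-8: the solver converged (omega error below the
1e-8 tolerance) and the withheld entries are reproduced essentially to
solver precision. The effective rank 5 is discovered, not supplied, and the
omega error of the returned matrix is exactly 0 because the measured cells
are restored by default (`restore_observed = TRUE`).

A shell interface covering every stage (`simulate`, `mask`, `complete`,
`evaluate`, `noise-bench`, `sweep`, `obs-sweep`, `de-concordance`) is
installed at `system.file("cli", "svtc", package = "svtcomplete")`; every
run writes a provenance record of its parameters and seed.

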
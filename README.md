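# relaxinv

Reconstruction of **T1–T2 relaxation-time distributions** from
two-dimensional NMR relaxometry data (IR-CPMG: inversion recovery detected
by a CPMG echo train).

Recovering the joint distribution F(T1, T2) ≥ 0 from a measured decay
surface S(t1, t2) is a 2D inverse Laplace transform — a severely
ill-posed, large-scale problem. The discrete model is

    K f + e = s,    K = K2 ⊗ K1,
    K1[i,j] = 1 − 2·exp(−t1_i/T1_j)   (IR kernel),
    K2[i,j] = exp(−t2_i/T2_j)          (CPMG kernel),

with f = vec(F), s = vec(S). `relaxinv` implements a **hybrid
TSVD–Tikhonov** inversion:

    min_{f ≥ 0}  ‖Σk Vkᵀ f − Ukᵀ s‖² + α‖f‖²

where Uk Σk Vkᵀ is the **exact** rank-k truncated SVD of the Kronecker
operator, assembled from the two factor SVDs and a descending reordering of
all pairwise singular-value products — never materializing K. Truncation
removes the noise-amplifying spectral tail and compresses the data to k
coefficients; the ridge penalty α‖f‖² stabilizes the rest. The truncation
index is chosen from the discrete Picard condition (threshold τ on the
spectrum, or an automatic break detector), and α = σk² couples the penalty
to the truncation point. The constrained problem is solved by a **Newton
Projection** method with conjugate-gradient inner solves, with monotone
descent and KKT certification.

Also included: the full-space non-negative Tikhonov model (Kronecker
matvecs throughout), the Venkataramanan–Song–Hürlimann (VSH)
factor-truncation baseline with its discrepancy-matching α iteration,
spectral filter-factor diagnostics, a three-peak synthetic phantom with
exact-SNR noise, Picard plots, parameter sweeps, peak reports, and
delimited-text I/O (including a minimal STELAR-like ascii reader).

## Worked example

Simulate the benchmark instance (2048 × 128 surface, 100 × 100 grid, three
Gaussian peaks, 23 dB SNR), truncate at τ = 1, and invert:

```r
library(relaxinv)

sim <- t1t2_phantom(seed = 1)
op  <- kron_tsvd(sim$kern, tau = 1)
op
#> <kron_tsvd> rank 83 of 10000, sigma_1 = 7825, sigma_k = 1.09

fit <- solve_hybrid(op, sim$data)   # alpha = sigma_k^2 by default
fit
#> <solve_result> method hybrid, alpha = 1.189, k = 83
#>   28 NP iterations (4593 CG), converged, |Kf - s| = 989.8

relative_error(sim$truth, fit)
#> [1] 0.2649302

peak_report(fit$F, floor = 0.2)
#> # A tibble: 8 × 5
#>   T2_ms   T1_ms height    i1    i2
#>   <dbl>   <dbl>  <dbl> <int> <int>
#> 1 65.8   397.    0.809    75    61
#> 2  7.05    8.88  0.743    28    29
#> 3 13.2    78.8   0.601    55    38
#> ...
```

Reading the output: thresholding the composite spectrum at τ = 1 keeps
k = 83 of the 10⁴ singular values, and the coupled penalty is
α = σ₈₃² ≈ 1.19. The recovered map reproduces the three planted peaks —
(433, 59), (8.6, 6.7) and (82, 13) ms — at neighboring grid nodes (the
remaining rows are low-amplitude satellites below ~0.35), with a relative
Frobenius error of 0.26 against the ground truth. `glance(fit)` returns the
same diagnostics as a one-row tibble, `tidy(fit)` the map in long form, and
`autoplot(fit$F)` draws it.

Compare inversion models on one realization:

```r
run_sweep(sim$kern, sim$data, sim$truth,
          methods = c("hybrid", "tikhonov", "vsh"),
          alphas = 10^seq(2, -4, length.out = 10), tau = 1)
```

A thin command-line front end covering simulation, Picard plots, inversion,
sweeps and filter tables is installed at `inst/cli/relaxinv`.

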
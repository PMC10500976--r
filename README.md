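# dmapcv

Diffusion-map analysis of reaction dynamics in molecular-dynamics
trajectories: collective-variable (CV) discovery and assessment,
quasi-stationarity monitoring, and committor estimation, with synthetic
Langevin systems whose analytic answers serve as built-in oracles.

## Who this is for

Researchers in molecular simulation who have trajectory snapshots of a
reactive or conformational process — from ab-initio MD, force-field MD, or
model dynamics — and want data-driven answers to three questions:

1. **Which low-dimensional coordinates capture the slow dynamics?**
   Diffusion maps embed snapshots by the leading eigenvectors of a
   kernel-based approximation to the backward Kolmogorov generator
   `L = -∇U·∇ + β⁻¹Δ` of overdamped Langevin dynamics. Candidate CVs —
   internal coordinates (bonds/angles/dihedrals) and PCA coefficients —
   are ranked by `|ρ|`, their absolute Pearson correlation with the
   nontrivial diffusion coordinates DC2/DC3.
2. **Which part of a trajectory is usable for such a local analysis?**
   Samples must follow the quasi-stationary distribution of their
   metastable basin. The package rebuilds the diffusion map every *m*
   frames, tracks the first five generator eigenvalues, and truncates the
   trajectory where the leading eigenvalues shift — the signature of a
   basin exit.
3. **Where is the transition state, quantitatively?** On snapshots spanning
   reactant basin A and product basin B, the committor q(x) — the
   probability of reaching B before A — solves the discrete boundary-value
   problem `(Lq)_i = 0` (interior), `q|_A = 0`, `q|_B = 1` on the sampled
   graph; the `q = 0.5` isocommittor band marks the transition region, and
   a projected potential-energy surface around the transition state
   validates CV choices by the presence of a saddle.

Kernels: constant `exp(-d²/ε)`, α-normalized, locally scaled
`exp(-d²/(ε_i ε_j))` with k-nearest-neighbour scales, and energy-weighted
(`w_i = exp(-βU_i/2)`, a target-measure reweighting). Angular coordinates
use a wrapped metric throughout (the distance between angles π/6 and
2π − π/6 is π/3, never 2π − π/3).

## Worked example

A two-dimensional double well (slow coordinate `x`, stiff harmonic `y`) —
the package's parameter-recovery benchmark:

```r
library(dmapcv)

sys  <- two_well_2d()                       # U = 5(x²-1)² + 100 y², β = 3
traj <- simulate_langevin(sys, x0 = c(1, 0), n_steps = 1500, seed = 11)
kc   <- kernel_config("weighted", r = 0.1, weight_mode = "energy", beta = 3)

dm <- diffusion_map(traj, kc, n_modes = 4)
correlation_table(traj[, c("x", "y")], tidy(dm)[, c("frame", "DC2", "DC3")])
#> # A tibble: 2 × 6
#>   cv    abs_cor_DC2 abs_cor_DC3 best_dc best_abs_cor  rank
#>   <chr>       <dbl>       <dbl> <chr>          <dbl> <int>
#> 1 x          0.974        0.287 DC2            0.974     1
#> 2 y          0.0126       0.272 DC3            0.272     2
```

DC2 — the leading nontrivial diffusion coordinate — correlates with the
slow coordinate at `|ρ| = 0.97`, so `x` is (correctly) ranked the best CV,
while the stiff `y` carries no slow signal.

Committor analysis of the 1-D double well from 40 barrier-initiated
shooting runs (4000 frames):

```r
sys <- double_well_1d()
res <- run_committor_analysis(run_config(
  system = sys, n_runs = 40, n_steps = 100, seed = 1,
  kernel = kernel_config("weighted", r = 0.002, weight_mode = "energy", beta = 3)
))
res$committor$q[1]            # solved committor at the barrier-top frame
#> [1] 0.5705
committor_validation(res$committor, analytic_committor_1d(sys)(res$features$x))
#> # A tibble: 1 × 3
#>     rmse max_error n_interior
#>    <dbl>     <dbl>      <int>
#> 1 0.0342    0.0854       3633
```

The solved committor is 0.57 at the transition state for this realization
(exactly 0.5 is the symmetric-well truth; the single-node value carries
realization noise of about ±0.07, which is why the acceptance script
averages it over replicate ensembles) and tracks the closed-form quadrature
committor with an interior RMSE of 0.034.

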
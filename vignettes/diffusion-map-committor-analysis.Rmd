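---
title: "Diffusion maps, quasi-stationarity and committors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion maps, quasi-stationarity and committors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmapcv)
```

## The model

`dmapcv` analyses molecular-dynamics snapshots under the working assumption
that the sampled process is an overdamped Langevin diffusion

$$\mathrm{d}x_t = -\nabla U(x_t)\,\mathrm{d}t + \sqrt{2\beta^{-1}}\,\mathrm{d}W_t,$$

whose backward Kolmogorov generator is
$L = -\nabla U\cdot\nabla + \beta^{-1}\Delta$ with spectrum
$0 = \lambda_1 < |\lambda_2| \le |\lambda_3| \le \dots$ (eigenvalues are
non-positive). Everything the package computes — diffusion coordinates,
quasi-stationarity diagnostics, committor functions — is an eigenvector,
eigenvalue or boundary-value problem of a data-driven approximation of $L$.

The approximation is a diffusion map. From pairwise snapshot distances
$d(x_i, x_j)$ (wrapped for angular coordinates, see below) a Gaussian kernel
is formed, optionally reweighted, normalized to a row-stochastic matrix $P$,
and converted to the discrete generator $L_\varepsilon = (P - I)/\varepsilon_\mathrm{eff}$.

## Kernel families and their exponent convention

All kernels use the squared-distance convention
$K_{ij} = \exp(-d_{ij}^2/\varepsilon)$ (single scale) or
$K_{ij} = \exp\!\big(-d_{ij}^2/(\varepsilon_i\varepsilon_j)\big)$ (local
scales), with $\varepsilon_i$ the distance from $i$ to its
$\lceil r(n-1)\rceil$-th nearest neighbour. This convention is stated
prominently because every downstream constant depends on it.

Weights $w_i$ multiply the kernel symmetrically,
$\tilde K_{ij} = w_i K_{ij} w_j$; because the transition matrix row-normalizes,
a symmetric weighting and a right-only weighting produce the same $P$. Three
modes are supported: `one`, `inv_rowsum` ($w_i = 1/p_i$, equivalent to the
$\alpha = 1$ density normalization) and `energy`
($w_i = e^{-\beta U(x_i)/2}$, a target-measure reweighting that biases the
random walk toward the Boltzmann measure even when the sample itself is not
Boltzmann-distributed — exactly the situation for ensembles shot from a
transition state). Energies are centred at their sample minimum inside the
exponential; this rescaling cancels in the row normalization and only
prevents overflow.

The $\alpha$-normalization $K_{ij}/(p_i p_j)^\alpha$ defaults to
$\alpha = 1/2$, the exponent at which, for Boltzmann-distributed samples, the
row-normalized operator converges to the backward Kolmogorov generator; for
weighted modes the default is $\alpha = 0$ since the weights already fix the
target measure. Both are plain arguments of `kernel_config()`.

### The generator scale

With the convention above, a second-order expansion of the kernel integral
operator gives $(P - I) \to (\beta\varepsilon/4)\,L$ as
$n \to \infty,\ \varepsilon \to 0$. The package therefore uses
$\varepsilon_\mathrm{eff} = \beta\,\varepsilon_\mathrm{scale}/4$, where
$\varepsilon_\mathrm{scale}$ is the constant $\varepsilon$ or, for local
scales, the squared geometric mean of the $\varepsilon_i$. The factor was
validated against two independent oracles on an Ornstein-Uhlenbeck process
with stiffness $k$ (closed-form spectrum $\lambda_j = -(j-1)k$): the
diffusion-map generator recovers $\lambda_2 = -k$ within 20% at $n = 2000$
equilibrium samples, and a central-difference discretization of $L$ on a
400-point grid agrees with the closed form to 0.1%. Note that the committor
solve is invariant to this scale (row-rescaling a singular system does not
move its solution), so only spectral read-outs depend on it.

## Angular coordinates

Bond angles and dihedrals live on the circle; a naive Euclidean difference
of two dihedrals near $\pm\pi$ invents a separation of almost $2\pi$ where
the true separation is tiny, which distorts every kernel built from it. The
package fixes one convention repo-wide — radians in $(-\pi, \pi]$, IUPAC
dihedral signs — and reduces every angular difference to $[0, \pi]$
(`wrap_angle_difference()`) inside all distance computations. PCA cannot
wrap; instead each angular column is recentred about its circular mean
before the SVD, so a cluster straddling the boundary stays a cluster. This
is adequate for basin-confined samples (angular spread well below $\pi$) and
documented as unsuitable for freely rotating dihedrals.

## Quasi-stationarity monitoring

A trajectory confined to a metastable basin relaxes to its quasi-stationary
distribution, under which the leading spectrum of the estimated generator is
stationary in time. `monitor_qsd()` rebuilds the diffusion map every
$m = 100$ frames from all frames seen so far (evenly subsampled to
`max_frames = 800` once the prefix outgrows that, which keeps the 40
eigensolves of a 4000-frame monitoring run around ten seconds) and records
the first five generator eigenvalues, the count used throughout the
monitoring stage. The default monitoring kernel is the locally-scaled,
energy-weighted family with $r = 0.1$.

`detect_stabilization()` formalizes "the eigenvalues stop changing": flag
the first check at which a tracked eigenvalue departs from its trailing
3-check mean by more than `rel_tol = 0.3`, skipping the first
`burn_in = 5` checks, and applying the rule to the leading nontrivial pair
(`modes = 2:3`). These four numbers are calibrated choices, not derived
ones, and the calibration logic is worth recording: while the sample grows,
eigenvalue estimates drift systematically (20-30% against a trailing mean
early on, and the 4th/5th modes keep fluctuating at that level throughout,
sitting as they do at the resolution limit of a few hundred samples), so a
0.2 tolerance over all five modes flags healthy basin-confined runs. The
event actually being detected — samples leaking out of the basin — collapses
$\lambda_2$ by a factor 2-10, far above the 0.3 band. On double-well test
trajectories the resulting truncation lands within two checks of the first
basin exit, with no false alarms on confined runs.

## Committor estimation

For basins $A$ (reactant) and $B$ (product), membership is assigned by
wrapped feature distance to reference configurations within a cutoff, and
the committor solves the discrete boundary-value problem: generator rows on
the complement, $q = 0$ on $A$, $q = 1$ on $B$, dense direct solve with the
residual reported. Connectivity of the kernel graph is checked first and
disconnected components are reported by index, since an unreachable island
makes the system singular. For a connected graph the solution obeys the
discrete maximum principle, so interior values stay inside $(0, 1)$ without
clamping.

Global maps default to $r = 0.002$ with energy weights; with the 4000-frame
study design below that means 8-nearest-neighbour local scales, a very
sparse effective graph. One practical consequence is worth stating plainly:
the solved committor at one individual node carries noticeable
realization-to-realization noise (standard deviation around 0.07 at the
barrier top of the double well), while aggregate measures (interior RMSE
against the analytic committor) are much more stable. The package's
measurement protocol for "the committor at the transition state" therefore
averages the TS-frame value over independent replicate ensembles; the
reported uncertainty of a single realization is part of the result, not a
defect to hide.

## Synthetic study systems and their oracles

All tests run on systems whose answers are known:

* `double_well_1d()` — $U = h(x^2-1)^2$, defaults $h = 5$, $\beta = 3$:
  a 15 kT barrier, so basins are strongly metastable on the simulated
  horizon. The committor has a closed quadrature form
  (`analytic_committor_1d()`), computed with overflow-safe rescaling.
* `two_well_2d()` — the double well plus a harmonic $y$ with
  $\kappa = 200$: the in-basin $x$ curvature is $8h = 40$, five times
  softer than $y$, making $x$ the slow CV by construction for the
  CV-recovery checks.
* `ou_1d()` — the spectral oracle (closed-form generator spectrum).
* `toy_triatomic()` — three atoms with internal coordinates (bond,
  reactive bond, angle): harmonic-harmonic-double-well with an analytic
  saddle, mimicking the IC structure of a three-atom association reaction.
  Its dynamics are integrated in IC space and embedded to Cartesians by a
  Z-matrix construction for file-format fixtures; a general IC-to-Cartesian
  back-transformation is deliberately out of scope.

The simulator is plain Euler-Maruyama — it *is* the overdamped model, with
no integrator sophistication to second-guess — at `dt = 1e-3` in reduced
units. Independent oracles: a shooting (trajectory-hitting) committor
estimator sharing no code with the solver, a finite-difference generator,
and direct quadrature. Detailed balance of the simulator is itself tested
(long-run histogram against $e^{-\beta U}/Z$).

### The committor study design

A single 4000-step overdamped trajectory started at the 15 kT barrier top
falls into one basin and stays there, leaving the other basin empty, so the
committor data set is an *ensemble*: 40 barrier-initiated runs of 100 steps
(4000 frames in total). The first run starts exactly at the barrier top, so
the transition-state configuration is a sample member; later runs disperse
their start by a Gaussian of width 0.15, the scale of the thermal width
$1/\sqrt{\beta\,|U''(0)|} \approx 0.13$ at the barrier. This design was
fixed once by validating against the analytic committor (interior RMSE
$\approx 0.03$ averaged over independent seeds) and is the default shape of
`langevin_ensemble()` and the fixture bundles.

## What the synthetic tests do and do not show

The generators emulate the statistical structure the analysis assumes:
metastable Boltzmann sampling within a basin, barrier-initiated shooting
ensembles spanning two basins, per-frame energies, and (for the triatomic)
angular internal coordinates with file-format round-trips. They do not
emulate high-dimensional force fields, multiple reaction channels,
anharmonic cross-couplings, or sampling at several temperatures. Passing
tests therefore demonstrate that the estimators are consistent and
correctly implemented on processes that satisfy the model assumptions —
not that diffusion-map CVs are chemically adequate for any particular real
system, which remains a scientific judgement on real data.

## Numerical choices and degenerate inputs

* Eigen-solves run on the symmetric conjugate
  $D^{-1/2}\tilde K D^{-1/2}$; eigenvector signs are fixed so the
  largest-magnitude entry is positive.
* Duplicate snapshots floor the local scales at a machine-scaled epsilon
  with a warning; collinear angle/dihedral atoms either error (naming frame
  and coordinate) or, under an explicit policy, emit `NaN`.
* The constant-kernel default scale is `median(d^2)/10`, scale-invariant
  under unit changes. A known failure mode, visible on some seeds, is that
  an isolated tail sample adds a spurious near-zero generator mode with a
  localized eigenvector; locally-scaled kernels remove the artifact but
  time-change the spectrum, so they are not used for quantitative spectral
  read-outs.
* Dense matrices throughout, with an explicit cap (default 10000 frames);
  trajectory sizes in this package's scope never need sparse solvers.
* Free-energy panels use histogram Boltzmann inversion,
  $F = -\beta^{-1}\log\hat\rho$, minimum shifted to zero; the estimator is
  recorded in the output metadata since it is a rendering aid, not a
  calibrated estimator.
* The PES stationarity threshold scales with the surface:
  $\|g\| < 0.05 \times \mathrm{range}(E)/\mathrm{spacing}$, with Hessian
  eigenvalue signs deciding minimum / maximum / saddle.

## Known limitations

* The QSD rule is one defensible formalization of an eigenvalue-stability
  heuristic; its thresholds are calibrated on the synthetic systems above.
* PCA angle handling assumes basin-confined angular spread.
* Committor node values at very small $r$ are noisy (see protocol above).
* No sparse/approximate nearest-neighbour kernels and no out-of-sample
  extension; all operators are rebuilt from scratch per data set.

## A compact worked run

```{r example, eval = FALSE}
sys <- two_well_2d()
traj <- simulate_langevin(sys, x0 = c(1, 0), n_steps = 1500, seed = 11)
kc <- kernel_config("weighted", r = 0.1, weight_mode = "energy", beta = 3)
trace <- monitor_qsd(traj, m = 100, kernel = kc)
detect_stabilization(trace)
dm <- diffusion_map(traj, kc, n_modes = 4)
correlation_table(traj[, c("x", "y")], tidy(dm)[, c("frame", "DC2", "DC3")])
```
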
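# shared fixtures, built in code

# random rigid motion applied to a coordinate matrix
rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.2, 2.5)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  sweep(coords %*% t(R), 2, rnorm(3, 0, 2), "+")
}

# tiny hand-checkable 4-atom trajectory
toy_traj <- function() {
  f1 <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.2, 0), c(0, 1.2, 0.8))
  f2 <- f1 + 0.1
  trajectory_tbl(list(f1, f2), c("O", "H", "H", "O"), energies = c(-1, -2))
}

# barrier-initiated shooting ensemble of the symmetric double well,
# cached across test files (the committor checks reuse it)
.dw_cache <- new.env(parent = emptyenv())
dw_committor_run <- function(n_runs = 40, n_steps = 100, seed = 1,
                             cutoff = 0.2) {
  key <- paste(n_runs, n_steps, seed, cutoff, sep = "_")
  if (!is.null(.dw_cache[[key]])) return(.dw_cache[[key]])
  sys <- double_well_1d()
  feats <- langevin_ensemble(sys, n_runs = n_runs, n_steps = n_steps,
                             seed = seed)
  basins <- define_basins(feats, sys$references$reactant,
                          sys$references$product, cutoff = cutoff)
  dm <- diffusion_map(feats,
                      kernel_config("weighted", r = 0.002,
                                    weight_mode = "energy",
                                    beta = sys$beta),
                      n_modes = 0)
  sol <- solve_committor(dm, basins)
  out <- list(system = sys, features = feats, basins = basins,
              dmap = dm, solution = sol,
              analytic = analytic_committor_1d(sys)(feats$x))
  .dw_cache[[key]] <- out
  out
}
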
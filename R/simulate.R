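#' Simulate overdamped Langevin dynamics (Euler-Maruyama)
#'
#' Integrates `x_{t+1} = x_t - grad U(x_t) dt + sqrt(2 dt / beta) xi_t`
#' with standard-normal increments. The initial configuration is recorded
#' as the first frame, so the trajectory holds exactly `n_steps` frames.
#' Per-frame potential energies are stored in an `energy` column.
#'
#' @param system a `synthetic_system`.
#' @param x0 initial coordinate vector (defaults to the system's reactant
#'   reference, else its first reference).
#' @param n_steps number of frames to produce.
#' @param dt time step in reduced units (default 1e-3).
#' @param seed RNG seed (integer); every simulation is reproducible.
#' @param beta inverse temperature (defaults to the system's).
#' @param noise set `FALSE` for the deterministic gradient-descent limit.
#' @return a `feature_tbl`: columns `frame`, one per system coordinate,
#'   and `energy`; attribute `is_angular` from the system.
#' @examples
#' sys <- double_well_1d()
#' tr <- simulate_langevin(sys, n_steps = 50, seed = 1)
#' head(tr)
#' @export
simulate_langevin <- function(system, x0 = NULL, n_steps, dt = 1e-3,
                              seed = NULL, beta = NULL, noise = TRUE) {
  if (dt <= 0) abort("`dt` must be positive.")
  beta <- beta %||% system$beta
  x0 <- as.numeric(x0 %||% system$references$reactant %||% system$references[[1]])
  if (length(x0) != system$dim) abort("`x0` has the wrong dimension.")
  if (!is.null(seed)) set.seed(seed)
  d <- system$dim
  out <- matrix(NA_real_, n_steps, d)
  out[1, ] <- x0
  sq <- sqrt(2 * dt / beta)
  x <- x0
  for (i in seq_len(n_steps - 1L)) {
    g <- as.numeric(system$gradient(matrix(x, 1)))
    x <- x - g * dt + if (noise) sq * rnorm(d) else 0
    if (any(!is.finite(x))) {
      abort(paste0("Langevin integration blew up at step ", i + 1L,
                   "; reduce `dt`."))
    }
    out[i + 1L, ] <- x
  }
  colnames(out) <- system$coord_names
  tbl <- feature_tbl(out, is_angular = system$is_angular)
  tbl$energy <- as.numeric(system$potential(out))
  attr(tbl, "dt") <- dt
  attr(tbl, "beta") <- beta
  tbl
}

#' Ensemble of barrier-initiated shooting trajectories
#'
#' Concatenates `n_runs` independent Langevin runs started near a common
#' point (by default the system's barrier reference). The first run starts
#' exactly at the shooting centre — so the transition-state configuration
#' itself is a member of the sample, where the committor can be read off —
#' while later runs disperse their initial point by an isotropic Gaussian
#' of standard deviation `dispersion` (exact duplicates of the shooting
#' centre would degenerate the local kernel scales). This is the sampling
#' design used for global diffusion maps and committor estimation: short
#' unbiased runs from the transition-state region reach both product and
#' reactant basins across the ensemble.
#'
#' @inheritParams simulate_langevin
#' @param n_runs number of independent runs.
#' @param n_steps frames per run.
#' @param x0 shooting centre (default: barrier reference).
#' @param dispersion standard deviation of the initial-point jitter
#'   (default 0.15, the order of the thermal width `1/sqrt(beta |U''|)` at
#'   the default double-well barrier).
#' @param seed base seed; run `i` uses `seed + i`.
#' @return a `feature_tbl` with additional column `run`.
#' @export
langevin_ensemble <- function(system, n_runs, n_steps, x0 = NULL,
                              dispersion = 0.15, dt = 1e-3, seed = 1,
                              beta = NULL) {
  x0 <- as.numeric(x0 %||% system$references$barrier %||% system$references[[1]])
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(seed + i)
    xi <- if (i == 1L) x0 else x0 + rnorm(system$dim, 0, dispersion)
    tr <- simulate_langevin(system, xi, n_steps = n_steps, dt = dt,
                            seed = NULL, beta = beta)
    tr$run <- i
    runs[[i]] <- tr
  }
  out <- dplyr::bind_rows(runs)
  out$frame <- seq_len(nrow(out))
  new_feature_tbl(out, angular_mask(runs[[1]]))
}

#' Empirical committor by direct shooting
#'
#' For each query point, launches `n_shots` independent Langevin
#' trajectories and records the fraction that enters region B before
#' region A (the defining trajectory-based committor). Regions are balls
#' `|x - centre| <= radius`. All shots for one point are propagated
#' simultaneously (vectorized Euler-Maruyama). Shots exceeding `max_steps`
#' without hitting either region are counted separately.
#'
#' This estimator is deliberately independent of the diffusion-map /
#' committor solver code paths, so it can serve as an oracle.
#'
#' @param system a `synthetic_system`.
#' @param points numeric vector (1-D) or matrix of query points (rows).
#' @param n_shots trajectories per point.
#' @param a_region,b_region lists `list(center=, radius=)`.
#' @param dt time step.
#' @param seed RNG seed.
#' @param max_steps cap on steps per shot.
#' @param beta inverse temperature override.
#' @return tibble with columns `point` (row index), `q_hat`, `se`
#'   (binomial standard error), `n_a`, `n_b`, `n_timeout`.
#' @export
empirical_committor <- function(system, points, n_shots, a_region, b_region,
                                dt = 1e-3, seed = 1, max_steps = 20000,
                                beta = NULL) {
  if (n_shots < 1) abort("`n_shots` must be >= 1.")
  beta <- beta %||% system$beta
  pts <- if (is.matrix(points)) points else matrix(points, ncol = system$dim)
  ca <- matrix(as.numeric(a_region$center), 1)
  cb <- matrix(as.numeric(b_region$center), 1)
  dist_a <- feature_distance_matrix(ca, cb)[1, 1]
  if (dist_a <= a_region$radius + b_region$radius) {
    abort("regions A and B overlap.")
  }
  set.seed(seed)
  sq <- sqrt(2 * dt / beta)
  d <- system$dim
  res <- vector("list", nrow(pts))
  for (p in seq_len(nrow(pts))) {
    X <- matrix(pts[p, ], n_shots, d, byrow = TRUE)
    da0 <- sqrt(sum((pts[p, ] - ca)^2)); db0 <- sqrt(sum((pts[p, ] - cb)^2))
    state <- rep(if (da0 <= a_region$radius) 1L
                 else if (db0 <= b_region$radius) 2L else 0L, n_shots)
    for (s in seq_len(max_steps)) {
      run <- state == 0L
      if (!any(run)) break
      Xr <- X[run, , drop = FALSE]
      G <- system$gradient(Xr)
      Xr <- Xr - G * dt + matrix(rnorm(sum(run) * d, 0, sq), ncol = d)
      X[run, ] <- Xr
      da <- sqrt(rowSums((Xr - matrix(ca, nrow(Xr), d, byrow = TRUE))^2))
      db <- sqrt(rowSums((Xr - matrix(cb, nrow(Xr), d, byrow = TRUE))^2))
      hit <- ifelse(da <= a_region$radius, 1L,
                    ifelse(db <= b_region$radius, 2L, 0L))
      state[run] <- hit
    }
    n_a <- sum(state == 1L); n_b <- sum(state == 2L)
    n_done <- n_a + n_b
    q <- if (n_done > 0) n_b / n_done else NA_real_
    res[[p]] <- tibble::tibble(
      point = p, q_hat = q,
      se = if (n_done > 0) sqrt(max(q * (1 - q), 1 / n_done) / n_done) else NA_real_,
      n_a = n_a, n_b = n_b, n_timeout = n_shots - n_done
    )
  }
  dplyr::bind_rows(res)
}

#' Label frames by potential basin
#'
#' Direct geometric labelling used by tests and the quasi-stationarity
#' oracle: a frame belongs to a basin when it lies within `radius` of that
#' reference (wrapped feature distance).
#'
#' @param features feature tibble or matrix.
#' @param references named list of reference coordinate vectors.
#' @param radius ball radius.
#' @return character vector: reference name or `NA` when in none.
#' @export
label_basins <- function(features, references, radius = 0.3) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  ang <- if (is.matrix(features)) rep(FALSE, ncol(X)) else unname(angular_mask(features))
  lab <- rep(NA_character_, nrow(X))
  dmin <- rep(Inf, nrow(X))
  for (nm in names(references)) {
    ref <- matrix(as.numeric(references[[nm]]), 1)
    d <- feature_distance_matrix(X, ref, is_angular = ang)[, 1]
    upd <- d <= radius & d < dmin
    lab[upd] <- nm
    dmin[upd] <- d[upd]
  }
  lab
}

#' Write a reproducible synthetic fixture bundle
#'
#' Generates, for the toy triatomic system, (i) a basin-confined run for
#' local maps / quasi-stationarity checks, (ii) an ensemble of
#' barrier-initiated runs for global maps and committors, (iii) reactant /
#' product / transition-state reference structures, and (iv) the
#' internal-coordinate topology — all as plain text (extended-XYZ with
#' per-frame `energy=` comments, YAML topology, YAML manifest echoing
#' every generation parameter). Identical seeds give byte-identical
#' bundles.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param n_basin frames in the basin-confined run.
#' @param n_runs,n_steps ensemble shape for the barrier-initiated bundle.
#' @return invisible named list of the file paths written.
#' @export
make_fixture_set <- function(dir, seed = 1, n_basin = 400, n_runs = 20,
                             n_steps = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sys <- toy_triatomic()
  ics_to_traj <- function(tbl) {
    M <- feature_matrix(tbl[, c("r1", "r2", "theta")])
    trajectory_tbl(triatomic_to_cartesian(M), c("O", "O", "H"),
                   energies = tbl$energy)
  }
  basin <- simulate_langevin(sys, x0 = sys$references$product,
                             n_steps = n_basin, seed = seed)
  ens <- langevin_ensemble(sys, n_runs = n_runs, n_steps = n_steps,
                           seed = seed + 1000)
  paths <- list(
    basin = file.path(dir, "basin_run.xyz"),
    ensemble = file.path(dir, "barrier_ensemble.xyz"),
    reactant = file.path(dir, "reactant.xyz"),
    product = file.path(dir, "product.xyz"),
    ts = file.path(dir, "transition_state.xyz"),
    topology = file.path(dir, "topology.yaml"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_xyz(ics_to_traj(basin), paths$basin)
  write_xyz(ics_to_traj(ens), paths$ensemble)
  for (nm in c("reactant", "product", "barrier")) {
    ref <- sys$references[[nm]]
    tr <- trajectory_tbl(list(triatomic_to_cartesian(ref)), c("O", "O", "H"),
                         energies = as.numeric(sys$potential(matrix(ref, 1))))
    write_xyz(tr, paths[[if (nm == "barrier") "ts" else nm]])
  }
  # 0-based indices on disk, matching the reader's convention
  yaml::write_yaml(list(
    bonds = list(c(0L, 1L), c(0L, 2L)),
    angles = list(c(2L, 0L, 1L)),
    names = c("O1-O2", "O1-H", "H-O1-O2")
  ), paths$topology)
  yaml::write_yaml(list(
    system = "toy_triatomic", seed = seed, n_basin = n_basin,
    n_runs = n_runs, n_steps = n_steps, dt = 1e-3, beta = sys$beta,
    params = sys$params,
    note = "synthetic fixture bundle; all data generated by dmapcv"
  ), paths$manifest)
  invisible(paths)
}
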
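#' Configuration for an end-to-end analysis run
#'
#' Collects every parameter of the local (QSD -> diffusion map -> CV
#' ranking) and global (diffusion map -> committor -> surfaces) pipelines.
#' Validation happens here, before any compute; every run writes a
#' manifest echoing the fully resolved configuration so any artifact can
#' be reproduced from its manifest alone.
#'
#' @param system a `synthetic_system` (simulated input), or `NULL` when
#'   `features` are supplied directly.
#' @param features optional precomputed feature tibble (bypasses
#'   simulation).
#' @param n_steps,x0,dt simulation settings (local runs: one trajectory;
#'   committor runs: per-ensemble-member settings).
#' @param n_runs,dispersion ensemble shape for committor runs.
#' @param kernel a [kernel_config()].
#' @param qsd list of QSD parameters `m`, `n_track`, `rel_tol`, `window`,
#'   `max_frames`.
#' @param basin_cutoff basin radius for committor runs.
#' @param n_modes diffusion-map eigenpairs.
#' @param seed single global seed; each stage derives its own stream from
#'   it deterministically.
#' @param out_dir output directory (`NULL` disables file artifacts).
#' @return a validated `run_config` list.
#' @export
run_config <- function(system = NULL, features = NULL, n_steps = 4000,
                       x0 = NULL, dt = 1e-3, n_runs = 40, dispersion = 0.15,
                       kernel = kernel_config("weighted", r = 0.1,
                                              weight_mode = "energy"),
                       qsd = list(m = 100, n_track = 5, rel_tol = 0.3,
                                  window = 3, max_frames = 800),
                       basin_cutoff = 0.2, n_modes = 6, seed = 1,
                       out_dir = NULL) {
  if (is.null(system) && is.null(features)) {
    abort("supply a `system` to simulate or precomputed `features`.")
  }
  if (!is.null(system) && !inherits(system, "synthetic_system")) {
    abort("`system` must be a synthetic_system.")
  }
  if (!inherits(kernel, "kernel_config")) abort("`kernel` must be a kernel_config.")
  qsd_def <- list(m = 100, n_track = 5, rel_tol = 0.3, window = 3,
                  max_frames = 800)
  qsd <- utils::modifyList(qsd_def, qsd)
  if (basin_cutoff <= 0) abort("`basin_cutoff` must be positive.")
  structure(list(system = system, features = features, n_steps = n_steps,
                 x0 = x0, dt = dt, n_runs = n_runs, dispersion = dispersion,
                 kernel = kernel, qsd = qsd, basin_cutoff = basin_cutoff,
                 n_modes = n_modes, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  # deterministic per-stage stream from the single global seed
  config$seed * 131L + match(stage, c("simulate", "ensemble", "qsd",
                                      "dmap", "committor")) * 7919L
}

config_manifest <- function(config, extra = list()) {
  k <- config$kernel
  c(list(
    package = "dmapcv",
    version = as.character(utils::packageVersion("dmapcv")),
    system = if (is.null(config$system)) "user-features" else config$system$name,
    system_params = if (is.null(config$system)) NULL else config$system$params,
    beta = if (is.null(config$system)) NULL else config$system$beta,
    n_steps = config$n_steps, dt = config$dt,
    n_runs = config$n_runs, dispersion = config$dispersion,
    kernel = list(kind = k$kind, epsilon = k$epsilon, r = k$r,
                  alpha = k$alpha, beta = k$beta,
                  weight_mode = k$weight_mode),
    qsd = config$qsd, basin_cutoff = config$basin_cutoff,
    n_modes = config$n_modes, seed = config$seed
  ), extra)
}

write_artifacts <- function(out_dir, tables, manifest) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Run the local analysis: QSD truncation, diffusion map, CV ranking
#'
#' Simulates (or ingests) a basin-confined trajectory, monitors
#' quasi-stationarity and truncates the trajectory to its QSD-consistent
#' prefix, builds the final local diffusion map on the retained frames,
#' and ranks candidate CVs — the internal coordinates themselves and the
#' leading PCA coefficients — by correlation with DC2/DC3.
#'
#' Every defaulted parameter is logged via the returned manifest; rerunning
#' with the same config and seed reproduces identical artifacts.
#'
#' @param config a [run_config()].
#' @return list with `correlation_table`, `qsd_trace`, `truncation_index`,
#'   `dmap`, `pca`, `features`, `manifest`.
#' @export
run_local_analysis <- function(config) {
  feats <- config$features %||% simulate_langevin(
    config$system, x0 = config$x0 %||% config$system$references$reactant,
    n_steps = config$n_steps, dt = config$dt,
    seed = stage_seed(config, "simulate")
  )
  trace <- monitor_qsd(feats, m = config$qsd$m, n_track = config$qsd$n_track,
                       kernel = config$kernel,
                       max_frames = config$qsd$max_frames)
  trunc <- detect_stabilization(trace, rel_tol = config$qsd$rel_tol,
                                window = config$qsd$window)
  if (trunc < 100) abort("QSD truncation left fewer than 100 frames; aborting.")
  kept <- feats[feats$frame <= trunc, , drop = FALSE]
  kept <- new_feature_tbl(kept, angular_mask(feats))
  dm <- diffusion_map(kept, kernel = config$kernel,
                      n_modes = max(3L, config$n_modes))
  dcs <- tidy(dm)[, c("frame", "DC2", "DC3")]
  cv_cols <- setdiff(names(kept), c("frame", "energy", "run"))
  ic_feats <- new_feature_tbl(kept[, c("frame", cv_cols)],
                              angular_mask(feats)[cv_cols])
  pca <- pca_fit(ic_feats)
  n_pc <- min(3L, length(cv_cols))
  pcs <- pc_coefficients(ic_feats, pca)[, seq_len(n_pc) + 1L, drop = FALSE]
  cvs <- dplyr::bind_cols(ic_feats[, cv_cols, drop = FALSE], pcs)
  ct <- correlation_table(cvs, dcs)
  manifest <- config_manifest(config, list(
    stage = "local_analysis", truncation_index = trunc,
    n_frames_kept = nrow(kept)
  ))
  write_artifacts(config$out_dir, list(
    correlation_table = tibble::as_tibble(ct),
    qsd_trace = tibble::as_tibble(trace),
    diffusion_coordinates = dcs
  ), manifest)
  list(correlation_table = ct, qsd_trace = trace, truncation_index = trunc,
       dmap = dm, pca = pca, features = kept, manifest = manifest)
}

#' Run the global analysis: diffusion map, committor, surfaces
#'
#' Simulates (or ingests) an ensemble of barrier-initiated trajectories,
#' builds a global diffusion map (local scales, default `r = 0.002` is the
#' caller's choice via the kernel config), defines reactant/product basins
#' around the references, solves the committor boundary-value problem, and
#' derives the isocommittor band plus a free-energy surface of the first
#' two coordinates (and, for synthetic systems, the exact potential
#' surface around the barrier).
#'
#' @param config a [run_config()] whose system (or features) carries
#'   `reactant`/`product` references.
#' @param reactant_ref,product_ref reference feature vectors (defaults:
#'   the system's references).
#' @return list with `committor` (solution), `band`, `dmap`, `basins`,
#'   `features`, `free_energy`, `manifest`.
#' @export
run_committor_analysis <- function(config, reactant_ref = NULL,
                                   product_ref = NULL) {
  reactant_ref <- reactant_ref %||% config$system$references$reactant
  product_ref <- product_ref %||% config$system$references$product
  if (is.null(reactant_ref) || is.null(product_ref) ||
      !length(reactant_ref) || !length(product_ref)) {
    abort("reactant/product references are required for a committor run.")
  }
  feats <- config$features %||% langevin_ensemble(
    config$system, n_runs = config$n_runs, n_steps = config$n_steps,
    x0 = config$x0, dispersion = config$dispersion, dt = config$dt,
    seed = stage_seed(config, "ensemble")
  )
  basins <- define_basins(feats, reactant_ref, product_ref,
                          cutoff = config$basin_cutoff)
  dm <- diffusion_map(feats, kernel = config$kernel, n_modes = 0)
  sol <- solve_committor(dm, basins)
  if (identical(basins$A, basins$B)) abort("degenerate basins.")
  band <- isocommittor_band(sol, 0.5, tol = 0.05)
  cv_cols <- setdiff(names(feats), c("frame", "energy", "run"))
  fes <- NULL
  if (length(cv_cols) >= 1) {
    s1 <- feats[[cv_cols[1]]]
    s2 <- if (length(cv_cols) >= 2) feats[[cv_cols[2]]] else sol$q
    beta_fes <- (if (!is.null(config$system)) config$system$beta) %||%
      config$kernel$beta
    fes <- tryCatch(
      free_energy_surface(tibble::tibble(c1 = s1, c2 = s2), beta = beta_fes),
      error = function(e) NULL)
  }
  manifest <- config_manifest(config, list(
    stage = "committor_analysis",
    n_frames = nrow(feats),
    reactant_ref = as.numeric(reactant_ref),
    product_ref = as.numeric(product_ref),
    residual = sol$residual
  ))
  write_artifacts(config$out_dir, list(
    committor = tidy(sol),
    isocommittor_band = tibble::tibble(frame = band)
  ), manifest)
  list(committor = sol, band = band, dmap = dm, basins = basins,
       features = feats, free_energy = fes, manifest = manifest)
}
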
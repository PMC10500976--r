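#' Monitor quasi-stationarity by iterative diffusion-map spectra
#'
#' A trajectory confined to a metastable basin relaxes toward its
#' quasi-stationary distribution (QSD), whose signature is a stable
#' leading spectrum of the Kolmogorov generator estimated from the
#' samples. Every `m` frames a diffusion map is rebuilt from all frames
#' seen so far and its first `n_track` generator eigenvalues are recorded;
#' `floor(N / m)` checks are performed in total. When a check would use
#' more than `max_frames` frames, an evenly spaced subsample of that size
#' is used (the neighbourhood fraction `r` makes the local scales
#' subsample-consistent).
#'
#' The full distance matrix is computed once and sliced per check, which
#' is numerically identical to recomputing from scratch at every check.
#'
#' @param features feature tibble (an `energy` column is used for energy
#'   weights automatically).
#' @param m check interval in frames (default 100).
#' @param n_track eigenvalues tracked per check (default 5).
#' @param kernel a [kernel_config()]; default: weighted kernel with local
#'   scales `r = 0.1` and energy-derived weights.
#' @param energies optional explicit per-frame energies.
#' @param max_frames cap on frames entering one check (default 800).
#' @return object of class `qsd_trace`: a tibble with columns `check`,
#'   `frames_used`, `lambda_1` ... `lambda_<n_track>` (generator scale,
#'   ascending magnitude), plus attributes `m`, `n_frames`, `kernel`.
#' @export
monitor_qsd <- function(features, m = 100, n_track = 5,
                        kernel = kernel_config("weighted", r = 0.1,
                                               weight_mode = "energy"),
                        energies = NULL, max_frames = 800) {
  if (is.null(energies) && "energy" %in% names(features)) {
    energies <- features$energy
  }
  feats <- features[, setdiff(names(features), c("energy", "run")), drop = FALSE]
  X <- feature_matrix(feats)
  ang <- angular_mask(feats)
  N <- nrow(X)
  if (N < m) abort("too few frames for even one check (need >= m).")
  n_checks <- N %/% m
  D_full <- feature_distance_matrix(X, is_angular = unname(ang))
  rows <- vector("list", n_checks)
  for (j in seq_len(n_checks)) {
    upto <- j * m
    idx <- if (upto > max_frames) {
      unique(round(seq(1L, upto, length.out = max_frames)))
    } else {
      seq_len(upto)
    }
    dm <- diffusion_map(X[idx, , drop = FALSE],
                        kernel = kernel,
                        energies = if (!is.null(energies)) energies[idx],
                        n_modes = n_track,
                        distances = D_full[idx, idx, drop = FALSE])
    lam <- dm$generator_eigenvalues
    row <- tibble::tibble(check = j, frames_used = upto)
    for (k in seq_len(n_track)) row[[paste0("lambda_", k)]] <- lam[k]
    rows[[j]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "m") <- m
  attr(out, "n_frames") <- N
  attr(out, "kernel") <- kernel
  class(out) <- c("qsd_trace", class(out))
  out
}

#' Truncate a trajectory to its quasi-stationary prefix
#'
#' Scans the eigenvalue traces of a [monitor_qsd()] run and returns the
#' last frame index before the first check at which any tracked nontrivial
#' eigenvalue departs from its trailing-window mean by more than `rel_tol`
#' (relative). Returns `N` (all frames kept) when no check trips. The
#' trivial eigenvalue (identically ~0) is excluded from the rule since its
#' relative fluctuation is meaningless.
#'
#' Increasing `rel_tol` can only keep more frames (monotone robustness).
#'
#' The first `burn_in` checks are never flagged: while the sample is still
#' small, the estimated eigenvalues drift systematically as the basin gets
#' explored, and flagging that equilibration transient would truncate
#' every trajectory at its start. The default `rel_tol = 0.3` sits above
#' the trailing-mean excursions this growth drift produces in a stable
#' basin, while the collapse of an eigenvalue when a new metastable state
#' appears is far larger (typically 2x-10x).
#'
#' @param trace a `qsd_trace`.
#' @param rel_tol relative-change tolerance (default 0.3).
#' @param window trailing checks averaged as the reference level
#'   (default 3, must be >= 2).
#' @param burn_in checks exempt from flagging at the start (default 5).
#' @param modes which tracked eigenvalues enter the rule (default `2:3`,
#'   the leading nontrivial pair: basin exit collapses these by far the
#'   most, while the highest tracked modes sit at the resolution limit of
#'   the sample and fluctuate with trajectory growth alone).
#' @return integer truncation frame index.
#' @export
detect_stabilization <- function(trace, rel_tol = 0.3, window = 3,
                                 burn_in = 5, modes = 2:3) {
  if (window < 2) abort("`window` must be >= 2.")
  m <- attr(trace, "m")
  N <- attr(trace, "n_frames")
  lam_cols <- grep("^lambda_", names(trace), value = TRUE)
  lam <- as.matrix(trace[, lam_cols])
  scale_floor <- 1e-8 * max(abs(lam), 1e-300)
  nontrivial <- which(apply(abs(lam), 2, max) > scale_floor * 10)
  nt <- setdiff(nontrivial, 1L)
  if (length(nt)) nontrivial <- nt
  nontrivial <- intersect(nontrivial, intersect(modes, seq_len(ncol(lam))))
  if (length(nontrivial) == 0L) return(N)
  n_checks <- nrow(lam)
  first <- max(window + 1L, burn_in + 1L)
  if (n_checks < first) return(N)
  for (j in first:n_checks) {
    for (k in nontrivial) {
      ref <- mean(lam[(j - window):(j - 1L), k])
      rel <- abs(lam[j, k] - ref) / max(abs(ref), scale_floor)
      if (rel > rel_tol) return((j - 1L) * m)
    }
  }
  N
}

#' @rdname monitor_qsd
#' @param x a `qsd_trace`.
#' @param ... unused.
#' @method tidy qsd_trace
#' @export
tidy.qsd_trace <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::starts_with("lambda_"),
                      names_to = "mode", names_prefix = "lambda_",
                      values_to = "eigenvalue")
}

#' @rdname monitor_qsd
#' @param object a `qsd_trace`.
#' @method autoplot qsd_trace
#' @export
autoplot.qsd_trace <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$check, .data$eigenvalue,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = "Generator eigenvalues per QSD check",
                  x = "check", y = "eigenvalue", colour = "mode")
}
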
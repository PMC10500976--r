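#' Fit a diffusion map to a feature series
#'
#' Runs the full kernel pipeline — wrapped pairwise distances, kernel,
#' weights, alpha normalization, row-stochastic transition matrix `P`,
#' approximate Kolmogorov generator `L = (P - I)/eps_eff` — and extracts
#' the leading spectrum by solving the symmetric conjugate
#' `D^{1/2} P D^{-1/2}` (numerically stable, guarantees a real spectrum).
#' Eigenvector signs are fixed so the largest-magnitude entry is positive.
#'
#' Diffusion coordinates `DC_j` are the nontrivial right eigenvectors of
#' `P` scaled by `lambda_j^t`; `DC2`/`DC3` label the 2nd/3rd eigenvectors,
#' the first two nontrivial modes.
#'
#' @param features feature tibble ([feature_tbl()],
#'   [compute_internal_coordinates()]) or numeric matrix.
#' @param kernel a [kernel_config()].
#' @param energies per-frame energies (needed for energy weights); taken
#'   from a `energy` column of `features` when present.
#' @param n_modes number of eigenpairs to keep (including the trivial
#'   constant mode). `0` skips the eigensolve entirely (the committor only
#'   needs the generator).
#' @param t diffusion time used to scale the coordinates (default 1).
#' @param max_n hard cap on the number of frames (dense matrices; default
#'   10000).
#' @param distances optional precomputed (wrapped) distance matrix; when
#'   supplied, the pairwise distance stage is skipped.
#' @return object of class `diffusion_map`: list with the kernel matrix,
#'   `transition_matrix`, `generator`, `local_scales`, `epsilon_effective`,
#'   `eigenvalues` (of `P`, descending), `generator_eigenvalues`,
#'   `eigenvectors`, and `dcs` (tibble `frame`, `DC2`, ...).
#' @examples
#' set.seed(1)
#' X <- feature_tbl(cbind(x = rnorm(80)))
#' dm <- diffusion_map(X, kernel_config("constant"), n_modes = 4)
#' glance(dm)
#' @export
diffusion_map <- function(features, kernel = kernel_config(),
                          energies = NULL, n_modes = 10, t = 1,
                          max_n = 10000, distances = NULL) {
  if (is.null(energies) && !is.matrix(features) && "energy" %in% names(features)) {
    energies <- features$energy
    features <- features[, setdiff(names(features), "energy"), drop = FALSE]
  }
  X <- if (is.matrix(features)) features else feature_matrix(features)
  n <- nrow(X)
  if (n > max_n) {
    abort(paste0("n = ", n, " exceeds the dense-matrix cap (", max_n,
                 "); subsample the trajectory."))
  }
  D <- distances %||% feature_distance_matrix(features)
  K <- build_kernel(features, kernel, energies = energies, distances = D)
  A <- alpha_normalize(K, kernel$alpha)
  P <- transition_matrix(A)
  eps_scale <- attr(K, "epsilon_scale")
  eps_eff <- kernel$beta * eps_scale / 4
  L <- generator_matrix(P, eps_eff)
  model <- structure(list(
    kernel_config = kernel,
    kernel = K,
    transition_matrix = P,
    generator = L,
    local_scales = attr(K, "local_scales"),
    weights = attr(K, "weights"),
    epsilon_scale = eps_scale,
    epsilon_effective = eps_eff,
    n = n,
    t = t,
    frame = if (is.matrix(features)) seq_len(n) else features$frame
  ), class = "diffusion_map")
  if (n_modes > 0) model <- spectral_decompose(model, n_modes, t = t)
  model
}

#' Leading eigenpairs of a diffusion map
#'
#' Solves the symmetric conjugate of the transition matrix and stores the
#' top `n_modes` eigenpairs in the model: eigenvalues of `P` sorted
#' descending (equivalently generator eigenvalues sorted by ascending
#' magnitude), unit-norm right eigenvectors of `P` with deterministic
#' signs, and the diffusion coordinates.
#'
#' @param model a `diffusion_map`.
#' @param n_modes eigenpair count (must not exceed `n`).
#' @param t diffusion time for the coordinate scaling.
#' @return the model, with spectral fields filled.
#' @export
spectral_decompose <- function(model, n_modes, t = model$t %||% 1) {
  n <- model$n
  if (n_modes > n) abort("`n_modes` exceeds the number of snapshots.")
  P <- model$transition_matrix
  d <- attr(P, "row_sums")
  A <- P * d # back to the symmetric kernel
  S <- A / sqrt(outer(d, d))
  es <- eigen(S, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  vals <- es$values[ord][seq_len(n_modes)]
  # right eigenvectors of P from the symmetric conjugate
  vecs <- es$vectors[, ord[seq_len(n_modes)], drop = FALSE] / sqrt(d)
  vecs <- apply(vecs, 2, function(v) v / sqrt(sum(v^2)))
  vecs <- apply(vecs, 2, function(v) if (v[which.max(abs(v))] < 0) -v else v)
  model$eigenvalues <- vals
  model$generator_eigenvalues <- (vals - 1) / model$epsilon_effective
  model$eigenvectors <- vecs
  model$dcs <- diffusion_coordinates(model, t = t,
                                     k = max(1L, n_modes - 1L))
  model
}

#' Diffusion coordinates of every snapshot
#'
#' `DC_j(x_i) = lambda_j^t * psi_j(x_i)` for the nontrivial eigenpairs
#' (the constant mode is excluded); columns are labelled `DC2`, `DC3`, ...
#' matching their eigenvector index.
#'
#' @param model a `diffusion_map` with spectrum.
#' @param t diffusion time.
#' @param k number of nontrivial components to keep.
#' @return tibble with columns `frame`, `DC2`, ..., `DC(k+1)`.
#' @export
diffusion_coordinates <- function(model, t = 1, k = NULL) {
  if (is.null(model$eigenvalues)) abort("model has no spectrum; run spectral_decompose().")
  avail <- length(model$eigenvalues) - 1L
  k <- k %||% avail
  if (k < 1 || k > avail) {
    abort(paste0("`k` must lie in [1, ", avail, "] (nontrivial modes available)."))
  }
  idx <- 2L:(k + 1L)
  dc <- sweep(model$eigenvectors[, idx, drop = FALSE], 2,
              model$eigenvalues[idx]^t, "*")
  colnames(dc) <- paste0("DC", idx)
  dplyr::bind_cols(tibble::tibble(frame = model$frame),
                   tibble::as_tibble(as.data.frame(dc)))
}

#' Diffusion distance between two snapshots
#'
#' The L2 norm of the difference of their diffusion-coordinate vectors,
#' which approximates dynamical proximity under the sampled process.
#'
#' @param dc_x,dc_y numeric DC vectors of equal length.
#' @return non-negative scalar.
#' @export
diffusion_distance <- function(dc_x, dc_y) {
  dc_x <- as.numeric(dc_x); dc_y <- as.numeric(dc_y)
  if (length(dc_x) != length(dc_y)) abort("DC vectors differ in length.")
  sqrt(sum((dc_x - dc_y)^2))
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat("<diffusion_map> n=", x$n, " kernel=", x$kernel_config$kind, sep = "")
  if (!is.null(x$eigenvalues)) {
    cat("\n  P eigenvalues: ",
        paste(sprintf("%.4f", head(x$eigenvalues, 5)), collapse = " "),
        if (length(x$eigenvalues) > 5) " ..." else "", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname diffusion_map
#' @param x a `diffusion_map`.
#' @param ... unused.
#' @method tidy diffusion_map
#' @export
tidy.diffusion_map <- function(x, ...) {
  if (is.null(x$dcs)) abort("model has no spectrum; run spectral_decompose().")
  x$dcs
}

#' @rdname diffusion_map
#' @method glance diffusion_map
#' @export
glance.diffusion_map <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    kernel = x$kernel_config$kind,
    alpha = x$kernel_config$alpha,
    epsilon_scale = x$epsilon_scale,
    epsilon_effective = x$epsilon_effective,
    lambda_2 = if (is.null(x$eigenvalues)) NA_real_ else x$eigenvalues[2],
    gen_lambda_2 = if (is.null(x$generator_eigenvalues)) NA_real_
                   else x$generator_eigenvalues[2],
    spectral_gap = if (is.null(x$eigenvalues) || length(x$eigenvalues) < 3)
      NA_real_ else x$eigenvalues[2] - x$eigenvalues[3]
  )
}

#' @rdname diffusion_map
#' @param object a `diffusion_map`.
#' @method autoplot diffusion_map
#' @export
autoplot.diffusion_map <- function(object, ...) {
  dcs <- tidy(object)
  if (ncol(dcs) >= 3) {
    ggplot2::ggplot(dcs, ggplot2::aes(.data$DC2, .data$DC3,
                                      colour = .data$frame)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(title = "Diffusion coordinates", colour = "frame")
  } else {
    ggplot2::ggplot(dcs, ggplot2::aes(.data$frame, .data$DC2)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(title = "Diffusion coordinate DC2")
  }
}

#' Serialize a diffusion map to a CSV archive
#'
#' Writes `eigenvalues.csv` (index, eigenvalue of P, generator eigenvalue),
#' `eigenvectors.csv`, `diffusion_coordinates.csv` and `local_scales.csv`
#' into a directory, so an embedding can be inspected or reused without R.
#'
#' @param model a `diffusion_map` with spectrum.
#' @param dir output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
write_diffusion_map <- function(model, dir) {
  if (is.null(model$eigenvalues)) abort("model has no spectrum; run spectral_decompose().")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("eigenvalues.csv", "eigenvectors.csv",
                            "diffusion_coordinates.csv", "local_scales.csv"))
  utils::write.csv(data.frame(index = seq_along(model$eigenvalues),
                              lambda_P = model$eigenvalues,
                              lambda_generator = model$generator_eigenvalues),
                   paths[1], row.names = FALSE)
  ev <- as.data.frame(model$eigenvectors)
  names(ev) <- paste0("psi_", seq_along(ev))
  utils::write.csv(cbind(frame = model$frame, ev), paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(model$dcs), paths[3], row.names = FALSE)
  utils::write.csv(data.frame(frame = model$frame,
                              local_scale = model$local_scales),
                   paths[4], row.names = FALSE)
  invisible(paths)
}
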
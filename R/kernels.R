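#' Diffusion-map kernel configuration
#'
#' Bundles every knob of the kernel stage. The kernel families are
#' \describe{
#'   \item{`constant`}{`K_ij = exp(-d_ij^2 / epsilon)` with a single global
#'     scale `epsilon`.}
#'   \item{`alpha_normalized`}{the constant kernel followed by the
#'     density-correcting normalization `K_ij / (p_i p_j)^alpha` with `p`
#'     the kernel row sums.}
#'   \item{`energy_based`}{the constant kernel with Boltzmann weights
#'     `w_i = exp(-beta U_i / 2)` applied symmetrically, so low-energy
#'     configurations carry more weight (a target-measure reweighting).}
#'   \item{`locally_scaled`}{`K_ij = exp(-d_ij^2 / (eps_i eps_j))` with
#'     per-point scales `eps_i` set to the distance to the
#'     `ceiling(r (n-1))`-th nearest neighbour.}
#'   \item{`weighted`}{the locally scaled kernel combined with a weight mode
#'     (`"one"`, `"inv_rowsum"` = 1/row-sum, or `"energy"`); the general
#'     family of which all the others are special cases.}
#' }
#' After weighting, the alpha normalization is applied (default
#' `alpha = 1/2`, the choice under which the row-normalized operator tends
#' to the backward Kolmogorov generator for Boltzmann-distributed samples;
#' weighted modes default to `alpha = 0` because their weights already fix
#' the target measure).
#'
#' @param kind kernel family (see Details).
#' @param epsilon global squared-distance scale; `NULL` (default) selects
#'   `median(d^2)/10` at build time.
#' @param r neighbourhood fraction in (0, 1) for local scales (default 0.1;
#'   global/committor maps typically use 0.002).
#' @param alpha normalization exponent in `[0, 1]`; `NULL` picks the
#'   family default described above.
#' @param beta inverse temperature multiplying energies in the weights.
#' @param weight_mode `"one"`, `"inv_rowsum"` or `"energy"`.
#' @return object of class `kernel_config`.
#' @export
kernel_config <- function(kind = c("locally_scaled", "constant",
                                   "alpha_normalized", "energy_based",
                                   "weighted"),
                          epsilon = NULL, r = 0.1, alpha = NULL, beta = 1,
                          weight_mode = c("one", "inv_rowsum", "energy")) {
  kind <- match.arg(kind)
  weight_mode <- match.arg(weight_mode)
  if (kind == "energy_based") weight_mode <- "energy"
  if (kind %in% c("constant", "alpha_normalized", "energy_based")) {
    if (!is.null(epsilon) && epsilon <= 0) abort("`epsilon` must be positive.")
  } else {
    if (!(r > 0 && r < 1)) abort("`r` must lie in (0, 1).")
  }
  weighted <- weight_mode != "one"
  if (is.null(alpha)) alpha <- if (weighted) 0 else 0.5
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  if (beta <= 0) abort("`beta` must be positive.")
  structure(list(kind = kind, epsilon = epsilon, r = r, alpha = alpha,
                 beta = beta, weight_mode = weight_mode),
            class = "kernel_config")
}

#' @export
print.kernel_config <- function(x, ...) {
  cat("<kernel_config> kind=", x$kind,
      if (x$kind %in% c("locally_scaled", "weighted")) paste0(" r=", x$r)
      else paste0(" epsilon=", x$epsilon %||% "auto"),
      " alpha=", x$alpha, " beta=", x$beta,
      " weights=", x$weight_mode, "\n", sep = "")
  invisible(x)
}

#' Per-point local kernel scales from nearest-neighbour distances
#'
#' `eps_i` is the distance from point `i` to its `k`-th nearest neighbour
#' with `k = max(1, ceiling(r * (n - 1)))`. Scales of duplicate points
#' (zero neighbour distance) are floored at a machine-scaled epsilon with a
#' warning.
#'
#' @param distances symmetric `n x n` distance matrix with zero diagonal.
#' @param r neighbourhood fraction in (0, 1).
#' @return positive numeric vector of length `n`.
#' @export
local_scales <- function(distances, r) {
  n <- nrow(distances)
  if (n < 2L) abort("need at least two points for local scales.")
  if (!(r > 0 && r < 1)) abort("`r` must lie in (0, 1).")
  k <- max(1L, as.integer(ceiling(r * (n - 1))))
  eps <- apply(distances, 1L, function(row) sort(row)[k + 1L])
  floor_val <- sqrt(.Machine$double.eps) * max(distances)
  if (any(eps <= floor_val)) {
    if (max(distances) == 0) floor_val <- sqrt(.Machine$double.eps)
    warn("duplicate or near-duplicate points: local scales floored.")
    eps <- pmax(eps, floor_val)
  }
  eps
}

#' Build a diffusion-map kernel matrix
#'
#' Evaluates the configured kernel on the pairwise (wrapped) feature
#' distances and applies the configured weights. The returned matrix is
#' symmetric, non-negative, and carries attributes `local_scales`,
#' `weights` and `epsilon_scale` (the squared-distance scale used for the
#' generator later on).
#'
#' @param features feature tibble (or numeric matrix).
#' @param config a [kernel_config()].
#' @param energies per-frame potential energies; required by energy weights.
#' @param distances optional precomputed distance matrix (skips the feature
#'   distance computation).
#' @return kernel matrix with attributes (see Details).
#' @export
build_kernel <- function(features, config = kernel_config(),
                         energies = NULL, distances = NULL) {
  D <- distances %||% feature_distance_matrix(features)
  if (any(!is.finite(D))) abort("non-finite feature distances.")
  n <- nrow(D)
  local <- config$kind %in% c("locally_scaled", "weighted")
  if (local) {
    eps_i <- local_scales(D, config$r)
    K0 <- exp(-D^2 / outer(eps_i, eps_i))
    eps_scale <- exp(mean(log(eps_i)))^2
  } else {
    eps <- config$epsilon %||% (median(D[upper.tri(D)])^2 / 10)
    if (eps <= 0) abort("`epsilon` must be positive.")
    eps_i <- rep(sqrt(eps), n)
    K0 <- exp(-D^2 / eps)
    eps_scale <- eps
  }
  w <- switch(config$weight_mode,
    one = rep(1, n),
    inv_rowsum = 1 / rowSums(K0),
    energy = {
      if (is.null(energies)) {
        abort("energy weights requested but `energies` is missing.")
      }
      if (length(energies) != n) abort("`energies` must have one value per frame.")
      exp(-config$beta * (energies - min(energies)) / 2)
    })
  K <- K0 * outer(w, w)
  attr(K, "local_scales") <- eps_i
  attr(K, "weights") <- w
  attr(K, "epsilon_scale") <- eps_scale
  K
}

#' Density-correcting alpha normalization of a kernel
#'
#' `A_ij = K_ij / (p_i^alpha p_j^alpha)` with `p` the row sums of `K`.
#' `alpha = 0` leaves the kernel unchanged; `alpha = 1` removes the
#' sampling density to leading order.
#'
#' @param K symmetric non-negative kernel matrix with positive row sums.
#' @param alpha exponent in `[0, 1]`.
#' @return normalized kernel (attributes of `K` preserved).
#' @export
alpha_normalize <- function(K, alpha) {
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
  if (alpha == 0) return(K)
  p <- rowSums(K)
  if (any(p <= 0)) abort("kernel has a zero row sum.")
  A <- K / outer(p^alpha, p^alpha)
  for (a in c("local_scales", "weights", "epsilon_scale")) {
    attr(A, a) <- attr(K, a)
  }
  A
}

#' Row-stochastic transition matrix from a normalized kernel
#'
#' Divides each row by its sum. Because the input is symmetric, the result
#' is similar to a symmetric matrix and therefore has a real spectrum in
#' `[-1, 1]` with leading eigenvalue 1 and constant eigenvector.
#'
#' @param A symmetric non-negative matrix with positive row sums.
#' @return row-stochastic matrix `P` with attribute `row_sums`.
#' @export
transition_matrix <- function(A) {
  d <- rowSums(A)
  if (any(d <= 0)) abort("kernel has a zero row sum.")
  P <- A / d
  attr(P, "row_sums") <- d
  for (a in c("local_scales", "weights", "epsilon_scale")) {
    attr(P, a) <- attr(A, a)
  }
  P
}

#' Approximate Kolmogorov generator from a transition matrix
#'
#' `L = (P - I) / epsilon_effective`. Rows sum to zero, so the
#' smallest-magnitude eigenvalue is exactly 0 with constant eigenvector.
#' With the kernel convention `exp(-d^2/eps)` the generator limit carries a
#' factor `beta * eps / 4`, which is what [diffusion_map()] passes here so
#' that the nontrivial eigenvalues sit on the physical scale of the
#' backward Kolmogorov operator.
#'
#' @param P row-stochastic matrix.
#' @param epsilon_effective positive time scale of the quotient.
#' @return generator matrix.
#' @export
generator_matrix <- function(P, epsilon_effective) {
  if (epsilon_effective <= 0) abort("`epsilon_effective` must be positive.")
  L <- P
  diag(L) <- diag(L) - 1
  L / epsilon_effective
}
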
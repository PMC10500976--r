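#' Lay out a 2-D grid of configurations around an anchor
#'
#' Builds configurations `z(c1, c2) = z_ts + c1 u1 + c2 u2` on a uniform
#' rectangular grid, anchored at a transition-state (or any) configuration
#' `z_ts`. For internal-coordinate CVs the directions are standard basis
#' vectors; for PCA-based CVs they are principal-component columns.
#'
#' @param z_ts anchor configuration (numeric vector in feature space).
#' @param u1,u2 direction vectors (same length as `z_ts`, linearly
#'   independent).
#' @param c1_bounds,c2_bounds length-2 numeric bounds for the two CVs.
#' @param n1,n2 grid counts per axis.
#' @return tibble with columns `i1`, `i2`, `c1`, `c2` and a `config`
#'   list-column; attributes `z_ts`, `u1`, `u2`, `n1`, `n2`.
#' @export
project_grid <- function(z_ts, u1, u2, c1_bounds, c2_bounds,
                         n1 = 25, n2 = 25) {
  z_ts <- as.numeric(z_ts); u1 <- as.numeric(u1); u2 <- as.numeric(u2)
  if (length(u1) != length(z_ts) || length(u2) != length(z_ts)) {
    abort("direction vectors must match the anchor's dimension.")
  }
  M <- cbind(u1, u2)
  if (qr(M)$rank < 2) abort("direction vectors are linearly dependent.")
  c1 <- seq(c1_bounds[1], c1_bounds[2], length.out = n1)
  c2 <- seq(c2_bounds[1], c2_bounds[2], length.out = n2)
  g <- tidyr::expand_grid(i1 = seq_len(n1), i2 = seq_len(n2))
  g$c1 <- c1[g$i1]
  g$c2 <- c2[g$i2]
  g$config <- purrr::map2(g$c1, g$c2, function(a, b) z_ts + a * u1 + b * u2)
  attr(g, "z_ts") <- z_ts
  attr(g, "u1") <- u1
  attr(g, "u2") <- u2
  attr(g, "n1") <- n1
  attr(g, "n2") <- n2
  g
}

#' Evaluate an energy function on a configuration grid
#'
#' Fills the grid with `E(c1, c2)`; node failures (errors or non-finite
#' returns) are recorded as `NaN` and reported, and the whole evaluation
#' errors only when every node fails.
#'
#' @param grid a [project_grid()] result.
#' @param energy_fn function mapping a configuration vector to an energy
#'   (e.g. a synthetic system's `potential`).
#' @return tibble of class `grid_surface`: grid columns plus `E`.
#' @export
evaluate_surface <- function(grid, energy_fn) {
  E <- purrr::map_dbl(grid$config, function(z) {
    v <- tryCatch(as.numeric(energy_fn(matrix(z, 1))), error = function(e) NaN)
    if (length(v) != 1L || !is.finite(v)) NaN else v
  })
  if (all(is.nan(E))) abort("energy evaluation failed on every grid node.")
  if (any(is.nan(E))) {
    inform(paste0(sum(is.nan(E)), " grid node(s) failed energy evaluation (NaN)."))
  }
  out <- grid
  out$E <- E
  class(out) <- c("grid_surface", class(out))
  out
}

surface_matrix <- function(surface) {
  n1 <- attr(surface, "n1"); n2 <- attr(surface, "n2")
  M <- matrix(NA_real_, n1, n2)
  M[cbind(surface$i1, surface$i2)] <- surface$E
  M
}

#' Classify a grid node as minimum, maximum, saddle or nonstationary
#'
#' Central-difference gradient and Hessian on the energy grid. The node is
#' stationary when the gradient norm falls below
#' `grad_tol_factor * energy_range / spacing` (a threshold scaled to the
#' surface, since "zero" gradient is meaningless in absolute units), and
#' is then classified by the signs of the 2x2 Hessian eigenvalues.
#'
#' @param surface a `grid_surface`.
#' @param node length-2 integer `(i1, i2)` grid indices, interior to the
#'   grid.
#' @param grad_tol_factor scale factor of the stationarity threshold
#'   (default 0.05).
#' @return one of `"minimum"`, `"maximum"`, `"saddle"`, `"nonstationary"`,
#'   with attributes `gradient` and `hessian_eigenvalues`.
#' @export
classify_stationary_point <- function(surface, node, grad_tol_factor = 0.05) {
  n1 <- attr(surface, "n1"); n2 <- attr(surface, "n2")
  i <- node[1]; j <- node[2]
  if (i <= 1 || i >= n1 || j <= 1 || j >= n2) {
    abort("node must be interior to the grid.")
  }
  M <- surface_matrix(surface)
  h1 <- diff(sort(unique(surface$c1)))[1]
  h2 <- diff(sort(unique(surface$c2)))[1]
  g <- c((M[i + 1, j] - M[i - 1, j]) / (2 * h1),
         (M[i, j + 1] - M[i, j - 1]) / (2 * h2))
  H <- matrix(c(
    (M[i + 1, j] - 2 * M[i, j] + M[i - 1, j]) / h1^2,
    (M[i + 1, j + 1] - M[i + 1, j - 1] - M[i - 1, j + 1] + M[i - 1, j - 1]) /
      (4 * h1 * h2),
    (M[i + 1, j + 1] - M[i + 1, j - 1] - M[i - 1, j + 1] + M[i - 1, j - 1]) /
      (4 * h1 * h2),
    (M[i, j + 1] - 2 * M[i, j] + M[i, j - 1]) / h2^2
  ), 2, 2)
  rng <- diff(range(M, na.rm = TRUE))
  tol <- grad_tol_factor * rng / min(h1, h2)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  curv_tol <- 1e-8 * max(abs(ev), rng / min(h1, h2)^2, 1e-300)
  cls <- if (sqrt(sum(g^2)) > tol) {
    "nonstationary"
  } else if (all(ev > curv_tol)) {
    "minimum"
  } else if (all(ev < -curv_tol)) {
    "maximum"
  } else if (any(ev > curv_tol) && any(ev < -curv_tol)) {
    "saddle"
  } else {
    "nonstationary"
  }
  structure(cls, gradient = g, hessian_eigenvalues = ev)
}

#' 2-D free-energy surface by histogram inversion
#'
#' Bins per-frame CV samples on a regular 2-D grid and applies Boltzmann
#' inversion, `F = -log(density) / beta`, shifting the minimum to zero.
#' Empty bins are undefined (`NA`). This histogram estimator is a simple
#' stand-in for rendering free-energy panels; the output records it as
#' `estimator = "histogram_inversion"` in an attribute.
#'
#' @param samples data frame with CV columns `c1` and `c2` (or first two
#'   numeric columns).
#' @param beta inverse temperature (> 0).
#' @param bins bins per axis (default 30).
#' @return tibble `c1`, `c2`, `count`, `F` (class `free_energy_surface`).
#' @export
free_energy_surface <- function(samples, beta, bins = 30) {
  if (beta <= 0) abort("`beta` must be positive.")
  cols <- intersect(c("c1", "c2"), names(samples))
  if (length(cols) < 2) {
    num <- names(samples)[vapply(samples, is.numeric, logical(1))]
    num <- setdiff(num, c("frame", "run", "energy"))
    if (length(num) < 2) abort("need two CV columns.")
    cols <- num[1:2]
  }
  x <- samples[[cols[1]]]; y <- samples[[cols[2]]]
  if (length(x) < 1) abort("need at least one sample.")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    abort("degenerate sample cloud: zero spread in a CV.")
  }
  bx <- seq(min(x), max(x), length.out = bins + 1)
  by <- seq(min(y), max(y), length.out = bins + 1)
  ix <- pmin(findInterval(x, bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(y, by, rightmost.closed = TRUE), bins)
  cnt <- matrix(0L, bins, bins)
  for (k in seq_along(ix)) cnt[ix[k], iy[k]] <- cnt[ix[k], iy[k]] + 1L
  dens <- cnt / (length(x) * diff(bx)[1] * diff(by)[1])
  FF <- -log(dens) / beta
  FF[!is.finite(FF)] <- NA_real_
  FF <- FF - min(FF, na.rm = TRUE)
  mid <- function(b) (head(b, -1) + tail(b, -1)) / 2
  out <- tidyr::expand_grid(i1 = seq_len(bins), i2 = seq_len(bins))
  out$c1 <- mid(bx)[out$i1]
  out$c2 <- mid(by)[out$i2]
  out$count <- cnt[cbind(out$i1, out$i2)]
  out$F <- FF[cbind(out$i1, out$i2)]
  attr(out, "beta") <- beta
  attr(out, "estimator") <- "histogram_inversion"
  class(out) <- c("free_energy_surface", class(out))
  out
}

#' @rdname evaluate_surface
#' @param object a `grid_surface`.
#' @param ... unused.
#' @method autoplot grid_surface
#' @export
autoplot.grid_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$c1, .data$c2, fill = .data$E)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "Potential energy surface", fill = "E")
}

#' @rdname free_energy_surface
#' @param object a `free_energy_surface`.
#' @param ... unused.
#' @method autoplot free_energy_surface
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$c1, .data$c2, fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = "Free-energy surface (histogram inversion)",
                  fill = "F")
}
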
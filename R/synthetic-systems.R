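new_synthetic_system <- function(name, dim, coord_names, potential, gradient,
                                 beta, references, params,
                                 spectrum = NULL, is_angular = NULL) {
  structure(list(name = name, dim = dim, coord_names = coord_names,
                 potential = potential, gradient = gradient, beta = beta,
                 references = references, params = params,
                 spectrum = spectrum,
                 is_angular = is_angular %||% rep(FALSE, dim)),
            class = "synthetic_system")
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat("<synthetic_system> ", x$name, " (dim ", x$dim, ", beta ", x$beta,
      ")\n", sep = "")
  invisible(x)
}

#' Synthetic benchmark systems with analytic oracles
#'
#' Overdamped-Langevin model systems used as ground truth throughout the
#' package. Each returns a `synthetic_system`: a potential `U(x)` and its
#' gradient (both accepting a coordinate vector or an `n x dim` matrix),
#' an inverse temperature, named reference configurations
#' (reactant / product / barrier where meaningful), and — where available
#' — a closed-form generator spectrum.
#'
#' \describe{
#'   \item{`double_well_1d(h, beta)`}{`U(x) = h (x^2 - 1)^2`: minima at
#'     `x = -1` (reactant) and `x = +1` (product), barrier of height `h` at
#'     `x = 0`. The default `h = 5`, `beta = 3` makes the barrier 15 kT, so
#'     each basin is strongly metastable.}
#'   \item{`two_well_2d(h, kappa, beta)`}{`U(x, y) = h (x^2 - 1)^2 +
#'     kappa y^2 / 2`: the double well in `x` plus a stiff harmonic `y`.
#'     With the default `kappa = 200` the in-basin `x` curvature (`8h = 40`)
#'     is five times softer than `y`, so `x` is the slow collective
#'     variable by construction.}
#'   \item{`ou_1d(k, beta)`}{Ornstein-Uhlenbeck: `U(x) = k x^2 / 2`. The
#'     backward Kolmogorov generator has the closed-form spectrum
#'     `lambda_j = -j k`, independent of `beta`, making it the primary
#'     spectral oracle.}
#'   \item{`toy_triatomic(...)`}{a 3-atom association model (an `H`
#'     approaching an `O-O` core) whose dynamical coordinates are its three
#'     internal coordinates (bond `O1-O2`, reactive bond `O1-H`, angle
#'     `H-O1-O2`): harmonic in the first bond and the angle, double-well in
#'     the reactive bond, with an analytic saddle at
#'     `(r1_eq, r2_barrier, theta_eq)`.}
#' }
#'
#' @param h double-well barrier height (energy units).
#' @param beta inverse temperature.
#' @return a `synthetic_system`.
#' @name synthetic_systems
NULL

#' @rdname synthetic_systems
#' @export
double_well_1d <- function(h = 5, beta = 3) {
  U <- function(x) h * (as.matrix(x)[, 1]^2 - 1)^2
  g <- function(x) {
    x <- as.matrix(x)
    cbind(4 * h * x[, 1] * (x[, 1]^2 - 1))
  }
  new_synthetic_system(
    "double_well_1d", 1L, "x", U, g, beta,
    references = list(reactant = -1, product = 1, barrier = 0),
    params = list(h = h)
  )
}

#' @rdname synthetic_systems
#' @param kappa harmonic stiffness of the fast `y` coordinate.
#' @export
two_well_2d <- function(h = 5, kappa = 200, beta = 3) {
  U <- function(x) {
    x <- as.matrix(x)
    h * (x[, 1]^2 - 1)^2 + kappa * x[, 2]^2 / 2
  }
  g <- function(x) {
    x <- as.matrix(x)
    cbind(4 * h * x[, 1] * (x[, 1]^2 - 1), kappa * x[, 2])
  }
  new_synthetic_system(
    "two_well_2d", 2L, c("x", "y"), U, g, beta,
    references = list(reactant = c(-1, 0), product = c(1, 0),
                      barrier = c(0, 0)),
    params = list(h = h, kappa = kappa)
  )
}

#' @rdname synthetic_systems
#' @param k harmonic stiffness of the OU process.
#' @export
ou_1d <- function(k = 2, beta = 1) {
  U <- function(x) k * as.matrix(x)[, 1]^2 / 2
  g <- function(x) cbind(k * as.matrix(x)[, 1])
  new_synthetic_system(
    "ou_1d", 1L, "x", U, g, beta,
    references = list(minimum = 0),
    params = list(k = k),
    spectrum = function(j) -(j - 1) * k
  )
}

#' @rdname synthetic_systems
#' @param k1 stiffness of the spectator bond `r1` (`O1-O2`).
#' @param r1_eq equilibrium length of `r1` (Angstrom).
#' @param h2 quartic scale of the reactive double well in `r2` (`O1-H`).
#' @param r2_barrier centre (barrier position) of the reactive bond well.
#' @param a half-separation of the two `r2` minima.
#' @param ktheta stiffness of the bend angle.
#' @param theta_eq equilibrium bend angle (radians).
#' @export
toy_triatomic <- function(k1 = 60, r1_eq = 1.3, h2 = 12, r2_barrier = 1.6,
                          a = 0.6, ktheta = 30, theta_eq = 1.85, beta = 3) {
  U <- function(x) {
    x <- as.matrix(x)
    k1 / 2 * (x[, 1] - r1_eq)^2 +
      h2 * ((x[, 2] - r2_barrier)^2 - a^2)^2 +
      ktheta / 2 * (x[, 3] - theta_eq)^2
  }
  g <- function(x) {
    x <- as.matrix(x)
    cbind(k1 * (x[, 1] - r1_eq),
          4 * h2 * (x[, 2] - r2_barrier) * ((x[, 2] - r2_barrier)^2 - a^2),
          ktheta * (x[, 3] - theta_eq))
  }
  new_synthetic_system(
    "toy_triatomic", 3L, c("r1", "r2", "theta"), U, g, beta,
    references = list(
      reactant = c(r1_eq, r2_barrier + a, theta_eq), # separated H
      product = c(r1_eq, r2_barrier - a, theta_eq),  # bound complex
      barrier = c(r1_eq, r2_barrier, theta_eq)
    ),
    params = list(k1 = k1, r1_eq = r1_eq, h2 = h2, r2_barrier = r2_barrier,
                  a = a, ktheta = ktheta, theta_eq = theta_eq),
    is_angular = c(FALSE, FALSE, TRUE)
  )
}

#' Embed toy-triatomic internal coordinates in Cartesian space
#'
#' Z-matrix-style reconstruction: `O1` at the origin, `O2` on the x axis at
#' `r1`, `H` in the xy plane at distance `r2` from `O1` under the bend
#' angle `theta` from the `O1->O2` direction.
#'
#' @param ics numeric vector `(r1, r2, theta)` or matrix with one row per
#'   frame.
#' @return `3 x 3` coordinate matrix, or a list of them for matrix input.
#' @export
triatomic_to_cartesian <- function(ics) {
  one <- function(v) {
    rbind(O1 = c(0, 0, 0),
          O2 = c(v[1], 0, 0),
          H = c(v[2] * cos(v[3]), v[2] * sin(v[3]), 0))
  }
  if (is.matrix(ics)) lapply(asplit(ics, 1), one) else one(as.numeric(ics))
}

#' Finite-difference check of a system's gradient
#' @param system a `synthetic_system`.
#' @param at coordinate vector to check at.
#' @param h step size.
#' @return maximum relative deviation between analytic and central-difference
#'   gradient components.
#' @export
check_gradient <- function(system, at, h = 1e-6) {
  at <- as.numeric(at)
  g <- as.numeric(system$gradient(matrix(at, 1)))
  fd <- vapply(seq_along(at), function(i) {
    e <- numeric(length(at)); e[i] <- h
    (system$potential(matrix(at + e, 1)) -
       system$potential(matrix(at - e, 1))) / (2 * h)
  }, numeric(1))
  max(abs(g - fd) / pmax(abs(fd), 1))
}

#' Closed-form 1-D committor by quadrature
#'
#' For a 1-D overdamped system the committor between boundaries `a < b`
#' solves the backward Kolmogorov equation with `q(a) = 0`, `q(b) = 1`,
#' giving `q(x) = int_a^x exp(beta U) ds / int_a^b exp(beta U) ds`.
#' Computed with adaptive quadrature; the integrand is rescaled by its
#' maximum so `exp(beta U)` cannot overflow.
#'
#' @param system 1-D `synthetic_system`.
#' @param a,b boundary points, `a < b`.
#' @return vectorized function `x -> q(x)` (clamped to `[0, 1]` outside
#'   `[a, b]`).
#' @export
analytic_committor_1d <- function(system, a = NULL, b = NULL) {
  if (system$dim != 1L) abort("analytic committor requires a 1-D system.")
  a <- a %||% system$references$reactant
  b <- b %||% system$references$product
  if (!(a < b)) abort("`a` must be less than `b`.")
  umax <- max(system$potential(matrix(seq(a, b, length.out = 512), ncol = 1)))
  f <- function(s) exp(system$beta * (system$potential(matrix(s, ncol = 1)) - umax))
  den <- integrate(f, a, b, rel.tol = 1e-10)$value
  function(x) {
    q <- vapply(as.numeric(x), function(xx) {
      if (xx <= a) return(0)
      if (xx >= b) return(1)
      integrate(f, a, xx, rel.tol = 1e-10)$value / den
    }, numeric(1))
    pmin(pmax(q, 0), 1)
  }
}

#' Finite-difference 1-D Kolmogorov generator on a grid
#'
#' Central-difference discretization of
#' `L = -U'(x) d/dx + beta^{-1} d^2/dx^2` with reflecting (Neumann)
#' boundaries, the operator the diffusion map approximates from samples.
#' Serves as an independent spectral oracle: eigenvalues are sorted by
#' ascending magnitude (the first is 0 with constant eigenfunction).
#'
#' @param system 1-D `synthetic_system`.
#' @param grid uniform, increasing grid vector (>= 50 points).
#' @return list with `L` (matrix), `values`, `vectors`, `grid`.
#' @export
fd_generator_1d <- function(system, grid) {
  if (system$dim != 1L) abort("finite-difference generator requires a 1-D system.")
  n <- length(grid)
  hs <- diff(grid)
  if (any(hs <= 0) || max(hs) - min(hs) > 1e-8 * mean(hs)) {
    abort("grid must be uniform and increasing.")
  }
  if (n < 50) abort("grid too coarse for a spectral oracle (need >= 50 points).")
  h <- mean(hs)
  du <- as.numeric(system$gradient(matrix(grid, ncol = 1)))
  ib <- 1 / system$beta
  L <- matrix(0, n, n)
  for (i in 2:(n - 1)) {
    L[i, i - 1] <- ib / h^2 + du[i] / (2 * h)
    L[i, i] <- -2 * ib / h^2
    L[i, i + 1] <- ib / h^2 - du[i] / (2 * h)
  }
  # reflecting ends: even ghost point, so the drift term cancels
  L[1, 1] <- -2 * ib / h^2
  L[1, 2] <- 2 * ib / h^2
  L[n, n] <- -2 * ib / h^2
  L[n, n - 1] <- 2 * ib / h^2
  es <- eigen(L)
  vals <- Re(es$values)
  ord <- order(abs(vals))
  list(L = L, values = vals[ord],
       vectors = Re(es$vectors)[, ord, drop = FALSE], grid = grid)
}
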
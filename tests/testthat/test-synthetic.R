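test_that("analytic gradients agree with finite differences", {
  systems <- list(double_well_1d(), two_well_2d(), ou_1d(),
                  toy_triatomic())
  pts <- list(0.4, c(0.7, 0.1), 0.9, c(1.35, 1.2, 1.7))
  for (i in seq_along(systems)) {
    expect_lt(check_gradient(systems[[i]], pts[[i]]), 1e-5)
  }
})

test_that("named references are stationary points of the potentials", {
  for (sys in list(double_well_1d(), two_well_2d(), toy_triatomic())) {
    for (ref in sys$references) {
      g <- sqrt(sum(sys$gradient(matrix(as.numeric(ref), 1))^2))
      expect_lt(g, 1e-8)
    }
  }
})

test_that("Langevin simulation is reproducible and records energies", {
  sys <- double_well_1d()
  t1 <- simulate_langevin(sys, n_steps = 300, seed = 5)
  t2 <- simulate_langevin(sys, n_steps = 300, seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 300)
  expect_equal(t1$x[1], -1) # initial configuration is the first frame
  expect_equal(t1$energy, as.numeric(sys$potential(cbind(t1$x))))
  # zero-noise limit from a minimum stays at the minimum
  t0 <- simulate_langevin(sys, x0 = 1, n_steps = 50, noise = FALSE)
  expect_true(all(t0$x == 1))
  # blow-up is reported with the offending step
  expect_error(simulate_langevin(sys, x0 = 3, n_steps = 100, dt = 1,
                                 seed = 1), "step")
})

test_that("OU sampling reproduces the stationary variance", {
  sys <- ou_1d(k = 2, beta = 1)
  tr <- simulate_langevin(sys, x0 = 0, n_steps = 1e5, dt = 1e-2, seed = 8)
  expect_equal(var(tr$x), 1 / 2, tolerance = 0.05)
})

test_that("long-run double-well histogram matches the Boltzmann weight", {
  sys <- double_well_1d(h = 1, beta = 1)
  tr <- simulate_langevin(sys, x0 = 1, n_steps = 2e5, dt = 1e-2, seed = 12)
  # thin far beyond the well-hopping relaxation time (a few time units) so
  # the chi-squared independence assumption holds
  x <- tr$x[seq(2000, 2e5, by = 500)]
  breaks <- c(-Inf, -1.2, -0.8, -0.4, 0, 0.4, 0.8, 1.2, Inf)
  obs <- table(cut(x, breaks))
  dens <- function(s) exp(-sys$beta * sys$potential(cbind(s)))
  z <- integrate(dens, -4, 4)$value
  p <- diff(vapply(breaks, function(b) {
    if (!is.finite(b)) return(if (b < 0) 0 else 1)
    integrate(dens, -4, b)$value / z
  }, numeric(1)))
  chi <- suppressWarnings(stats::chisq.test(as.vector(obs), p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("analytic 1-D committor satisfies boundaries and quadrature", {
  sys <- double_well_1d()
  q <- analytic_committor_1d(sys)
  expect_equal(q(-1), 0)
  expect_equal(q(1), 1)
  expect_equal(q(0), 0.5, tolerance = 1e-9) # symmetry of the potential
  # asymmetric interval: agreement with an independent Riemann-sum oracle
  ou <- ou_1d(k = 2, beta = 1)
  qa <- analytic_committor_1d(ou, a = -1, b = 2)
  grid <- seq(-1, 2, length.out = 30001)
  f <- exp(ou$beta * (ou$potential(cbind(grid)) - max(ou$potential(cbind(grid)))))
  cum <- cumsum((f[-1] + f[-length(f)]) / 2)
  riemann <- function(x) cum[which.min(abs(grid[-1] - x))] / cum[length(cum)]
  for (x0 in c(-0.5, 0.3, 1.2)) {
    expect_equal(qa(x0), riemann(x0), tolerance = 1e-6)
  }
  expect_error(analytic_committor_1d(sys, a = 1, b = -1), "less than")
  expect_error(analytic_committor_1d(two_well_2d()), "1-D")
})

test_that("shooting committor matches the analytic oracle within error bars", {
  sys <- double_well_1d()
  a_reg <- list(center = -1, radius = 0.2)
  b_reg <- list(center = 1, radius = 0.2)
  # a point inside B commits immediately
  inside <- empirical_committor(sys, 0.95, n_shots = 10, a_reg, b_reg, seed = 2)
  expect_equal(inside$q_hat, 1)
  # barrier top: 0.5 within 3 binomial standard errors
  res <- empirical_committor(sys, c(-0.3, 0, 0.3), n_shots = 400,
                             a_reg, b_reg, seed = 3, max_steps = 5000)
  qa <- analytic_committor_1d(sys)(c(-0.3, 0, 0.3))
  expect_true(all(abs(res$q_hat - qa) <= 3 * pmax(res$se, 0.02)))
  expect_lte(abs(res$q_hat[2] - 0.5), 3 * res$se[2])
  expect_true(all(res$n_timeout == 0))
  expect_error(empirical_committor(sys, 0, 10, list(center = 0, radius = 1),
                                   list(center = 1, radius = 1)), "overlap")
})

test_that("finite-difference generator reproduces the OU spectrum", {
  ou <- ou_1d(k = 2, beta = 1)
  fd <- fd_generator_1d(ou, seq(-4, 4, length.out = 400))
  expect_equal(fd$values[1], 0, tolerance = 1e-8)
  v1 <- fd$vectors[, 1]
  expect_lt(sd(v1) / abs(mean(v1)), 1e-6) # constant eigenfunction
  expect_equal(fd$values[2], -2, tolerance = 0.02) # within 2 percent
  expect_equal(fd$values[3], -4, tolerance = 0.2)
  # metastable gap of the double well: second eigenvalue tiny vs third
  dw <- double_well_1d(h = 2, beta = 2)
  fdw <- fd_generator_1d(dw, seq(-2, 2, length.out = 400))
  expect_lt(abs(fdw$values[2]), abs(fdw$values[3]) / 5)
  expect_error(fd_generator_1d(ou, seq(-1, 1, length.out = 10)), "coarse")
  expect_error(fd_generator_1d(ou, cumsum(runif(80, 0.5, 1.5))), "uniform")
})

test_that("finite-difference committor agrees with the quadrature one", {
  sys <- double_well_1d()
  grid <- seq(-1, 1, length.out = 400)
  fd <- fd_generator_1d(sys, grid)
  n <- length(grid)
  interior <- 2:(n - 1)
  L <- fd$L
  qfd <- numeric(n); qfd[n] <- 1
  qfd[interior] <- solve(L[interior, interior], -L[interior, n] * 1)
  qa <- analytic_committor_1d(sys)(grid)
  expect_lt(max(abs(qfd - qa)), 1e-3)
})

test_that("fixture bundles are deterministic and basin-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_fixture_set(d1, seed = 6, n_basin = 150, n_runs = 20,
                         n_steps = 60)
  p2 <- make_fixture_set(d2, seed = 6, n_basin = 150, n_runs = 20,
                         n_steps = 60)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  sys <- toy_triatomic()
  topo <- read_ic_topology(p1$topology)
  # basin-confined run never enters the opposite (reactant) basin
  basin <- compute_internal_coordinates(read_xyz(p1$basin), topo)
  lab <- label_basins(basin, sys$references["reactant"], radius = 0.3)
  expect_true(all(is.na(lab)))
  lab_p <- label_basins(basin, sys$references["product"], radius = 0.4)
  expect_true(mean(!is.na(lab_p)) > 0.5)
  # barrier-initiated ensemble visits both basins across runs
  ens <- compute_internal_coordinates(read_xyz(p1$ensemble), topo)
  lab2 <- label_basins(ens, sys$references[c("reactant", "product")],
                       radius = 0.35)
  expect_gt(sum(lab2 == "reactant", na.rm = TRUE), 0)
  expect_gt(sum(lab2 == "product", na.rm = TRUE), 0)
})
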
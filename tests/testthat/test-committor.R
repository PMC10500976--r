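test_that("basin assignment matches brute-force thresholding", {
  set.seed(61)
  x <- runif(300, -1.6, 1.6)
  ft <- feature_tbl(cbind(x = x))
  b <- define_basins(ft, -1, 1, cutoff = 0.2)
  expect_equal(b$A, which(abs(x + 1) <= 0.2))
  expect_equal(b$B, which(abs(x - 1) <= 0.2))
  expect_length(intersect(b$A, b$B), 0)
  # frames exactly at the references are assigned to their basin
  ft2 <- feature_tbl(cbind(x = c(-1, 0, 1)))
  b2 <- define_basins(ft2, -1, 1, cutoff = 0.05)
  expect_equal(b2$A, 1L)
  expect_equal(b2$B, 3L)
  # overlap resolves to the nearer reference
  ft3 <- feature_tbl(cbind(x = c(-0.2, 0.2, 5)))
  b3 <- define_basins(ft3, -1, 1, cutoff = 1.3)
  expect_equal(b3$A, 1L)
  expect_equal(b3$B, 2L)
  expect_error(define_basins(ft, -1, 1, cutoff = 1e-6), "increase")
  expect_error(define_basins(ft, -1, 1, cutoff = 0), "positive")
})

test_that("three-state chain solves the hand-built interior equation", {
  # transition matrix built by hand; A = {1}, B = {3}
  P <- matrix(c(0.50, 0.50, 0.00,
                0.25, 0.50, 0.25,
                0.00, 0.50, 0.50), 3, 3, byrow = TRUE)
  model <- structure(list(
    transition_matrix = P, kernel = (P > 0) * 1, n = 3L, frame = 1:3
  ), class = "diffusion_map")
  sol <- solve_committor(model, A = 1, B = 3)
  # interior equation: 0.25 q1 - 0.5 q2 + 0.25 q3 = 0 with q1=0, q3=1
  expect_equal(sol$q, c(0, 0.5, 1))
  expect_lt(sol$residual, 1e-14)
  expect_error(solve_committor(model, A = 1, B = 1), "disjoint")
  expect_error(solve_committor(model, A = integer(), B = 3), "non-empty")
  expect_error(solve_committor(model, A = c(1, 2), B = 3), "interior")
})

test_that("disconnected kernel graphs are reported, not solved", {
  x <- feature_tbl(cbind(c(0, 0.1, 0.2, 100, 100.1)))
  dm <- diffusion_map(x, kernel_config("constant", epsilon = 0.05),
                      n_modes = 0)
  expect_error(solve_committor(dm, A = 1, B = 3), "disconnected")
})

test_that("committor obeys boundaries, bounds and 1-D monotonicity", {
  run <- dw_committor_run()
  sol <- run$solution
  expect_true(all(sol$q[run$basins$B] == 1))
  expect_true(all(sol$q[run$basins$A] == 0))
  # discrete maximum principle on the connected graph
  qi <- sol$q[sol$interior]
  expect_true(all(qi > -1e-10 & qi < 1 + 1e-10))
  # nondecreasing along the sorted coordinate, within noise
  ord <- order(run$features$x)
  qs <- sol$q[ord]
  run_mean <- stats::filter(qs, rep(1 / 75, 75), sides = 2)
  drops <- diff(run_mean[!is.na(run_mean)])
  expect_gt(min(drops), -0.02)
  expect_gt(cor(run$features$x, sol$q, method = "spearman"), 0.95)
})

test_that("solution accuracy against the analytic quadrature committor", {
  run <- dw_committor_run()
  val <- committor_validation(run$solution, run$analytic)
  expect_lt(val$rmse, 0.08)
  # perfect oracle agreement yields zero error
  self <- committor_validation(run$solution, run$solution$q)
  expect_equal(self$rmse, 0)
  expect_equal(self$max_error, 0)
  expect_error(committor_validation(run$solution, 1:3), "length")
})

test_that("committor error shrinks when the sample doubles", {
  # averaged over two independent seeds (stochastic consistency)
  rmse_at <- function(n_runs, seed) {
    sys <- double_well_1d()
    feats <- langevin_ensemble(sys, n_runs = n_runs, n_steps = 100,
                               dispersion = 0.1, seed = seed)
    basins <- define_basins(feats, -1, 1, 0.2)
    dm <- diffusion_map(feats, kernel_config("weighted", r = 0.002,
                                             weight_mode = "energy",
                                             beta = sys$beta), n_modes = 0)
    committor_validation(solve_committor(dm, basins),
                         analytic_committor_1d(sys)(feats$x))$rmse
  }
  seeds <- c(101, 505)
  small <- mean(vapply(seeds, function(s) rmse_at(20, s), numeric(1)))
  big <- mean(vapply(seeds, function(s) rmse_at(40, s + 11), numeric(1)))
  expect_lt(big, small)
})

test_that("isocommittor band selects the transition region", {
  q <- c(0, 0.2, 0.5, 0.81, 1)
  expect_equal(isocommittor_band(q, 0.5, tol = 0), 3L)
  expect_equal(isocommittor_band(q, 0.5, tol = 1), 1:5)
  run <- dw_committor_run()
  band <- isocommittor_band(run$solution, 0.5, tol = 0.1)
  expect_gt(length(band), 0)
  # the band sits near the barrier top of the double well
  expect_lt(median(abs(run$features$x[band])), 0.15)
})

test_that("committor tidiers label basins and plot", {
  run <- dw_committor_run()
  tb <- tidy(run$solution)
  expect_equal(sum(tb$basin == "A"), length(run$basins$A))
  expect_equal(sum(tb$basin == "B"), length(run$basins$B))
  g <- glance(run$solution)
  expect_lt(g$residual, 1e-9)
  expect_s3_class(autoplot(run$solution), "ggplot")
})

test_that("near-reference selection restricts non-plotted coordinates", {
  X <- feature_tbl(cbind(a = c(1, 1.05, 2), b = c(0, 0.5, 0.01),
                         th = c(0.1, 0.1, pi)), is_angular = c(FALSE, FALSE, TRUE))
  ref <- c(1, 0, 0.1)
  expect_equal(select_near_reference(X, ref, tol = 0.2), 1L)
  # excluding the plotted coordinate frees it from the restriction
  expect_equal(select_near_reference(X, ref, tol = 0.2, exclude = "b"), 1:2)
  # angular wrap: a frame at -pi+0.05 is near a reference at pi
  X2 <- feature_tbl(cbind(th = c(-pi + 0.05, 0)), is_angular = TRUE)
  expect_equal(select_near_reference(X2, pi, tol = 0.1), 1L)
  expect_error(select_near_reference(X, c(1, 0), 0.1), "dimension")
  expect_error(select_near_reference(X, ref, 0.1, exclude = "zz"), "unknown")
})
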
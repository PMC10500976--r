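test_that("every constructed model satisfies the stochastic-matrix bounds", {
  set.seed(41)
  X <- feature_tbl(cbind(rnorm(60), rnorm(60)))
  for (kc in list(kernel_config("constant"),
                  kernel_config("locally_scaled", r = 0.2),
                  kernel_config("alpha_normalized", alpha = 1),
                  kernel_config("weighted", r = 0.2, weight_mode = "inv_rowsum"))) {
    dm <- diffusion_map(X, kc, n_modes = 6)
    P <- dm$transition_matrix
    expect_equal(rowSums(P), rep(1, 60), tolerance = 1e-10)
    expect_true(all(P >= 0))
    expect_equal(dm$eigenvalues[1], 1, tolerance = 1e-8)
    expect_true(all(dm$eigenvalues <= 1 + 1e-10 & dm$eigenvalues >= -1 - 1e-10))
    # trivial eigenvector is constant, generator null mode is 0
    v1 <- dm$eigenvectors[, 1]
    expect_lt(sd(v1) / abs(mean(v1)), 1e-6)
    expect_lt(abs(dm$generator_eigenvalues[1]), 1e-8)
  }
})

test_that("energy weights are applied and require energies", {
  set.seed(42)
  X <- feature_tbl(cbind(rnorm(40)))
  expect_error(diffusion_map(X, kernel_config("weighted", r = 0.2,
                                              weight_mode = "energy")),
               "energies")
  X$energy <- X$f1^2
  dm <- diffusion_map(X, kernel_config("weighted", r = 0.2,
                                       weight_mode = "energy"), n_modes = 3)
  expect_equal(dm$n, 40)
  expect_equal(length(dm$weights), 40)
  expect_equal(max(dm$weights), 1) # weight 1 at the energy minimum
})

test_that("two well-separated clusters split on the second eigenvector", {
  set.seed(43)
  X <- feature_tbl(cbind(c(rnorm(25, 0, 0.1), rnorm(25, 3, 0.1))))
  dm <- diffusion_map(X, kernel_config("constant", epsilon = 0.5),
                      n_modes = 3)
  v2 <- dm$eigenvectors[, 2]
  expect_true(all(sign(v2[1:25]) == sign(v2[1])))
  expect_true(all(sign(v2[26:50]) == -sign(v2[1])))
  expect_gt(dm$eigenvalues[2], 0.99) # metastable mode survives
})

test_that("diffusion coordinates label and scale the nontrivial modes", {
  set.seed(44)
  X <- feature_tbl(cbind(seq(0, 1, length.out = 30) + rnorm(30, 0, 0.01)))
  dm <- diffusion_map(X, kernel_config("constant"), n_modes = 5, t = 2)
  dcs <- tidy(dm)
  expect_named(dcs, c("frame", paste0("DC", 2:5)))
  expect_equal(dcs$DC3, dm$eigenvalues[3]^2 * dm$eigenvectors[, 3],
               tolerance = 1e-12)
  expect_error(diffusion_coordinates(dm, k = 10), "nontrivial")
  # identical snapshots carry identical coordinates
  X2 <- feature_tbl(cbind(c(0, 0, 1, 2, 3)))
  dm2 <- diffusion_map(X2, kernel_config("constant", epsilon = 1), n_modes = 3)
  d2 <- tidy(dm2)
  expect_equal(unlist(d2[1, -1]), unlist(d2[2, -1]), tolerance = 1e-9)
})

test_that("diffusion distance equals the spectral sum and is a norm", {
  set.seed(45)
  X <- feature_tbl(cbind(c(0, 0.4, 1.1, 2.3, 3.0)))
  dm <- diffusion_map(X, kernel_config("constant", epsilon = 2), n_modes = 5,
                      t = 1)
  dcs <- as.matrix(tidy(dm)[, -1])
  # direct summation oracle over eigenpairs
  lam <- dm$eigenvalues; V <- dm$eigenvectors
  for (i in 1:5) for (j in 1:5) {
    direct <- sqrt(sum(lam[2:5]^2 * (V[i, 2:5] - V[j, 2:5])^2))
    expect_equal(diffusion_distance(dcs[i, ], dcs[j, ]), direct,
                 tolerance = 1e-12)
  }
  # truncation splits the squared distance exactly into kept + remainder
  dc2 <- as.matrix(diffusion_coordinates(dm, k = 2)[, -1])
  full <- diffusion_distance(dcs[1, ], dcs[4, ])^2
  kept <- diffusion_distance(dc2[1, ], dc2[4, ])^2
  rest <- sum(lam[4:5]^2 * (V[1, 4:5] - V[4, 4:5])^2)
  expect_equal(full, kept + rest, tolerance = 1e-12)
  # triangle inequality on random triples
  for (k in 1:20) {
    ijk <- sample(5, 3)
    expect_lte(diffusion_distance(dcs[ijk[1], ], dcs[ijk[2], ]),
               diffusion_distance(dcs[ijk[1], ], dcs[ijk[3], ]) +
                 diffusion_distance(dcs[ijk[3], ], dcs[ijk[2], ]) + 1e-12)
  }
  expect_error(diffusion_distance(1:3, 1:4), "length")
})

test_that("slow coordinate of a stiff 2-D system is recovered by DC2", {
  sys <- two_well_2d() # slow x, stiff y
  tr <- simulate_langevin(sys, x0 = c(1, 0), n_steps = 800, seed = 46)
  dm <- diffusion_map(tr, kernel_config("weighted", r = 0.1,
                                        weight_mode = "energy",
                                        beta = sys$beta), n_modes = 3)
  rho <- abs(cor(tidy(dm)$DC2, tr$x))
  expect_gt(rho, 0.9)
})

test_that("model caps, errors and accessors behave", {
  X <- feature_tbl(cbind(rnorm(30)))
  expect_error(diffusion_map(X, max_n = 10), "cap")
  expect_error(diffusion_map(X, n_modes = 31), "exceeds")
  dm <- diffusion_map(X, kernel_config("constant"), n_modes = 0)
  expect_null(dm$eigenvalues)
  expect_error(tidy(dm), "spectrum")
  dm <- spectral_decompose(dm, 4)
  expect_length(dm$eigenvalues, 4)
  g <- glance(dm)
  expect_equal(g$n, 30)
  expect_s3_class(autoplot(dm), "ggplot")
})

test_that("diffusion maps serialize to a readable CSV archive", {
  set.seed(47)
  X <- feature_tbl(cbind(rnorm(25)))
  dm <- diffusion_map(X, kernel_config("locally_scaled", r = 0.2), n_modes = 3)
  dir <- withr::local_tempdir()
  paths <- write_diffusion_map(dm, dir)
  expect_true(all(file.exists(paths)))
  ev <- utils::read.csv(file.path(dir, "eigenvalues.csv"))
  expect_equal(ev$lambda_P, dm$eigenvalues, tolerance = 1e-12)
  dcs <- utils::read.csv(file.path(dir, "diffusion_coordinates.csv"))
  expect_equal(dcs$DC2, tidy(dm)$DC2, tolerance = 1e-12)
  expect_error(write_diffusion_map(diffusion_map(X, n_modes = 0), dir),
               "spectrum")
})
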
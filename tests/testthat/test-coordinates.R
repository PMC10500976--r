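test_that("wrap_angle_difference handles boundary-straddling angles", {
  expect_equal(wrap_angle_difference(pi / 6, 2 * pi - pi / 6), pi / 3)
  expect_equal(wrap_angle_difference(1.3, 1.3), 0)
  expect_equal(wrap_angle_difference(0, pi), pi)
  expect_error(wrap_angle_difference(Inf, 0), "finite")
})

test_that("wrap_angle_difference is symmetric, bounded, 2pi-invariant", {
  set.seed(1)
  th1 <- runif(200, -10, 10)
  th2 <- runif(200, -10, 10)
  d12 <- wrap_angle_difference(th1, th2)
  expect_equal(d12, wrap_angle_difference(th2, th1))
  expect_true(all(d12 >= 0 & d12 <= pi))
  expect_equal(d12, wrap_angle_difference(th1 + 2 * pi, th2), tolerance = 1e-9)
  expect_equal(d12, wrap_angle_difference(th1, th2 - 4 * pi), tolerance = 1e-9)
})

test_that("feature_distance applies the wrap inside the norm", {
  expect_equal(feature_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(feature_distance(1.0, 2.0), 1.0)
  # mixed vector differing only in one angle straddling the boundary
  a <- c(1.0, pi / 6)
  b <- c(1.0, 2 * pi - pi / 6)
  expect_equal(feature_distance(a, b, is_angular = c(FALSE, TRUE)), pi / 3)
  expect_error(feature_distance(1, c(1, 2)), "length")
})

test_that("wrapped feature distance is a metric on random triples", {
  set.seed(2)
  ang <- c(FALSE, TRUE, TRUE, FALSE)
  for (i in 1:50) {
    x <- runif(4, -5, 5); y <- runif(4, -5, 5); z <- runif(4, -5, 5)
    dxy <- feature_distance(x, y, ang)
    dyx <- feature_distance(y, x, ang)
    expect_equal(dxy, dyx)
    expect_equal(feature_distance(x, x, ang), 0)
    expect_lte(dxy, feature_distance(x, z, ang) + feature_distance(z, y, ang) + 1e-12)
  }
})

test_that("feature_distance_matrix matches pairwise feature_distance", {
  set.seed(3)
  X <- cbind(runif(7, 0, 3), runif(7, -pi, pi))
  ft <- feature_tbl(X, is_angular = c(FALSE, TRUE))
  D <- feature_distance_matrix(ft)
  for (i in 1:7) for (j in 1:7) {
    expect_equal(D[i, j], feature_distance(X[i, ], X[j, ], c(FALSE, TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("internal coordinates reproduce constructed geometries", {
  # bond of 1.5 A, right angle, cis (0) and trans (pi) dihedrals
  f_cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  f_trans <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0))
  tr <- trajectory_tbl(list(f_cis, f_trans), c("C", "C", "C", "C"))
  topo <- ic_topology(bonds = list(c(2, 3)), angles = list(c(1, 2, 3)),
                      dihedrals = list(c(1, 2, 3, 4)))
  ics <- compute_internal_coordinates(tr, topo)
  expect_equal(ics[[2]], c(1, 1))               # bond length
  expect_equal(ics[[3]], c(pi / 2, pi / 2))     # right angle both frames
  expect_equal(abs(ics[[4]]), c(0, pi))         # cis 0, trans pi
  expect_equal(unname(angular_mask(ics)), c(FALSE, TRUE, TRUE))

  tr2 <- trajectory_tbl(list(rbind(c(0, 0, 0), c(1.5, 0, 0))), c("O", "H"))
  ics2 <- compute_internal_coordinates(tr2, ic_topology(bonds = list(c(1, 2))))
  expect_equal(ics2[[2]], 1.5)
})

test_that("degenerate angles are flagged with frame and coordinate", {
  f <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  tr <- trajectory_tbl(list(f), c("C", "C", "C", "C"))
  topo <- ic_topology(dihedrals = list(c(1, 2, 3, 4)), names = "chain")
  expect_error(compute_internal_coordinates(tr, topo), "chain.*frame 1")
  expect_warning(
    ics <- compute_internal_coordinates(tr, topo, degenerate = "nan"),
    "NaN")
  expect_true(is.nan(ics$chain))
})

test_that("ic_topology validates indices and duplicates", {
  expect_error(ic_topology(bonds = list(c(1, 1))), "distinct")
  expect_error(ic_topology(bonds = list(c(1, 2), c(1, 2))), "duplicate")
  expect_error(ic_topology(), "empty")
  tr <- trajectory_tbl(list(rbind(c(0, 0, 0), c(1, 0, 0))), c("H", "H"))
  expect_error(
    compute_internal_coordinates(tr, ic_topology(bonds = list(c(1, 5)))),
    "outside")
})

test_that("kabsch alignment removes rigid motions and matches bio3d", {
  ref <- frame_coords(toy_traj(), 1)
  moved <- rigid_motion(ref, seed = 9)
  tr <- trajectory_tbl(list(ref, moved), c("O", "H", "H", "O"))
  res <- kabsch_align(tr, ref)
  expect_equal(res$rmsd$rmsd[1], 0, tolerance = 1e-10)
  expect_equal(res$rmsd$rmsd[2], 0, tolerance = 1e-8)

  # independent route: bio3d's superposition on a non-rigid pair
  set.seed(10)
  frame2 <- ref + matrix(rnorm(12, 0, 0.4), 4, 3)
  tr2 <- trajectory_tbl(list(frame2), c("O", "H", "H", "O"))
  ours <- kabsch_align(tr2, ref)$rmsd$rmsd[1]
  theirs <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(frame2)), fit = TRUE)
  expect_lt(abs(ours - theirs), 5e-4) # bio3d reports 3 decimals

  # alignment never increases the RMSD, and is pre-rotation invariant
  unaligned <- sqrt(mean(rowSums((frame2 - ref)^2)))
  expect_lte(ours, unaligned + 1e-12)
  tr3 <- trajectory_tbl(list(rigid_motion(frame2, seed = 11)),
                        c("O", "H", "H", "O"))
  expect_equal(kabsch_align(tr3, ref)$rmsd$rmsd[1], ours, tolerance = 1e-8)
})

test_that("kabsch alignment falls back to translation for < 3 atoms", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0))
  tr <- trajectory_tbl(list(ref + 5), c("H", "H"))
  expect_warning(res <- kabsch_align(tr, ref), "ill-posed")
  expect_equal(res$rmsd$rmsd[1], 0, tolerance = 1e-10)
})

test_that("coordination number has Fermi-Dirac limits and monotonicity", {
  put <- function(r) rbind(c(0, 0, 0), c(r, 0, 0))
  expect_lt(coordination_number(put(9), 1, 2, r0 = 1.5), 1e-8)
  expect_gt(coordination_number(put(0.3), 1, 2, r0 = 1.5), 1 - 1e-4)
  expect_equal(coordination_number(put(1.5), 1, 2, r0 = 1.5), 0.5)
  # monotone non-increasing in each neighbour distance
  rs <- seq(0.5, 3, by = 0.1)
  cn <- vapply(rs, function(r) coordination_number(put(r), 1, 2, r0 = 1.5),
               numeric(1))
  expect_true(all(diff(cn) <= 1e-12))
  expect_error(coordination_number(put(1), 1, c(1, 2), r0 = 1), "own neigh")
  # bounded by the neighbour count
  f3 <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0))
  expect_lte(coordination_number(f3, 1, c(2, 3), r0 = 2), 2)
})
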
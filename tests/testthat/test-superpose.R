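test_that("kabsch recovers identity and planted rigid motions", {
  set.seed(1)
  a <- random_coords(6)
  f <- kabsch(a, a)
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)

  # 90 degree rotation about z plus translation
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  b <- a %*% R90 + matrix(c(1, 2, 3), nrow(a), 3, byrow = TRUE)
  f <- kabsch(a, b)
  expect_equal(f$rmsd, 0, tolerance = 1e-9)
  expect_equal(sweep(a %*% f$rotation, 2, f$translation, `+`), b,
               tolerance = 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
})

test_that("mirror images give positive RMSD and never a reflection", {
  set.seed(2)
  a <- random_coords(5)
  b <- a %*% diag(c(-1, 1, 1))  # reflection: unreachable by proper rotation
  f <- kabsch(a, b)
  expect_gt(f$rmsd, 0.1)
  expect_equal(det(f$rotation), 1, tolerance = 1e-9)
  # brute-force search over proper rotations confirms kabsch found the minimum
  expect_equal(f$rmsd, rmsd_bruteforce(a, b), tolerance = 1e-3)
})

test_that("kabsch matches the brute-force rotation-grid oracle", {
  set.seed(3)
  for (rep in 1:8) {
    k <- sample(4:6, 1)
    a <- random_coords(k)
    b <- random_coords(k)
    expect_equal(kabsch(a, b)$rmsd, rmsd_bruteforce(a, b), tolerance = 1e-3)
  }
})

test_that("degenerate inputs are refused", {
  expect_error(kabsch(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line + 1), "collinear")
})

test_that("rmsd_between is zero for identical frames and rigid motions", {
  sp <- sim_spec(n_res_a = 6, n_res_b = 5, n_snapshots = 2, sigma = 0.3, seed = 5)
  tr <- simulate_traj(sp)
  expect_equal(rmsd_between(tr, 1, 1, atom_select(atom_class = "calpha")), 0,
               tolerance = 1e-9)
  # frame 2 replaced by a rigid motion of frame 1
  set.seed(6)
  R <- random_rotation()
  co <- matrix(tr$xyz[1, ], ncol = 3, byrow = TRUE) %*% R
  co <- sweep(co, 2, c(3, -2, 7), `+`)
  tr$xyz[2, ] <- as.numeric(t(co))
  expect_lt(rmsd_between(tr, 1, 2, atom_select(atom_class = "calpha")), 1e-6)
})

test_that("rmsd_matrix is symmetric with zero diagonal and metric on fixtures", {
  sp <- sim_spec(n_res_a = 8, n_res_b = 6, n_snapshots = 12, sigma = 0.4, seed = 7)
  m <- rmsd_matrix(simulate_traj(sp), atom_select(atom_class = "calpha"))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(m), rep(0, 12))
  expect_true(all(m >= 0))
  # triangle inequality (RMSD over an identical atom set is a metric)
  n <- nrow(m)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-6)
})

test_that("rmsd agrees with an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  set.seed(8)
  a <- random_coords(10)
  b <- a + matrix(rnorm(30, 0, 0.8), 10, 3)
  ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
  # bio3d rounds its RMSD to three decimals
  expect_equal(kabsch(a, b)$rmsd, ref, tolerance = 1e-3)
})

test_that("two-state trajectories produce block-structured RMSD matrices", {
  sp <- sim_spec(n_res_a = 10, n_res_b = 10, n_snapshots = 40,
                 sigma = 0.5 / sqrt(3), seed = 9)
  sp <- add_state_displacement(sp, separation = 5)
  sp <- set_dwell(sp, c(0.5, 0.5))
  tr <- simulate_traj(sp)
  m <- rmsd_matrix(tr, atom_select(atom_class = "calpha"))
  within1 <- m[1:20, 1:20][upper.tri(m[1:20, 1:20])]
  within2 <- m[21:40, 21:40][upper.tri(m[21:40, 21:40])]
  between <- m[1:20, 21:40]
  expect_lt(max(within1, within2), 2)
  expect_gt(min(between), 3)
})

test_that("rmsf recovers planted isotropic fluctuation amplitudes", {
  # sigma = 0.5 A per coordinate: expected RMSF = sigma * sqrt(3)
  sp <- sim_spec(n_res_a = 40, n_res_b = 40, n_snapshots = 2000,
                 sigma = 0.5, seed = 10)
  pr <- rmsf_profile(simulate_traj(sp))
  gt <- ground_truth(sp)
  expect_equal(nrow(pr), 80)
  expect_lt(max(abs(pr$rmsf - gt$rmsf$rmsf_expected) / gt$rmsf$rmsf_expected),
            0.05)
  expect_equal(mean(pr$relative), 1, tolerance = 1e-9)
})

test_that("doubling the planted sigma doubles the RMSF", {
  sp1 <- sim_spec(n_res_a = 25, n_res_b = 25, n_snapshots = 800,
                  sigma = 0.3, seed = 12)
  sp2 <- sim_spec(n_res_a = 25, n_res_b = 25, n_snapshots = 800,
                  sigma = 0.6, seed = 12)
  r1 <- rmsf_profile(simulate_traj(sp1))$rmsf
  r2 <- rmsf_profile(simulate_traj(sp2))$rmsf
  expect_equal(mean(r2 / r1), 2, tolerance = 0.05)
})

test_that("static trajectories have zero RMSF", {
  sp <- sim_spec(n_res_a = 5, n_res_b = 5, n_snapshots = 10, sigma = 0, seed = 1)
  pr <- suppressWarnings(rmsf_profile(simulate_traj(sp)))
  expect_true(all(pr$rmsf < 1e-10))
})

test_that("flexibility classes follow the relative-RMSF bin edges", {
  pr <- data.frame(relative = c(0.4, 0.5, 0.99, 1.0, 1.49, 1.5, 2.0, 2.5,
                                3.0, 3.2))
  cls <- classify_flexibility(pr)$flex_class
  expect_equal(as.character(cls),
               c("<0.5 (black)", "0.5-1 (blue)", "0.5-1 (blue)",
                 "1-1.5 (light blue)", "1-1.5 (light blue)",
                 "1.5-2 (light green)", "2-2.5 (yellow)", "2.5-3 (orange)",
                 ">3 (red)", ">3 (red)"))
  # total and monotone
  expect_false(anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
})
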
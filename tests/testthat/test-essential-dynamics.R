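planted_mode_spec <- function(n_snapshots = 2000, sigma = 0.02, seed = 40) {
  sp <- sim_spec(n_res_a = 15, n_res_b = 15, sigma = sigma,
                 n_snapshots = n_snapshots, seed = seed)
  sp <- add_planted_mode(sp, amplitude = 1.0, period = 100)
  add_planted_mode(sp, amplitude = 0.5, period = 37)
}

test_that("static trajectories have all-zero eigenvalues", {
  sp <- sim_spec(n_res_a = 5, n_res_b = 5, n_snapshots = 10, sigma = 0, seed = 41)
  dec <- suppressWarnings(traj_pca(simulate_traj(sp)))
  expect_true(all(dec$eigenvalues < 1e-12))
})

test_that("planted modes are recovered in order with correct spectra", {
  sp <- planted_mode_spec()
  tr <- simulate_traj(sp)
  gt <- ground_truth(sp)
  dec <- traj_pca(tr)
  # mode directions: |cosine| similarity >= 0.99 against the planted vectors
  cos1 <- abs(sum(dec$eigenvectors[, 1] * gt$modes[[1]]$vector))
  cos2 <- abs(sum(dec$eigenvectors[, 2] * gt$modes[[2]]$vector))
  expect_gte(cos1, 0.99)
  expect_gte(cos2, 0.99)
  # planted 4:1 eigenvalue ratio recovered within 10%
  ratio <- dec$eigenvalues[1] / dec$eigenvalues[2]
  planted <- gt$modes[[1]]$eigenvalue_expected / gt$modes[[2]]$eigenvalue_expected
  expect_lt(abs(ratio / planted - 1), 0.10)
  # leading eigenvalue close to the planted sinusoid variance
  expect_equal(dec$eigenvalues[1], gt$modes[[1]]$eigenvalue_expected,
               tolerance = 0.1)
})

test_that("eigen decomposition satisfies its algebraic identities", {
  sp <- sim_spec(n_res_a = 8, n_res_b = 8, sigma = 0.3, n_snapshots = 100,
                 seed = 42)
  dec <- traj_pca(simulate_traj(sp))
  # trace identity: sum of eigenvalues = total coordinate variance
  expect_equal(sum(dec$eigenvalues), sum(apply(dec$projections, 2, var)),
               tolerance = 1e-8)
  # orthonormal eigenvector columns
  G <- crossprod(dec$eigenvectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # variance fractions sum to one
  expect_equal(sum(dec$variance_fraction), 1, tolerance = 1e-9)
  # projections: zero mean, variance equal to the eigenvalue
  expect_lt(max(abs(colMeans(dec$projections))), 1e-8)
  nz <- dec$eigenvalues > 1e-10
  expect_equal(apply(dec$projections[, nz], 2, var), dec$eigenvalues[nz],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pca agrees with an independent essential-dynamics implementation", {
  skip_if_not_installed("bio3d")
  sp <- planted_mode_spec(n_snapshots = 400, seed = 43)
  tr <- simulate_traj(sp)
  dec <- traj_pca(tr)
  fitted <- bio3d::fit.xyz(fixed = tr$xyz[1, ], mobile = tr$xyz,
                           fixed.inds = seq_len(ncol(tr$xyz)),
                           mobile.inds = seq_len(ncol(tr$xyz)))
  ref <- bio3d::pca.xyz(fitted, use.svd = FALSE)
  # alignment details differ (iterated mean vs first frame) but the planted
  # modes dominate: leading spectra and directions must agree
  expect_equal(dec$eigenvalues[1:2], ref$L[1:2], tolerance = 0.02)
  expect_gt(abs(sum(dec$eigenvectors[, 1] * ref$U[, 1])), 0.99)
  expect_gt(abs(sum(dec$eigenvectors[, 2] * ref$U[, 2])), 0.99)
})

test_that("insufficient snapshots and bad stride are refused", {
  sp <- sim_spec(n_res_a = 5, n_res_b = 5, n_snapshots = 20, sigma = 0.2,
                 seed = 44, dt_ns = 2)
  tr <- simulate_traj(sp)
  expect_error(traj_pca(tr, stride_ns = 20), "at least 3")
  dec <- traj_pca(tr, stride_ns = 4)
  expect_equal(nrow(dec$projections), 10L)
})

test_that("mode mobility is localized on planted residues and norm-consistent", {
  # plant a mode confined to residues 11-14 of chain A
  sp <- sim_spec(n_res_a = 20, n_res_b = 10, sigma = 0.02, n_snapshots = 600,
                 seed = 45)
  ref <- build_reference(sp)
  natoms <- nrow(ref)
  v <- rep(0, 3 * natoms)
  target <- which(ref$chain == "A" & ref$resseq %in% 11:14)
  set.seed(46)
  for (i in target) v[(3 * i - 2):(3 * i)] <- rnorm(3)
  v <- v / sqrt(sum(v^2))
  sp$modes <- list(list(vector = v, amplitude = 1.2, period = 80))
  dec <- traj_pca(simulate_traj(sp))
  mob <- mode_mobility(dec, 1)
  expect_equal(order(mob, decreasing = TRUE)[1:4], sort(target)[order(-mob[target])])
  expect_gt(min(mob[target]) / max(mob[-target]), 2)
  # sum of squared mobilities equals the eigenvalue
  expect_equal(sum(mob^2), dec$eigenvalues[1], tolerance = 1e-8)
  expect_error(mode_mobility(dec, 10000), "out of range")
})

test_that("dccm recovers planted correlated and anti-correlated pairs", {
  set.seed(47)
  n <- 400
  base <- random_coords(10, scale = 8)
  s <- sin(2 * pi * seq_len(n) / 50)
  u <- c(1, 0, 0)
  f <- function(t) {
    co <- base + matrix(rnorm(30, 0, 0.02), 10, 3)
    co[9, ] <- co[9, ] + s[t] * u
    co[10, ] <- co[10, ] - s[t] * u
    co
  }
  tr <- manual_traj(ca_topology(10), n, f)
  cc <- traj_dccm(tr)
  expect_equal(unname(diag(cc)), rep(1, 10))
  expect_lt(cc[9, 10], -0.95)
  expect_true(all(cc >= -1 & cc <= 1))
  # same-direction motion instead: correlation flips to +1
  f2 <- function(t) {
    co <- base + matrix(rnorm(30, 0, 0.02), 10, 3)
    co[9, ] <- co[9, ] + s[t] * u
    co[10, ] <- co[10, ] + s[t] * u
    co
  }
  cc2 <- traj_dccm(manual_traj(ca_topology(10), n, f2))
  expect_gt(cc2[9, 10], 0.95)
})

test_that("dccm is invariant under a global rotation of all frames", {
  sp <- sim_spec(n_res_a = 6, n_res_b = 6, sigma = 0.3, n_snapshots = 80,
                 seed = 48)
  tr <- simulate_traj(sp)
  cc <- traj_dccm(tr)
  set.seed(49)
  R <- random_rotation()
  rot <- t(apply(tr$xyz, 1, function(row)
    as.numeric(t(matrix(row, ncol = 3, byrow = TRUE) %*% R))))
  tr2 <- trajectory(tr$topology, rot, dt_ns = tr$dt_ns)
  expect_equal(unclass(traj_dccm(tr2)), unclass(cc), tolerance = 1e-6)
})

test_that("zero-variance residues yield zero correlations with a warning", {
  set.seed(50)
  base <- random_coords(8, scale = 6)
  tr <- manual_traj(ca_topology(8), 10, function(t) base)  # fully static
  expect_warning(cc <- traj_dccm(tr), "zero variance")
  expect_equal(unname(diag(cc)), rep(1, 8))
  expect_true(all(cc[upper.tri(cc)] == 0))
})
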
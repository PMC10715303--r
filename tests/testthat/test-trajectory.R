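test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 3)
  same <- superpose(x, x)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(same$rotation), 1, tolerance = 1e-10)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg about z
  moved <- x %*% t(Rz) + matrix(c(5, -2, 7), nrow(x), 3, byrow = TRUE)
  fit <- superpose(moved, x)
  expect_lt(fit$rmsd, 1e-8)
})

test_that("Kabsch RMSD matches a rotation-grid + polish oracle on a 4-atom pair", {
  ref <- matrix(c(0, 0, 0,  1.5, 0, 0,  0, 2, 0,  0.5, 0.5, 1.8), 4, 3, byrow = TRUE)
  mob <- ref + matrix(c(0.3, -0.2, 0.1,  -0.1, 0.25, -0.3,
                        0.2, 0.1, 0.15,  -0.4, -0.1, 0.2), 4, 3, byrow = TRUE)
  got <- superpose(mob, ref)$rmsd
  # independent oracle: centred RMSD as a function of Euler angles, coarse
  # grid then Nelder-Mead polish (never touches the SVD path)
  cref <- sweep(ref, 2, colMeans(ref)); cmob <- sweep(mob, 2, colMeans(mob))
  euler_rmsd <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rx <- matrix(c(1, 0, 0, 0, ca[1], -sa[1], 0, sa[1], ca[1]), 3, 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, 3, byrow = TRUE)
    Rz <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, 3, byrow = TRUE)
    d <- cmob %*% t(Rz %*% Ry %*% Rx) - cref
    sqrt(mean(rowSums(d^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (cc in grid) {
    v <- euler_rmsd(c(a, b, cc))
    if (v < best) { best <- v; best_ang <- c(a, b, cc) }
  }
  pol <- stats::optim(best_ang, euler_rmsd, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(abs(got - pol$value), 1e-3)
  expect_lte(got, pol$value + 1e-9)  # Kabsch is the true minimum
})

test_that("superposition rejects degenerate selections", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), class = "setphen_argument_error")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "setphen_argument_error")
})

test_that("RMSD series is zero for rigid-motion-only trajectories", {
  helix <- build_helix(20, backbone = "full")
  tr0 <- gen_trajectory(helix, sigma = 0, n_frames = 5, seed = 3)
  expect_true(all(rmsd_series(tr0)$rmsd < 1e-8))
  tr1 <- gen_trajectory(helix, sigma = 0, n_frames = 5, seed = 3,
                        rigid_motion = TRUE)
  expect_true(all(rmsd_series(tr1)$rmsd < 1e-8))
})

test_that("RMSF recovers the generator's per-residue amplitude profile", {
  helix <- build_helix(50, backbone = "cacb")
  sigma <- 0.5
  n <- 2000
  tr <- gen_trajectory(helix, sigma = sigma, n_frames = n, seed = 21)
  prof <- rmsf_profile(tr, selection = "CA")
  expected <- sigma * sqrt(3) * sqrt((n - 1) / n)
  ratio <- prof$rmsf / expected
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # doubling every amplitude doubles the profile (within sampling error)
  tr2 <- gen_trajectory(helix, sigma = 2 * sigma, n_frames = 400, seed = 22)
  tr1 <- gen_trajectory(helix, sigma = sigma, n_frames = 400, seed = 22)
  r2 <- rmsf_profile(tr2, selection = "CA")$rmsf
  r1 <- rmsf_profile(tr1, selection = "CA")$rmsf
  expect_lt(abs(mean(r2 / r1) - 2), 0.1)
})

test_that("RMSF is invariant to per-frame global rigid motion", {
  helix <- build_helix(25, backbone = "cacb")
  tr_a <- gen_trajectory(helix, sigma = 0.4, n_frames = 300, seed = 8)
  tr_b <- gen_trajectory(helix, sigma = 0.4, n_frames = 300, seed = 8,
                         rigid_motion = TRUE)
  # same displacement stream; rigid motion consumes extra RNG numbers, so
  # compare distributional summaries rather than frames
  ra <- rmsf_profile(tr_a, selection = "CA")$rmsf
  rb <- rmsf_profile(tr_b, selection = "CA")$rmsf
  expect_lt(abs(mean(ra) - mean(rb)) / mean(ra), 0.1)
  # identical frames rigidly moved: exact invariance
  all_same <- gen_trajectory(helix, sigma = 0, n_frames = 50, seed = 9,
                             rigid_motion = TRUE)
  expect_true(all(rmsf_profile(all_same, selection = "CA")$rmsf < 1e-8))
})

test_that("RMSF comparison scores: identical, shifted and reshaped profiles", {
  wt <- c(0.4, 0.7, 1.2, 0.5, 0.9, 0.3)
  same <- rmsf_compare(wt, wt)
  expect_equal(same$r_rmsf, 1.0)
  expect_equal(same$mean_abs_diff, 0.0)
  shifted <- rmsf_compare(wt, wt + 0.3)
  expect_equal(shifted$r_rmsf, 1.0)
  expect_equal(shifted$mean_abs_diff, 0.3)
  expect_lt(rmsf_compare(wt, rev(wt))$r_rmsf, 1)
  expect_warning(z <- rmsf_compare(rep(1, 6), wt), "zero-variance")
  expect_true(is.na(z$r_rmsf))
})

test_that("radius of gyration: point, dumbbell, and direct-formula oracle", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1.0)
  set.seed(12)
  cloud <- matrix(rnorm(60, sd = 3), ncol = 3)
  m <- runif(20, 0.5, 2)
  com <- colSums(cloud * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(cloud, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(cloud, m), oracle, tolerance = 1e-10)
  expect_error(radius_of_gyration(two, c(0, 0)), class = "setphen_argument_error")
})

test_that("SASA: isolated sphere, coincident atoms, additivity, convergence", {
  one <- sasa(matrix(0, 1, 3), "S", probe = 1.4, n_points = 960,
              radii = c(S = 1.9))
  exact <- 4 * pi * (1.9 + 1.4)^2
  expect_lt(abs(one$total - exact) / exact, 0.01)

  twin <- sasa(matrix(0, 2, 3, byrow = TRUE), c("C", "C"))
  lone <- sasa(matrix(0, 1, 3), "C")
  expect_lt(abs(twin$total - lone$total) / lone$total, 0.01)

  far <- sasa(matrix(c(0, 0, 0, 50, 0, 0), 2, 3, byrow = TRUE), c("C", "C"))
  expect_lt(abs(far$total - 2 * lone$total) / (2 * lone$total), 0.01)

  helix <- build_helix(12, backbone = "full")
  s1 <- sasa(helix, n_points = 480)$total
  s2 <- sasa(helix, n_points = 960)$total
  expect_lt(abs(s2 - s1) / s2, 0.005)
  expect_error(sasa(matrix(0, 1, 3), "XX"), class = "setphen_argument_error")
})

test_that("SASA and Rg are intrinsically rigid-motion invariant", {
  helix <- build_helix(10, backbone = "full")
  set.seed(6); R <- random_rotation()
  moved <- apply_rigid(helix, R, c(-4, 8, 2))
  # rotation invariance holds to the sphere-point discretization level
  expect_equal(sasa(moved)$total, sasa(helix)$total, tolerance = 5e-3)
  expect_equal(sasa(moved, n_points = 3840)$total,
               sasa(helix, n_points = 3840)$total, tolerance = 2e-3)
  expect_equal(radius_of_gyration(setphen:::structure_coords(moved)),
               radius_of_gyration(setphen:::structure_coords(helix)),
               tolerance = 1e-10)
})

test_that("hydrogen-bond occupancy counts window frames inside the distance band", {
  # two-atom topology, hand-built distances per frame
  atoms <- data.frame(res_index = c(1, 2), name = c("O", "N"),
                      element = c("O", "N"), x = 0, y = 0, z = 0, o = 1, b = 0)
  res <- data.frame(chain = "A", resno = 1:2, aa = c("S", "K"))
  topo <- setphen:::new_structure(res, atoms)
  mk_frames <- function(dists) {
    t(vapply(dists, function(d) c(0, 0, 0, d, 0, 0), numeric(6)))
  }
  pairs <- data.frame(label = "D1", from_atom = "1:O", to_atom = "2:N")

  all_in <- setphen:::new_trajectory(topo, mk_frames(rep(2.5, 8)))
  expect_equal(hbond_occupancy(all_in, pairs)$occupancy$occupancy, 1.0)

  all_out <- setphen:::new_trajectory(topo, mk_frames(rep(4.0, 8)))
  expect_equal(hbond_occupancy(all_out, pairs)$occupancy$occupancy, 0.0)

  # window = last 25% of 16 frames = 4 frames, two at 3.0 (in) two at 3.6 (out)
  d <- c(rep(2.5, 12), 3.0, 3.6, 3.0, 3.6)
  half <- setphen:::new_trajectory(topo, mk_frames(d))
  expect_equal(hbond_occupancy(half, pairs)$occupancy$occupancy, 0.5)
  # full-trajectory window counts everything
  expect_equal(hbond_occupancy(all_in, pairs, window = 1)$occupancy$occupancy, 1.0)
  expect_error(hbond_occupancy(all_in, data.frame(label = "x", from_atom = "9:ZZ",
                                                  to_atom = "2:N")),
               class = "setphen_argument_error")
})
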
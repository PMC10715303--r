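test_that("state free energy is E_MM + G_PB + G_SA - TS", {
  zero <- list(E_vdw = 0, E_ele = 0, E_bnd = 0, G_PB = 0, G_SA = 0, TS = 0)
  expect_equal(state_free_energy(zero), 0)
  row <- list(E_vdw = -10, E_ele = -20, E_bnd = 5, G_PB = 12, G_SA = -2, TS = 3)
  expect_equal(state_free_energy(row), -18)
  row$TS <- NULL
  expect_equal(state_free_energy(row), -15)   # omitted entropy treated as 0
  bad <- list(E_vdw = 1, E_ele = NA, E_bnd = 0, G_PB = 0, G_SA = 0, TS = 0)
  expect_error(state_free_energy(bad), "E_ele", class = "setphen_format_error")
})

test_that("binding series: additivity zero, single frame, frame alignment", {
  mk <- function(state, n, evdw) {
    data.frame(frame_ps = seq_len(n) * 10, state = state, E_vdw = evdw,
               E_ele = 1, E_bnd = 2, G_PB = 3, G_SA = 4, TS = 0)
  }
  # complex components exactly receptor + ligand per frame -> all zero
  tbl <- rbind(mk("complex", 5, 10 + 1 + 2 + 3 + 4 + 10),
               mk("receptor", 5, 10), mk("ligand", 5, 10))
  bs <- binding_series(tbl)
  expect_true(all(abs(bs$per_frame$dg_bind) < 1e-12))
  expect_equal(bs$n_frames, 5L)

  single <- rbind(mk("complex", 1, -40), mk("receptor", 1, 0), mk("ligand", 1, 0))
  b1 <- binding_series(single)
  expect_equal(b1$mean, b1$per_frame$dg_bind[1])
  expect_equal(b1$sd, 0)

  misaligned <- rbind(mk("complex", 5, 0), mk("receptor", 4, 0), mk("ligand", 5, 0))
  expect_error(binding_series(misaligned), "receptor", class = "setphen_format_error")
})

test_that("generator-truth binding energy is recovered within 3 standard errors", {
  for (seed in c(2, 17, 301)) {
    tbl <- gen_energy_table(dg_mean = -163.4, dg_sd = 2, n_frames = 150, seed = seed)
    bs <- binding_series(tbl)
    expect_equal(bs$n_frames, 150L)
    expect_lt(abs(bs$mean - (-163.4)), 3 * 2 / sqrt(150))
  }
  exact <- binding_series(gen_energy_table(dg_mean = -50, dg_sd = 0,
                                           n_frames = 10, seed = 1,
                                           component_sd = 0))
  expect_equal(exact$per_frame$dg_bind, rep(-50, 10), tolerance = 1e-10)
})

test_that("linearity and frame-order invariance of the aggregation", {
  tbl <- gen_energy_table(dg_mean = -80, dg_sd = 3, n_frames = 40, seed = 5)
  b <- binding_series(tbl)
  scaled <- tbl
  for (cc in setphen:::ENERGY_COMPONENTS) scaled[[cc]] <- 2.5 * scaled[[cc]]
  expect_equal(binding_series(scaled)$mean, 2.5 * b$mean, tolerance = 1e-10)
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(binding_series(shuffled)$mean, b$mean, tolerance = 1e-10)
})

test_that("variant-vs-reference differences carry the sign interpretation", {
  expect_equal(ddg_vs_reference(-163.4, -163.4)$interpretation, "unchanged")
  weaker <- ddg_vs_reference(-132.8, -163.4)
  expect_equal(weaker$ddg_bind, 30.6, tolerance = 1e-9)
  expect_equal(weaker$interpretation, "weaker")
  improved <- ddg_vs_reference(-193.1, -163.4)
  expect_equal(improved$ddg_bind, -29.7, tolerance = 1e-9)
  expect_equal(improved$interpretation, "improved")
})

test_that("pairwise nonbonded energies: Coulomb value, LJ minimum, dielectric scaling", {
  coords <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  params <- data.frame(q = c(2, -1), eps = c(0, 0), r_min = c(1, 1))
  e <- pair_interaction_energy(coords, 1, 2, params)
  expect_equal(e$E_ele, 332.0636 * 2 * (-1) / 5, tolerance = 1e-9)
  expect_equal(e$E_vdw, 0)

  # LJ pair at its minimum distance gives -eps_pair
  lj <- data.frame(q = c(0, 0), eps = c(0.2, 0.2), r_min = c(3.5, 3.5))
  at_min <- matrix(c(0, 0, 0, 3.5, 0, 0), 2, 3, byrow = TRUE)
  e2 <- pair_interaction_energy(at_min, 1, 2, lj)
  expect_equal(e2$E_vdw, -0.2, tolerance = 1e-9)
  expect_equal(e2$E_ele, 0)

  e4 <- pair_interaction_energy(coords, 1, 2, params, dielectric = 2)
  expect_equal(e4$E_ele, e$E_ele / 2, tolerance = 1e-12)
  # distance-dependent screening divides by an extra r
  edd <- pair_interaction_energy(coords, 1, 2, params, dielectric = 1,
                                 distance_dependent = TRUE)
  expect_equal(edd$E_ele, e$E_ele / 5, tolerance = 1e-12)

  expect_error(pair_interaction_energy(matrix(0, 2, 3), 1, 2, params),
               class = "setphen_argument_error")
  expect_error(pair_interaction_energy(coords, 1, 2, params[, 1:2]),
               class = "setphen_format_error")
})
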
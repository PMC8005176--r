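params <- gist_params()

test_that("pair energies reproduce hand calculations", {
  # neutral, LJ off: exactly zero at any distance
  expect_equal(pair_energy(c(0, 0, 0), c(1.3, 0, 0), 0, 0, params = params), 0)
  # unit charges at 1 A: the Coulomb constant itself
  expect_equal(pair_energy(c(0, 0, 0), c(1, 0, 0), 1, -1, params = params),
               -332.0636)
  expect_error(pair_energy(c(0, 0, 0), c(0, 0, 0), 1, 1, params = params),
               "zero distance")
  # a fixed TIP3P-like dimer: 9-pair hand-summed oracle
  Wa <- water_sites_at(c(0, 0, 0))
  Wb <- water_sites_at(c(2.9, 0.5, -0.3), rot_z(70))
  q <- c(-0.834, 0.417, 0.417)
  s <- c(3.15061, 0, 0)
  e <- c(0.1521, 0, 0)
  expected <- bf_water_pair(Wa, Wb, q, s, e)
  got <- 0
  for (a in 1:3) for (b in 1:3)
    got <- got + pair_energy(Wa[a, ], Wb[b, ], q[a], q[b], s[a], s[b],
                             e[a], e[b], params = params)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("pair energy is symmetric and linear in the charge product", {
  set.seed(31)
  for (rep in 1:20) {
    pa <- runif(3, -3, 3); pb <- runif(3, -3, 3)
    qa <- runif(1, -1, 1); qb <- runif(1, -1, 1)
    sa <- runif(1, 2, 4);  sb <- runif(1, 2, 4)
    ea <- runif(1, 0, .3); eb <- runif(1, 0, .3)
    e1 <- pair_energy(pa, pb, qa, qb, sa, sb, ea, eb, params = params)
    e2 <- pair_energy(pb, pa, qb, qa, sb, sa, eb, ea, params = params)
    expect_equal(e1, e2, tolerance = 1e-12)
    # LJ off: scaling q_a q_b scales the energy
    c1 <- pair_energy(pa, pb, qa, qb, params = params)
    c2 <- pair_energy(pa, pb, 2 * qa, 3 * qb, params = params)
    expect_equal(c2, 6 * c1, tolerance = 1e-12)
  }
})

test_that("energy accumulation matches the all-pairs oracle", {
  # apolar solute: delta_e_sw identically zero
  w1 <- water_sites_at(c(2.8, 0.4, 0.1))
  w2 <- water_sites_at(c(-1.5, 2.6, -0.7), rot_z(120))
  w3 <- water_sites_at(c(0.5, -3.0, 1.4), rot_z(240))
  waters <- list(list(w1, w2, w3),
                 list(water_sites_at(c(2.6, 0.6, -0.2), rot_z(30)),
                      water_sites_at(c(-1.8, 2.2, -0.4), rot_z(150)),
                      water_sites_at(c(0.9, -2.7, 1.2), rot_z(300))))
  traj0 <- fix_traj(waters)                       # solute charge/LJ zero
  b0 <- bin_waters(traj0, build_grid(c(0, 0, 0), 10, 0.5))
  b0 <- accumulate_energies(traj0, b0, params)
  expect_true(all(b0$grid$delta_e_sw == 0))

  # charged solute: per-voxel means equal the brute-force pair sums
  atoms <- fix_atoms(3, solute_charge = 0.5, solute_sigma = 3.4,
                     solute_epsilon = 0.1)
  traj <- fix_traj(waters, atoms = atoms)
  b <- bin_waters(traj, build_grid(c(0, 0, 0), 10, 0.5))
  b <- accumulate_energies(traj, b, params)
  q <- c(-0.834, 0.417, 0.417); s <- c(3.15061, 0, 0); e <- c(0.1521, 0, 0)
  for (r in seq_len(nrow(b$observations))) {
    ob <- b$observations[r, ]
    W <- waters[[ob$frame]]
    esw <- 0
    for (a in 1:3)
      esw <- esw + bf_pair(W[[ob$water]][a, ], c(0, 0, 0), q[a], 0.5,
                           s[a], 3.4, e[a], 0.1)
    eww <- 0
    for (v in seq_along(W)) if (v != ob$water)
      eww <- eww + bf_water_pair(W[[ob$water]], W[[v]], q, s, e)
    expect_equal(ob$e_sw, esw, tolerance = 1e-10)
    expect_equal(ob$e_ww, eww / 2, tolerance = 1e-10)
  }
  # voxel means: every water sits alone in its voxel here
  occ <- which(b$grid$counts > 0)
  for (v in occ) {
    rows <- b$observations$voxel == v
    expect_equal(b$grid$delta_e_sw[v], mean(b$observations$e_sw[rows]),
                 tolerance = 1e-12)
    expect_equal(b$grid$delta_e_ww[v],
                 mean(b$observations$e_ww[rows]) - params$eww_ref / 2,
                 tolerance = 1e-12)
  }
})

test_that("an isolated water carries only the bulk reference offset", {
  w <- list(water_sites_at(c(2.8, 0.4, 0.1)))
  traj <- fix_traj(rep(list(w), 3))
  b <- bin_waters(traj, build_grid(c(0, 0, 0), 10, 0.5))
  bh <- accumulate_energies(traj, b, gist_params(eww_ref_mode = "half"))
  v <- which(bh$grid$counts > 0)
  expect_equal(bh$grid$delta_e_ww[v], -(-9.533) / 2)
  bf <- accumulate_energies(traj, b, gist_params(eww_ref_mode = "full"))
  expect_equal(bf$grid$delta_e_ww[v], 9.533)
})

test_that("translational entropy follows the printed estimator exactly", {
  # two frames, one water, displaced by d inside one voxel: both
  # observations see the same cross-frame NN distance d
  d <- 0.21
  waters <- list(list(water_sites_at(c(3.05, 0.1, 0.1))),
                 list(water_sites_at(c(3.05 + d, 0.1, 0.1))))
  traj <- fix_traj(waters)
  b <- bin_waters(traj, build_grid(c(0, 0, 0), 12, 0.5))
  s <- trans_entropy(b$observations, b$observations, params, n_frames = 2)
  expected <- params$gas_constant *
    (params$euler_gamma + log(2 * params$rho0 * (4 * pi / 3) * d^3))
  expect_equal(s, expected, tolerance = 1e-12)
})

test_that("nearest-neighbour searches match brute force on small instances", {
  set.seed(33)
  n <- 100
  obs_xyz <- matrix(runif(3 * n, -5, 5), ncol = 3)
  frames <- sample(1:5, n, replace = TRUE)
  d_pkg <- gistwater:::nn_cross_frame(obs_xyz, frames, chunk = 17)
  expect_equal(d_pkg, bf_nn_cross(obs_xyz, frames), tolerance = 1e-12)
  box <- c(10, 10, 10)
  d_box <- gistwater:::nn_cross_frame(obs_xyz, frames, box = box, chunk = 23)
  expect_equal(d_box, bf_nn_cross(obs_xyz, frames, box = box),
               tolerance = 1e-12)
  # quaternion angular NN against all-pairs loop
  Q <- t(replicate(20, gistwater:::random_quaternion()))
  expect_equal(gistwater:::nn_quat_angles(Q), bf_nn_quat(Q),
               tolerance = 1e-10)
})

test_that("orientational entropy handles known rotations and degeneracy", {
  o <- c(3.1, 0.1, 0.1)
  w1 <- water_sites_at(o)
  w2 <- water_sites_at(o + c(0.1, 0, 0), rot_z(90))
  traj <- fix_traj(list(list(w1), list(w2)))
  b <- bin_waters(traj, build_grid(c(0, 0, 0), 12, 0.5))
  q1 <- b$observations[1, c("qw", "qx", "qy", "qz")]
  q2 <- b$observations[2, c("qw", "qx", "qy", "qz")]
  expect_equal(quat_angle(as.numeric(q1), as.numeric(q2)), pi / 2,
               tolerance = 1e-10)
  s <- orient_entropy(b$observations, params, n_frames = 2)
  expected <- params$gas_constant *
    (params$euler_gamma + log(2 * (pi / 2)^3 / (6 * pi)))
  expect_equal(as.numeric(s), expected, tolerance = 1e-10)
  # identical orientations: floored, flagged, strongly negative
  traj2 <- fix_traj(list(list(w1), list(water_sites_at(o + c(0.1, 0, 0)))))
  b2 <- bin_waters(traj2, build_grid(c(0, 0, 0), 12, 0.5))
  s2 <- orient_entropy(b2$observations, params, n_frames = 2)
  expect_equal(attr(s2, "n_floored"), 2)
  floor_expected <- params$gas_constant *
    (params$euler_gamma + log(2 * (1e-3)^3 / (6 * pi)))
  expect_equal(as.numeric(s2), floor_expected, tolerance = 1e-10)
  expect_lt(as.numeric(s2), -0.03)
  # single observation: undefined, zero with warning
  b3 <- bin_waters(fix_traj(list(list(w1))), build_grid(c(0, 0, 0), 12, 0.5))
  expect_warning(s3 <- orient_entropy(b3$observations, params, 1),
                 "fewer than two")
  expect_equal(as.numeric(s3), 0)
})

test_that("free energy assembly obeys the decomposition identity", {
  # hand-set one-voxel case: dE = -5, T dS = +1  =>  dA = -6
  g <- build_grid(c(0, 0, 0), 1, 1)
  g$n_frames <- 1L
  g$counts <- 1L
  g$delta_e_sw <- -3
  g$delta_e_ww <- -2
  g$s_trans <- 1 / (2 * 300)
  g$s_orient <- 1 / (2 * 300)
  out <- assemble_free_energy(list(grid = g), params)
  expect_equal(out$grid$delta_a, -6)
  # randomized grids: identity to 1e-10 and independent summation oracle
  set.seed(35)
  g2 <- build_grid(c(0, 0, 0), 2, 0.5)
  g2$n_frames <- 10L
  g2$counts <- rpois(g2$n_voxels, 2)
  g2$delta_e_sw <- rnorm(g2$n_voxels)
  g2$delta_e_ww <- rnorm(g2$n_voxels)
  g2$s_trans <- rnorm(g2$n_voxels, sd = 1e-3)
  g2$s_orient <- rnorm(g2$n_voxels, sd = 1e-3)
  out2 <- assemble_free_energy(list(grid = g2), params)
  ident <- out2$grid$delta_e_sw + out2$grid$delta_e_ww -
    300 * (out2$grid$s_trans + out2$grid$s_orient)
  expect_lt(max(abs(out2$grid$delta_a - ident)), 1e-10)
  oracle <- 0
  for (v in seq_len(g2$n_voxels))
    oracle <- oracle + out2$grid$delta_a[v] * g2$counts[v] / 10
  expect_equal(out2$delta_a_solv, oracle, tolerance = 1e-12)
})

test_that("radial distribution functions match brute-force binning", {
  # one water fixed at 2.5 A for 5 frames: step coordination number
  w <- list(water_sites_at(c(2.5, 0, 0)))
  traj <- fix_traj(rep(list(w), 5))
  rdf <- compute_rdf(traj, site = "O", bin_width = 0.1, r_max = 6)
  expect_equal(rdf$n_at_cutoff, 1)     # n(2.9) = 1
  expect_equal(max(rdf$table$n[rdf$table$r < 2.4]), 0)
  expect_equal(rdf$table$n[nrow(rdf$table)], 1)
  # randomized instance vs loop histogram (O and H sites)
  set.seed(36)
  waters <- lapply(1:3, function(f)
    lapply(1:15, function(w) water_sites_at(runif(3, -5, 5), rot_z(w * 17))))
  trj <- fix_traj(waters)
  for (site in c("O", "H")) {
    r <- compute_rdf(trj, site = site, bin_width = 0.25, r_max = 5)
    breaks <- seq(0, 5, 0.25)
    D <- c()
    for (f in 1:3) for (w in 1:15) {
      rows <- if (site == "O") 1 else 2:3
      for (a in rows)
        D <- c(D, sqrt(sum((waters[[f]][[w]][a, ] - c(0, 0, 0))^2)))
    }
    bf <- bf_rdf_counts(D, breaks)
    mult <- if (site == "O") 1 else 2
    shell <- 4 / 3 * pi * diff(breaks^3)
    expect_equal(r$table$g,
                 bf / (3 * 1 * shell * mult * water_model()$rho0),
                 tolerance = 1e-10)
    expect_equal(r$table$n, cumsum(bf) / 3, tolerance = 1e-10)
  }
  expect_error(compute_rdf(trj, solute_atoms = integer(0)), "empty")
})

test_that("bulk waters at reference density give a flat rdf", {
  spec <- synthetic_spec(hotspots = NULL, n_frames = 12, seed = 5)
  traj <- generate_trajectory(spec)
  rdf <- compute_rdf(traj, solute_atoms = 1, site = "O",
                     bin_width = 0.25, r_max = 5.5)
  sel <- rdf$table$r > 3.2 & rdf$table$r < 5.4
  # weighted mean of g over the window: ideal-gas value 1 within noise
  tb <- rdf$table[sel, ]
  expect_lt(abs(weighted.mean(tb$g, diff((seq(0, 5.5, .25))^3)[sel]) - 1),
            0.25)
})
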
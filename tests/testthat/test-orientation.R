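# Build an observation table row for a water with sites W (3x3: O,H1,H2).
obs_row <- function(W, frame = 1L, water = 1L) {
  q <- water_quaternion(W[1, ], W[2, ], W[3, ])
  data.frame(frame = frame, water = water,
             ox = W[1, 1], oy = W[1, 2], oz = W[1, 3],
             h1x = W[2, 1], h1y = W[2, 2], h1z = W[2, 3],
             h2x = W[3, 1], h2y = W[3, 2], h2z = W[3, 3],
             qw = q[1], qx = q[2], qy = q[3], qz = q[4])
}

test_that("proton binning applies the radial shell and conserves counts", {
  W <- water_sites_at(c(3, 0, 0), rot_z(35))
  obs <- do.call(rbind, lapply(1:10, function(f) obs_row(W, frame = f)))
  pg <- bin_protons(c(3, 0, 0), obs)
  expect_equal(pg$n_protons, 20)
  expect_equal(sort(pg$counts[pg$counts > 0]), c(10, 10))
  expect_equal(sum(pg$counts), pg$n_protons)    # conservation
  # oxygen displaced 2 A: every proton outside [0.8, 1.1] -> hard error
  expect_error(bin_protons(c(5, 0, 0), obs), "unresolvable")
})

test_that("noisy proton binning matches a brute-force loop", {
  set.seed(61)
  o <- c(0, 0, 0)
  obs <- do.call(rbind, lapply(1:40, function(f) {
    ax <- rnorm(3); ang <- rnorm(1, sd = 10 * pi / 180)
    K <- gistwater:::rotation_matrix(ax, ang)
    obs_row(water_sites_at(rnorm(3, sd = 0.15), K %*% rot_z(25)), frame = f)
  }))
  pg <- bin_protons(o, obs, fine_spacing = 0.1)
  P <- rbind(as.matrix(obs[, c("h1x", "h1y", "h1z")]),
             as.matrix(obs[, c("h2x", "h2y", "h2z")]))
  bf_counts <- integer(length(pg$counts))
  for (r in seq_len(nrow(P))) {
    d <- sqrt(sum((P[r, ] - o)^2))
    if (d < 0.8 || d > 1.1) next
    ijk <- floor((P[r, ] - pg$origin) / pg$spacing) + 1
    lin <- gistwater:::ijk2lin(matrix(as.integer(ijk), 1), pg$dims)
    bf_counts[lin] <- bf_counts[lin] + 1L
  }
  expect_equal(pg$counts, bf_counts)
})

test_that("the first proton lands on the most occupied fine voxel", {
  W <- water_sites_at(c(0, 0, 0))
  obs7 <- do.call(rbind, lapply(1:7, function(f) obs_row(W, frame = f)))
  # 3 frames of a slightly rotated pose: a 7-vs-3(+3) count split
  W2 <- water_sites_at(c(0, 0, 0), rot_z(40))
  obs3 <- do.call(rbind, lapply(8:10, function(f) obs_row(W2, frame = f)))
  pg <- bin_protons(c(0, 0, 0), rbind(obs7, obs3))
  h1 <- place_first_proton(pg)
  # one of the two 7-count voxels wins (lexicographic tie-break); its
  # centroid is the corresponding noiseless proton position
  expect_lt(min(sqrt(sum((h1 - W[2, ])^2)), sqrt(sum((h1 - W[3, ])^2))),
            1e-10)
  # argmax equals brute-force scan on random grids
  set.seed(62)
  for (rep in 1:5) {
    obs <- do.call(rbind, lapply(1:30, function(f)
      obs_row(water_sites_at(rnorm(3, sd = 0.1),
                             rot_z(runif(1, 0, 360))), frame = f)))
    pgr <- bin_protons(c(0, 0, 0), obs)
    v <- which(pgr$counts == max(pgr$counts))[1]
    expect_equal(place_first_proton(pgr),
                 pgr$pos_sum[v, ] / pgr$counts[v], tolerance = 1e-12)
  }
})

test_that("the second proton obeys the angular window", {
  model <- water_model()
  # clean pose: second proton recovered exactly, angle 104.5 deg
  W <- water_sites_at(c(0, 0, 0), rot_z(10))
  obs <- do.call(rbind, lapply(1:10, function(f) obs_row(W, frame = f)))
  pg <- bin_protons(c(0, 0, 0), obs)
  h1 <- place_first_proton(pg)
  h2 <- place_second_proton(pg, c(0, 0, 0), h1, model)
  expect_false(attr(h2, "fallback"))
  got <- rbind(h1, c(h2))
  want <- W[2:3, ]
  err <- min(max(abs(got - want)), max(abs(got - want[2:1, ])))
  expect_lt(err, 1e-10)
  expect_equal(vertex_angle(h1, c(0, 0, 0), h2), 104.5, tolerance = 1e-8)

  # all occupancy at 60 degrees from H1: outside the window -> fallback
  a60 <- 60 * pi / 180
  Wbad <- rbind(c(0, 0, 0),
                0.9572 * c(1, 0, 0),
                0.9572 * c(cos(a60), sin(a60), 0))
  obs2 <- do.call(rbind, lapply(1:10, function(f) obs_row(Wbad, frame = f)))
  pg2 <- bin_protons(c(0, 0, 0), obs2)
  h1b <- place_first_proton(pg2)
  expect_warning(h2b <- place_second_proton(pg2, c(0, 0, 0), h1b, model),
                 "fallback")
  expect_true(attr(h2b, "fallback"))
  expect_equal(vertex_angle(h1b, c(0, 0, 0), h2b), 104.5, tolerance = 1e-6)

  # two in-window peaks with counts 9 vs 4: the stronger peak wins, and the
  # choice equals a brute-force scan with the angle filter
  aa <- 104.5 * pi / 180
  ac <- 101 * pi / 180
  p0 <- 0.9572 * c(1, 0, 0)
  Wa <- rbind(c(0, 0, 0), p0, 0.9572 * c(cos(aa), sin(aa), 0))
  Wc <- rbind(c(0, 0, 0), p0, 0.9572 * c(cos(ac), -sin(ac), 0))
  obs3 <- rbind(do.call(rbind, lapply(1:9, function(f) obs_row(Wa, f))),
                do.call(rbind, lapply(10:13, function(f) obs_row(Wc, f))))
  pg3 <- bin_protons(c(0, 0, 0), obs3)
  h1c <- place_first_proton(pg3)
  h2c <- place_second_proton(pg3, c(0, 0, 0), h1c, model)
  occ <- which(pg3$counts > 0)
  best <- 0; best_ct <- -1
  for (v in occ) {
    ctr <- pg3$pos_sum[v, ] / pg3$counts[v]
    a <- vertex_angle(h1c, c(0, 0, 0), ctr)
    if (abs(a - 104.5) < 5 && pg3$counts[v] > best_ct) {
      best <- v; best_ct <- pg3$counts[v]
    }
  }
  expect_equal(c(h2c), pg3$pos_sum[best, ] / pg3$counts[best],
               tolerance = 1e-12)
  expect_equal(best_ct, 9)
})

test_that("non-fallback waters always satisfy the angle window", {
  set.seed(63)
  model <- water_model()
  for (rep in 1:20) {
    obs <- do.call(rbind, lapply(1:25, function(f) {
      ax <- rnorm(3); ang <- rnorm(1, sd = 12 * pi / 180)
      K <- gistwater:::rotation_matrix(ax, ang)
      obs_row(water_sites_at(rnorm(3, sd = 0.12),
                             K %*% rot_z(runif(1, 0, 360))), frame = f)
    }))
    pg <- bin_protons(c(0, 0, 0), obs)
    h1 <- place_first_proton(pg)
    h2 <- suppressWarnings(place_second_proton(pg, c(0, 0, 0), h1, model))
    if (!attr(h2, "fallback"))
      expect_lt(abs(vertex_angle(h1, c(0, 0, 0), h2) - 104.5), 5)
  }
})

test_that("a single dominant orientation is recovered within resolution", {
  # angular noise only (no positional spread): both O->H directions within
  # 2*(fine spacing / bond length) + sigma/sqrt(N) radians of truth
  # hotspot centred on a voxel centre so the placed oxygen coincides with
  # the true site and only the proton resolution limits the recovery
  spec <- synthetic_spec(
    hotspots = data.frame(x = 2.75, y = 1.25, z = 0.25, sigma = 0, p = 1,
                          qw = 1, qx = 0, qy = 0, qz = 0,
                          angular_sigma = 8),
    bulk_density = 0, n_frames = 100, seed = 8)
  traj <- generate_trajectory(spec)
  g <- gist_analysis(traj, gw_config(), thermo = FALSE,
                     grid = build_grid(c(0, 0, 0), 12, 0.5))
  alloc <- allocate_oxygens(g$grid)
  placed <- suppressMessages(orient_waters(alloc, g$observations))
  expect_false(placed$fallback[1])
  o <- c(placed$ox[1], placed$oy[1], placed$oz[1])
  body <- rbind(water_sites_at(c(0, 0, 0))[2, ],
                water_sites_at(c(0, 0, 0))[3, ])
  got <- rbind(c(placed$h1x[1], placed$h1y[1], placed$h1z[1]) - o,
               c(placed$h2x[1], placed$h2y[1], placed$h2z[1]) - o)
  ang <- function(u, v) acos(min(1, max(-1, sum(u * v) /
                                          sqrt(sum(u^2) * sum(v^2)))))
  errs <- c(max(ang(got[1, ], body[1, ]), ang(got[2, ], body[2, ])),
            max(ang(got[1, ], body[2, ]), ang(got[2, ], body[1, ])))
  tol <- 2 * (0.1 / 0.9572) + (8 * pi / 180) / sqrt(100)
  expect_lt(min(errs), tol)
})
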
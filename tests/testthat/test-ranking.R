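mk_placed <- function(delta_a, opos, h_offset = c(0.6, 0.6, 0)) {
  n <- length(delta_a)
  data.frame(id = seq_len(n),
             ox = opos[, 1], oy = opos[, 2], oz = opos[, 3],
             h1x = opos[, 1] + h_offset[1], h1y = opos[, 2], h1z = opos[, 3],
             h2x = opos[, 1] - h_offset[1], h2y = opos[, 2] + h_offset[2],
             h2z = opos[, 3],
             fallback = FALSE, delta_a = delta_a)
}

test_that("distance classification uses the nearest solute atom", {
  solute <- rbind(c(0, 0, 0), c(2, 0, 0))
  c1 <- classify_distance(c(4.5, 0, 0), solute)   # 2.5 from second atom
  expect_equal(as.character(c1), "near")
  expect_equal(attr(c1, "distance"), 2.5)
  expect_equal(as.character(classify_distance(c(5, 0, 0), solute)), "mid")
  expect_equal(as.character(classify_distance(c(8, 0, 0), solute)), "bulk")
  # boundaries go outward
  expect_equal(as.character(classify_distance(c(3, 0, 0), rbind(c(0, 0, 0)))),
               "mid")
  expect_equal(as.character(classify_distance(c(6, 0, 0), rbind(c(0, 0, 0)))),
               "bulk")
  set.seed(71)
  for (rep in 1:20) {
    sol <- matrix(runif(9, -3, 3), 3)
    p <- runif(3, -6, 6)
    expect_equal(attr(classify_distance(p, sol), "distance"),
                 bf_min_dist(p, sol), tolerance = 1e-12)
  }
})

test_that("waters are ranked ascending by free energy with distance ties", {
  opos <- rbind(c(8, 0, 0), c(2.1, 0, 0), c(4, 0, 0))
  placed <- mk_placed(c(-9.1, -12.2, -10.5), opos)
  rk <- rank_waters(placed, rbind(c(0, 0, 0)))
  expect_equal(rk$waters$delta_a, c(-12.2, -10.5, -9.1))
  expect_equal(rk$waters$rank, 1:3)
  # equal free energies: nearer water first
  placed2 <- mk_placed(c(-5, -5), rbind(c(4, 0, 0), c(2.1, 0, 0)))
  rk2 <- rank_waters(placed2, rbind(c(0, 0, 0)))
  expect_equal(rk2$waters$distance, c(2.1, 4))
  # random lists: sorted order matches R's reference sort
  set.seed(72)
  for (rep in 1:10) {
    n <- 15
    da <- round(rnorm(n), 1)
    op <- matrix(runif(3 * n, -7, 7), ncol = 3)
    rkr <- rank_waters(mk_placed(da, op), rbind(c(0, 0, 0)))
    expect_false(is.unsorted(rkr$waters$delta_a))
    expect_equal(sort(rkr$waters$delta_a), sort(da))
  }
})

test_that("chart export round-trips and classes partition the set", {
  set.seed(73)
  n <- 12
  op <- matrix(runif(3 * n, -7, 7), ncol = 3)
  rk <- rank_waters(mk_placed(rnorm(n), op), rbind(c(0, 0, 0)))
  csv <- withr::local_tempfile(fileext = ".csv")
  export_chart(rk, csv)
  tab <- read.csv(csv)
  expect_equal(tab$rank, rk$waters$rank)
  expect_equal(tab$delta_a, rk$waters$delta_a)
  expect_equal(tab$class, rk$waters$class)
  expect_setequal(unique(tab$color), unname(c(near = "orange", mid = "blue",
                                              bulk = "red")[unique(tab$class)]))
  counts <- table(factor(rk$waters$class, c("near", "mid", "bulk")))
  expect_equal(sum(counts), n)
})

test_that("cluster selection writes consistent solute-water PDB files", {
  traj <- fix_traj(list(list(water_sites_at(c(3, 0, 0)))))
  set.seed(74)
  n <- 6
  op <- matrix(runif(3 * n, -5, 5), ncol = 3)
  rk <- rank_waters(mk_placed(sort(rnorm(n)), op), rbind(c(0, 0, 0)))
  pdb0 <- withr::local_tempfile(fileext = ".pdb")
  select_and_write_cluster(rk, traj, pdb0, n = 0)
  p0 <- bio3d::read.pdb(pdb0, verbose = FALSE)
  expect_equal(nrow(p0$atom), 1)                  # solute only
  pdb1 <- withr::local_tempfile(fileext = ".pdb")
  select_and_write_cluster(rk, traj, pdb1, n = 1)
  p1 <- bio3d::read.pdb(pdb1, verbose = FALSE)
  expect_equal(nrow(p1$atom), 4)
  expect_equal(p1$atom$resid[2:4], rep("HOH", 3))
  pdb6 <- withr::local_tempfile(fileext = ".pdb")
  select_and_write_cluster(rk, traj, pdb6, n = 6)
  p6 <- bio3d::read.pdb(pdb6, verbose = FALSE)
  # coordinates in the cluster match the ranked table to PDB precision
  ow <- matrix(p6$xyz, ncol = 3, byrow = TRUE)[1 + 3 * (seq_len(6) - 1) + 1, ]
  expect_lt(max(abs(ow - as.matrix(rk$waters[, c("ox", "oy", "oz")]))),
            1e-3 + 1e-12)
  expect_error(select_and_write_cluster(rk, traj, tempfile(), n = 7),
               "out of range")
  # criteria form: free-energy ceiling plus class filter
  pdbc <- withr::local_tempfile(fileext = ".pdb")
  out <- select_and_write_cluster(rk, traj, pdbc,
                                  delta_a_max = rk$waters$delta_a[3])
  expect_equal(attr(out, "n_waters"), 3L)
})
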
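# Independent brute-force oracles.  These deliberately use plain double
# loops and no package internals beyond exported constructors, so they
# stay independent of the code paths they check.

# Cross-frame nearest-neighbour distances, all-pairs.
bf_nn_cross <- function(oxyz, frames, box = NULL) {
  n <- nrow(oxyz)
  out <- rep(Inf, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (frames[a] == frames[b]) next
      d <- oxyz[a, ] - oxyz[b, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      out[a] <- min(out[a], sqrt(sum(d^2)))
    }
  }
  out
}

# Nearest quaternion angular distance, all-pairs.
bf_nn_quat <- function(Q) {
  n <- nrow(Q)
  out <- rep(Inf, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    out[a] <- min(out[a], 2 * acos(min(1, abs(sum(Q[a, ] * Q[b, ])))))
  }
  out
}

# Coulomb + LJ pair energy, scalar.
bf_pair <- function(pa, pb, qa, qb, sa = 0, sb = 0, ea = 0, eb = 0,
                    box = NULL) {
  d <- pa - pb
  if (!is.null(box)) d <- d - box * round(d / box)
  r <- sqrt(sum(d^2))
  e <- 332.0636 * qa * qb / r
  eps <- sqrt(ea * eb)
  if (eps > 0) {
    sr6 <- (((sa + sb) / 2) / r)^6
    e <- e + 4 * eps * (sr6^2 - sr6)
  }
  e
}

# Total interaction energy between two rigid waters: 9 site pairs.
bf_water_pair <- function(Wa, Wb, q, s, e, box = NULL) {
  tot <- 0
  for (a in 1:3) for (b in 1:3)
    tot <- tot + bf_pair(Wa[a, ], Wb[b, ], q[a], q[b], s[a], s[b],
                         e[a], e[b], box = box)
  tot
}

# Literal greedy density-allocation loop on a counts vector over a grid of
# dims; independent neighbour ordering by brute-force full-grid sort.
bf_greedy_alloc <- function(counts, dims, quantum, target = 0.95) {
  lin2ijk0 <- function(v) {
    v0 <- v - 1L
    c(v0 %/% (dims[3] * dims[2]) + 1L,
      (v0 %/% dims[3]) %% dims[2] + 1L,
      v0 %% dims[3] + 1L)
  }
  all_ijk <- t(vapply(seq_along(counts), lin2ijk0, integer(3)))
  residual <- counts
  total <- sum(counts)
  allocated <- 0
  placements <- list()
  while (total > 0 && allocated / total < target && sum(residual) > 0) {
    m <- max(residual)
    v <- which(residual == m)[1]
    ctr <- all_ijk[v, ]
    d2 <- (all_ijk[, 1] - ctr[1])^2 + (all_ijk[, 2] - ctr[2])^2 +
      (all_ijk[, 3] - ctr[3])^2
    ord <- order(d2, all_ijk[, 1], all_ijk[, 2], all_ijk[, 3])
    need <- quantum
    draws <- list()
    for (u in ord) {
      if (need <= 0) break
      if (residual[u] <= 0) next
      take <- min(residual[u], need)
      residual[u] <- residual[u] - take
      need <- need - take
      draws[[length(draws) + 1]] <- c(u, take)
    }
    allocated <- allocated + (quantum - need)
    placements[[length(placements) + 1]] <-
      list(voxel = v, draws = do.call(rbind, draws))
  }
  list(placements = placements, residual = residual, allocated = allocated)
}

# Histogram of solute-site distances, loop version (bins (lo, hi]).
bf_rdf_counts <- function(D, breaks) {
  counts <- numeric(length(breaks) - 1)
  for (d in D) {
    for (b in seq_len(length(counts))) {
      if (d > breaks[b] && d <= breaks[b + 1]) {
        counts[b] <- counts[b] + 1
        break
      }
    }
  }
  counts
}

# Minimum solute distance, loop version.
bf_min_dist <- function(p, solute) {
  best <- Inf
  for (a in seq_len(nrow(solute)))
    best <- min(best, sqrt(sum((p - solute[a, ])^2)))
  best
}
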
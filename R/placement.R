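#' Greedy allocation of water oxygens from the density grid
#'
#' Implements the density-allocation loop: repeatedly take the voxel with
#' the highest residual occupancy count (ties broken lexicographically by
#' voxel index), place a water oxygen at that voxel's centre, and draw one
#' water's worth of counts -- the occupancy quantum, `N_f` counts, i.e. a
#' water present every frame -- first from that voxel, then from its
#' neighbours in order of increasing centre-to-centre distance (shells
#' grown as needed).  The loop stops once the allocated fraction of the
#' total initial in-grid counts reaches `target_fraction` (default 0.95)
#' or no residual counts remain.
#'
#' @param grid a grid with populated occupancy counts ([bin_waters()]).
#' @param n_frames number of trajectory frames (the occupancy quantum); by
#'   default taken from the grid.
#' @param target_fraction stop once this fraction of the total counts is
#'   allocated; must lie in (0, 1].
#' @return Object of class `gw_allocation`: `placed` (data.frame with one
#'   row per placed oxygen: `id`, `ox oy oz` voxel-centre position,
#'   `i j k`, `voxel`, `counts_drawn`, `primary_count` residual count of
#'   the primary voxel at selection time), `contributions` (list, per
#'   placement, of data.frame `voxel`, `i j k`, `count`), `residual`
#'   (per-voxel leftover counts), `total_initial`, `allocated`,
#'   `allocation_fraction`, `quantum`.
#' @export
allocate_oxygens <- function(grid, n_frames = grid$n_frames,
                             target_fraction = 0.95) {
  stopifnot(inherits(grid, "gw_grid"))
  if (is.null(n_frames)) stop("number of frames unknown; bin waters first")
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]")
  residual <- as.numeric(grid$counts)
  total <- sum(residual)
  quantum <- n_frames
  placed <- list()
  contribs <- list()
  allocated <- 0
  # Offsets sorted once by (distance^2, di, dj, dk); for a fixed centre
  # this equals sorting the absolute neighbours by distance with
  # lexicographic (i, j, k) tie-break, i.e. the voxel_neighbors() order
  # with shells grown as far as ever needed.
  off <- sorted_offsets(grid$dims)
  remaining <- total
  while (total > 0 && allocated / total < target_fraction &&
           remaining > 0) {
    m <- max(residual)
    v <- which.max(residual)           # linear order IS lexicographic (i,j,k)
    ijk <- lin2ijk(v, grid$dims)[1, ]
    need <- quantum
    take <- min(residual[v], need)
    draw_v <- v
    draw_n <- take
    residual[v] <- residual[v] - take
    remaining <- remaining - take
    need <- need - take
    if (need > 0 && remaining > 0) {
      block <- 4096L
      r0 <- 1L
      while (need > 0 && remaining > 0 && r0 <= nrow(off)) {
        rows <- r0:min(r0 + block - 1L, nrow(off))
        r0 <- r0 + block
        nb <- sweep(off[rows, , drop = FALSE], 2, ijk, "+")
        ok <- nb[, 1] >= 1L & nb[, 1] <= grid$dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= grid$dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= grid$dims[3]
        if (!any(ok)) next
        u <- ijk2lin(nb[ok, , drop = FALSE], grid$dims)
        res <- residual[u]
        pos <- which(res > 0)
        if (length(pos) == 0) next
        cum <- cumsum(res[pos])
        n_take <- findInterval(need - 1e-9, cum) + 1L
        n_take <- min(n_take, length(pos))
        sel <- pos[seq_len(n_take)]
        takes <- res[sel]
        over <- sum(takes) - need
        if (over > 0) takes[n_take] <- takes[n_take] - over
        residual[u[sel]] <- residual[u[sel]] - takes
        remaining <- remaining - sum(takes)
        need <- need - sum(takes)
        draw_v <- c(draw_v, u[sel])
        draw_n <- c(draw_n, takes)
      }
    }
    drawn <- quantum - need
    allocated <- allocated + drawn
    ctr <- voxel_center(v, grid)[1, ]
    placed[[length(placed) + 1L]] <- data.frame(
      id = length(placed) + 1L, ox = ctr[1], oy = ctr[2], oz = ctr[3],
      i = ijk[1], j = ijk[2], k = ijk[3], voxel = v,
      counts_drawn = drawn, primary_count = m)
    cijk <- lin2ijk(draw_v, grid$dims)
    contribs[[length(contribs) + 1L]] <- data.frame(
      voxel = draw_v, i = cijk[, 1], j = cijk[, 2], k = cijk[, 3],
      count = draw_n)
  }
  placed_df <- if (length(placed) > 0) do.call(rbind, placed) else
    data.frame(id = integer(), ox = numeric(), oy = numeric(),
               oz = numeric(), i = integer(), j = integer(), k = integer(),
               voxel = integer(), counts_drawn = numeric(),
               primary_count = numeric())
  structure(list(placed = placed_df, contributions = contribs,
                 residual = residual, total_initial = total,
                 allocated = allocated,
                 allocation_fraction = if (total > 0) allocated / total else 0,
                 quantum = quantum),
            class = "gw_allocation")
}

#' @export
print.gw_allocation <- function(x, ...) {
  cat(sprintf("gw_allocation: %d waters placed, %.1f%% of %g counts allocated\n",
              nrow(x$placed), 100 * x$allocation_fraction, x$total_initial))
  invisible(x)
}

# Neighbour offsets (excluding 0,0,0) covering the whole grid, sorted by
# squared distance then (di, dj, dk); memoised per grid dimension.
offset_cache <- new.env(parent = emptyenv())
sorted_offsets <- function(dims) {
  key <- paste(dims, collapse = "x")
  if (!is.null(offset_cache[[key]])) return(offset_cache[[key]])
  rng <- lapply(dims, function(n) -(n - 1L):(n - 1L))
  g <- as.matrix(expand.grid(di = rng[[1]], dj = rng[[2]], dk = rng[[3]]))
  g <- g[rowSums(g == 0L) < 3L, , drop = FALSE]
  d2 <- rowSums(g^2)
  g <- g[order(d2, g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  storage.mode(g) <- "integer"
  offset_cache[[key]] <- g
  g
}

#' Density-weighted solvation free energy of a placed water
#'
#' The free energy assigned to a placed water is the weighted sum of the
#' per-voxel `delta_a` of its contributing voxels, each weighted by the
#' fraction of the occupancy quantum drawn from it.  A placement fully
#' satisfied from one voxel therefore inherits that voxel's `delta_a`
#' exactly.
#'
#' @param contribution one element of `gw_allocation$contributions`.
#' @param grid a grid carrying `delta_a` ([assemble_free_energy()]).
#' @param quantum the occupancy quantum (counts per placed water).
#' @return free energy in kcal/mol.
#' @export
assign_delta_a <- function(contribution, grid, quantum) {
  if (is.null(grid$delta_a))
    stop("grid lacks delta_a; run the thermodynamic analysis first")
  da <- grid$delta_a[contribution$voxel]
  if (any(is.na(da)))
    stop("contributing voxel lacks thermodynamics")
  sum(contribution$count / quantum * da)
}

# Map allocation draws back to concrete water observations: per voxel the
# observations are ordered by (frame, water) and consumed in placement
# order, so each placement knows exactly which (water, frame) pairs it
# represents.  Returns a list of integer vectors of observation rows.
allocation_observations <- function(alloc, observations) {
  by_vox <- split(seq_len(nrow(observations)),
                  observations$voxel)
  by_vox <- lapply(by_vox, function(rows)
    rows[order(observations$frame[rows], observations$water[rows])])
  used <- new.env(parent = emptyenv())
  for (v in names(by_vox)) assign(v, 0L, envir = used)
  lapply(alloc$contributions, function(ct) {
    unlist(lapply(seq_len(nrow(ct)), function(r) {
      v <- as.character(ct$voxel[r])
      rows <- by_vox[[v]]
      if (is.null(rows)) return(integer(0))
      k0 <- get(v, envir = used)
      take <- min(ct$count[r], length(rows) - k0)
      if (take <= 0) return(integer(0))
      assign(v, k0 + take, envir = used)
      rows[(k0 + 1L):(k0 + take)]
    }), use.names = FALSE)
  })
}
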
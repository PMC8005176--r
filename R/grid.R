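#' Build the cubic GIST analysis grid
#'
#' Voxels are half-open boxes `[origin + (i-1)*spacing, origin + i*spacing)`
#' per axis, so binning is a partition of the grid volume.  The standard
#' analysis setting is a 30 x 30 x 30 Angstrom cube at 0.5 Angstrom spacing
#' (60^3 voxels) centred on the restrained solute.
#'
#' @param center grid centre, xyz in Angstrom.
#' @param edge cube edge length in Angstrom (scalar or length-3).
#' @param spacing voxel edge in Angstrom (default 0.5).
#' @return Object of class `gw_grid`: `origin`, `spacing`, `dims` (voxels
#'   per axis), `n_voxels`, and a per-voxel integer `counts` accumulator
#'   (zeroed) in lexicographic (i, j, k) linear order.
#' @examples
#' g <- build_grid(c(0, 0, 0), edge = 30, spacing = 0.5)
#' g$dims  # 60 60 60
#' @export
build_grid <- function(center, edge, spacing = 0.5) {
  stopifnot(length(center) == 3, all(edge > 0), spacing > 0)
  if (any(edge < spacing)) stop("grid edge must be at least one spacing")
  edge <- rep_len(as.numeric(edge), 3)
  dims <- as.integer(round(edge / spacing))
  origin <- as.numeric(center) - dims * spacing / 2
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 n_voxels = prod(dims),
                 counts = integer(prod(dims))),
            class = "gw_grid")
}

#' @export
print.gw_grid <- function(x, ...) {
  cat(sprintf("gw_grid: %d x %d x %d voxels, spacing %.3g A, origin (%s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              paste(sprintf("%.2f", x$origin), collapse = ", ")))
  if (sum(x$counts) > 0)
    cat(sprintf("  %d water observations binned\n", sum(x$counts)))
  invisible(x)
}

# Linear voxel index in lexicographic (i, j, k) order, 1-based: ascending
# linear index sorts by i, then j, then k, which is also the tie-break
# order used throughout.
ijk2lin <- function(ijk, dims) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  ((ijk[, 1] - 1L) * dims[2] + (ijk[, 2] - 1L)) * dims[3] + ijk[, 3]
}

lin2ijk <- function(lin, dims) {
  lin0 <- as.integer(lin) - 1L
  k <- lin0 %% dims[3]
  j <- (lin0 %/% dims[3]) %% dims[2]
  i <- lin0 %/% (dims[3] * dims[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

# Voxel centres for linear indices: matrix n x 3.
voxel_center <- function(lin, grid) {
  ijk <- lin2ijk(lin, grid$dims)
  sweep((ijk - 0.5) * grid$spacing, 2, grid$origin, "+")
}

# Map positions (n x 3) to voxel ijk; returns NA rows for out-of-grid.
pos2ijk <- function(pos, grid) {
  pos <- matrix(pos, ncol = 3)
  rel <- sweep(pos, 2, grid$origin, "-") / grid$spacing
  ijk <- floor(rel) + 1
  ok <- ijk >= 1 & ijk <= matrix(grid$dims, nrow(ijk), 3, byrow = TRUE)
  ijk[!(ok[, 1] & ok[, 2] & ok[, 3]), ] <- NA_integer_
  storage.mode(ijk) <- "integer"
  ijk
}

#' Neighbouring voxels in growing shells
#'
#' All voxels with Chebyshev distance up to `shell` from `index` (the
#' centre itself excluded), clipped to the grid, sorted by Euclidean
#' centre-to-centre distance ascending with ties broken lexicographically
#' by (i, j, k).  This is the order in which the placement algorithm draws
#' density from around a placed water.
#'
#' @param index voxel index triple (1-based).
#' @param grid a [build_grid()] object.
#' @param shell maximum Chebyshev distance in voxels (>= 1).
#' @return integer matrix with columns `i`, `j`, `k`, one row per neighbour.
#' @export
voxel_neighbors <- function(index, grid, shell = 1L) {
  stopifnot(shell >= 1)
  index <- as.integer(index)
  if (any(index < 1) || any(index > grid$dims))
    stop("voxel index out of grid bounds")
  off <- -shell:shell
  g <- as.matrix(expand.grid(di = off, dj = off, dk = off))
  g <- g[rowSums(g == 0) < 3, , drop = FALSE]
  nb <- sweep(g, 2, index, "+")
  ok <- nb[, 1] >= 1 & nb[, 1] <= grid$dims[1] &
    nb[, 2] >= 1 & nb[, 2] <= grid$dims[2] &
    nb[, 3] >= 1 & nb[, 3] <= grid$dims[3]
  nb <- nb[ok, , drop = FALSE]
  d2 <- rowSums(sweep(nb, 2, index, "-")^2)
  ord <- order(d2, nb[, 1], nb[, 2], nb[, 3])
  nb <- nb[ord, , drop = FALSE]
  colnames(nb) <- c("i", "j", "k")
  storage.mode(nb) <- "integer"
  nb
}

#' Bin water observations into the grid
#'
#' Every water whose oxygen lies inside the grid contributes one
#' observation per frame; its voxel occupancy count is incremented and the
#' observation (positions, voxel, orientation quaternion) recorded.  Waters
#' outside the grid are skipped.  A water belongs to the voxel containing
#' its oxygen.
#'
#' @param traj a [gw_trajectory()].
#' @param grid a [build_grid()] object.
#' @return List with `grid` (counts updated; `n_frames` attached) and
#'   `observations`, a data.frame with one row per in-grid (water, frame)
#'   pair: `frame`, `water` (row in the topology water table), `ox oy oz`,
#'   `h1x ...`, `h2x ...`, `i j k`, `voxel` (linear index), `qw qx qy qz`.
#' @export
bin_waters <- function(traj, grid) {
  stopifnot(inherits(traj, "gw_trajectory"), inherits(grid, "gw_grid"))
  w <- traj$topology$water_residues
  if (is.null(w) || nrow(w) == 0) {
    grid$n_frames <- traj$n_frames
    return(list(grid = grid, observations = empty_observations()))
  }
  nw <- nrow(w)
  obs_list <- vector("list", traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    o <- matrix(traj$coords[w[, "o"], , f], ncol = 3)
    h1 <- matrix(traj$coords[w[, "h1"], , f], ncol = 3)
    h2 <- matrix(traj$coords[w[, "h2"], , f], ncol = 3)
    ijk <- pos2ijk(o, grid)
    ok <- !is.na(ijk[, 1])
    if (!any(ok)) next
    idx <- which(ok)
    q <- t(vapply(idx, function(m)
      water_quaternion(o[m, ], h1[m, ], h2[m, ]), numeric(4)))
    obs_list[[f]] <- data.frame(
      frame = f, water = idx,
      ox = o[idx, 1], oy = o[idx, 2], oz = o[idx, 3],
      h1x = h1[idx, 1], h1y = h1[idx, 2], h1z = h1[idx, 3],
      h2x = h2[idx, 1], h2y = h2[idx, 2], h2z = h2[idx, 3],
      i = ijk[idx, 1], j = ijk[idx, 2], k = ijk[idx, 3],
      voxel = ijk2lin(ijk[idx, , drop = FALSE], grid$dims),
      qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4])
  }
  obs <- do.call(rbind, obs_list)
  if (is.null(obs)) obs <- empty_observations()
  tab <- tabulate(obs$voxel, nbins = grid$n_voxels)
  grid$counts <- grid$counts + as.integer(tab)
  grid$n_frames <- traj$n_frames
  list(grid = grid, observations = obs)
}

empty_observations <- function() {
  data.frame(frame = integer(), water = integer(),
             ox = numeric(), oy = numeric(), oz = numeric(),
             h1x = numeric(), h1y = numeric(), h1z = numeric(),
             h2x = numeric(), h2y = numeric(), h2z = numeric(),
             i = integer(), j = integer(), k = integer(),
             voxel = integer(),
             qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric())
}

#' Export a per-voxel scalar field as an OpenDX grid file
#'
#' Writes the plain-text OpenDX format understood by PyMOL, VMD and
#' gridDataFormats: origin, three delta vectors, and the field values in
#' x-fastest-last (lexicographic i, j, k) order, which is the package's
#' native voxel ordering.
#'
#' @param grid a [build_grid()] object.
#' @param field numeric vector of length `grid$n_voxels` (e.g. counts or a
#'   thermodynamic field), in the grid's linear order.
#' @param path output path.
#' @param name dataset name written into the file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, field, path, name = "gistwater field") {
  stopifnot(length(field) == grid$n_voxels)
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  # OpenDX voxel positions are cell centres.
  co <- grid$origin + grid$spacing / 2
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", co[1], co[2], co[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf(paste0("object 3 class array type double rank 0 items %d ",
                   "data follows"), grid$n_voxels)), con)
  vals <- sprintf("%.6g", field)
  pad <- (3 - length(vals) %% 3) %% 3
  if (pad > 0) vals <- c(vals, rep("", pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  writeLines(trimws(paste(m[, 1], m[, 2], m[, 3])), con)
  writeLines(sprintf('attribute "dep" string "positions"\nobject "%s" class field',
                     name), con)
  invisible(path)
}

#' Export all per-voxel fields as a tidy CSV
#'
#' One row per voxel with its indices, centre coordinates, occupancy and
#' any computed thermodynamic fields.
#'
#' @param grid a grid that has been through [bin_waters()] (and optionally
#'   [gist_analysis()]).
#' @param path output CSV path.
#' @param keep_empty write rows for voxels with zero occupancy (default
#'   `FALSE`).
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path, keep_empty = FALSE) {
  lin <- seq_len(grid$n_voxels)
  ijk <- lin2ijk(lin, grid$dims)
  ctr <- voxel_center(lin, grid)
  df <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                   x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                   n_obs = grid$counts)
  for (f in c("density", "delta_e_sw", "delta_e_ww",
              "s_trans", "s_orient", "delta_a"))
    if (!is.null(grid[[f]])) df[[f]] <- grid[[f]]
  if (!keep_empty) df <- df[df$n_obs > 0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
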
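#' Bin proton positions around a placed oxygen on a fine grid
#'
#' Collects the protons of exactly those water observations whose oxygen
#' was drawn into the placement (its contributing voxels, in the frames
#' counted there), keeps the ones inside a radial shell around the placed
#' oxygen bracketing the rigid O-H bond length, and bins them on a fine
#' cubic grid (default 0.1 Angstrom spacing).  Per fine voxel both the
#' count and the position sum are kept so the occupancy-weighted centroid
#' is available.
#'
#' @param placed_o placed oxygen position, xyz.
#' @param obs_rows the observations assigned to this placement (rows of
#'   the [bin_waters()] observation table).
#' @param fine_spacing fine-grid spacing in Angstrom (default 0.1).
#' @param shell inner and outer shell radii around the placed oxygen in
#'   Angstrom; default `c(0.8, 1.1)` brackets the 0.9572 Angstrom rigid
#'   bond plus the sub-voxel offset of the oxygen placement.
#' @return Object of class `gw_proton_grid`: `origin`, `spacing`, `dims`,
#'   `counts`, `pos_sum` (n x 3), `o_pos`, `shell`, `n_protons`.
#' @export
bin_protons <- function(placed_o, obs_rows, fine_spacing = 0.1,
                        shell = c(0.8, 1.1)) {
  stopifnot(fine_spacing > 0, length(shell) == 2, shell[1] < shell[2])
  P <- rbind(as.matrix(obs_rows[, c("h1x", "h1y", "h1z")]),
             as.matrix(obs_rows[, c("h2x", "h2y", "h2z")]))
  colnames(P) <- c("x", "y", "z")
  d <- sqrt(rowSums(sweep(P, 2, placed_o, "-")^2))
  keep <- d >= shell[1] & d <= shell[2]
  if (!any(keep))
    stop("no proton observations inside the radial shell: orientation unresolvable")
  P <- P[keep, , drop = FALSE]
  half <- ceiling(shell[2] / fine_spacing) + 1L
  dims <- rep(2L * half, 3)
  origin <- placed_o - half * fine_spacing
  ijk <- floor(sweep(P, 2, origin, "-") / fine_spacing) + 1
  storage.mode(ijk) <- "integer"
  lin <- ijk2lin(ijk, dims)
  counts <- tabulate(lin, nbins = prod(dims))
  pos_sum <- matrix(0, prod(dims), 3)
  for (a in 1:3) {
    s <- rowsum(P[, a], lin)
    pos_sum[as.integer(rownames(s)), a] <- s[, 1]
  }
  structure(list(origin = origin, spacing = fine_spacing, dims = dims,
                 counts = counts, pos_sum = pos_sum, o_pos = placed_o,
                 shell = shell, n_protons = nrow(P)),
            class = "gw_proton_grid")
}

#' @export
print.gw_proton_grid <- function(x, ...) {
  cat(sprintf("gw_proton_grid: %d protons in %d occupied fine voxels (%.2g A)\n",
              x$n_protons, sum(x$counts > 0), x$spacing))
  invisible(x)
}

# Occupancy-weighted centroids of fine voxels (linear indices `lin`).
proton_centroid <- function(pg, lin) {
  pg$pos_sum[lin, , drop = FALSE] / pg$counts[lin]
}

#' Place the first proton at the most occupied fine voxel
#'
#' Returns the occupancy-weighted centroid of the proton positions binned
#' into the fine voxel with the highest count (ties broken
#' lexicographically by voxel index, which is the grid's linear order).
#'
#' @param pg a [bin_protons()] result.
#' @return xyz position of the first proton.
#' @export
place_first_proton <- function(pg) {
  if (all(pg$counts == 0)) stop("empty proton grid")
  v <- which.max(pg$counts)          # first max = lexicographic tie-break
  proton_centroid(pg, v)[1, ]
}

#' Place the second proton under the H-O-H angle constraint
#'
#' Candidate fine voxels are those whose occupancy-weighted centroid `c`
#' keeps the angle H1-O-c within `angle_tol` of the water model's
#' equilibrium H-O-H angle; among them the most occupied voxel wins (ties
#' lexicographic) and its centroid is returned, so the resulting water
#' angle satisfies the constraint by construction.  When no occupied voxel
#' falls inside the angular window, an ideal-geometry fallback is emitted
#' with a warning: the O->H1 direction rotated by the equilibrium angle
#' within the plane spanned by O->H1 and the mean binned proton direction.
#'
#' @param pg a [bin_protons()] result.
#' @param o_pos,h1_pos placed oxygen and first proton positions.
#' @param model a [water_model()] (equilibrium angle, bond length).
#' @param angle_tol half-width of the angular window in degrees (default 5).
#' @return xyz position of the second proton, with attribute `fallback`
#'   (logical).
#' @export
place_second_proton <- function(pg, o_pos, h1_pos, model = water_model(),
                                angle_tol = 5) {
  stopifnot(angle_tol > 0)
  occ <- which(pg$counts > 0)
  ctr <- proton_centroid(pg, occ)
  u1 <- unit(h1_pos - o_pos)
  dirs <- sweep(ctr, 2, o_pos, "-")
  dn <- sqrt(rowSums(dirs^2))
  cosang <- (dirs %*% u1)[, 1] / dn
  ang <- rad2deg(acos(pmax(-1, pmin(1, cosang))))
  inwin <- abs(ang - model$hoh_angle_eq) < angle_tol
  if (any(inwin)) {
    cand <- occ[inwin]
    best <- cand[which.max(pg$counts[cand])]
    h2 <- proton_centroid(pg, best)[1, ]
    attr(h2, "fallback") <- FALSE
    return(h2)
  }
  warning("no occupied fine voxel inside the angular window; ",
          "ideal-geometry fallback used")
  mean_dir <- colSums(pg$pos_sum) / sum(pg$counts) - o_pos
  v <- mean_dir - sum(mean_dir * u1) * u1
  if (vnorm(v) < 1e-8) {
    # mean direction parallel to O->H1: pick any orthogonal direction
    ref <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ref - sum(ref * u1) * u1
  }
  v <- unit(v)
  theta <- deg2rad(model$hoh_angle_eq)
  h2 <- o_pos + model$oh_length * (cos(theta) * u1 + sin(theta) * v)
  attr(h2, "fallback") <- TRUE
  h2
}

#' Assign proton positions to every placed oxygen
#'
#' Runs the proton-placement algorithm for each placed water: bin the
#' protons of its own contributing observations on the fine grid, put the
#' first proton at the most occupied fine voxel, and the second at the
#' most occupied voxel inside the H-O-H angular window.  Placements whose
#' shell captures no protons, or whose angular window is empty, fall back
#' to ideal geometry and are flagged.
#'
#' @param alloc a [allocate_oxygens()] result.
#' @param observations the observation table the allocation was computed
#'   from.
#' @param model a [water_model()].
#' @param fine_spacing fine-grid spacing in Angstrom (default 0.1).
#' @param angle_tol angular window half-width in degrees (default 5).
#' @param shell radial proton shell in Angstrom.
#' @return The `placed` data.frame of `alloc` with columns `h1x h1y h1z`,
#'   `h2x h2y h2z`, `hoh_angle` (degrees) and `fallback` added.
#' @export
orient_waters <- function(alloc, observations, model = water_model(),
                          fine_spacing = 0.1, angle_tol = 5,
                          shell = c(0.8, 1.1)) {
  placed <- alloc$placed
  n <- nrow(placed)
  h1 <- matrix(NA_real_, n, 3)
  h2 <- matrix(NA_real_, n, 3)
  fallback <- logical(n)
  obs_map <- allocation_observations(alloc, observations)
  for (p in seq_len(n)) {
    o_pos <- c(placed$ox[p], placed$oy[p], placed$oz[p])
    rows <- observations[obs_map[[p]], , drop = FALSE]
    pg <- tryCatch(
      bin_protons(o_pos, rows, fine_spacing = fine_spacing, shell = shell),
      error = function(e) NULL)
    if (is.null(pg) || nrow(rows) == 0) {
      # unresolvable orientation: ideal geometry from the mean water
      # orientation of the contributing observations (or default axes)
      hh <- fallback_water(o_pos, rows, model)
      h1[p, ] <- hh$h1
      h2[p, ] <- hh$h2
      fallback[p] <- TRUE
      next
    }
    h1[p, ] <- place_first_proton(pg)
    h2p <- withCallingHandlers(
      place_second_proton(pg, o_pos, h1[p, ], model = model,
                          angle_tol = angle_tol),
      warning = function(w) invokeRestart("muffleWarning"))
    h2[p, ] <- h2p
    fallback[p] <- isTRUE(attr(h2p, "fallback"))
  }
  placed$h1x <- h1[, 1]; placed$h1y <- h1[, 2]; placed$h1z <- h1[, 3]
  placed$h2x <- h2[, 1]; placed$h2y <- h2[, 2]; placed$h2z <- h2[, 3]
  placed$hoh_angle <- vapply(seq_len(n), function(p)
    vertex_angle(h1[p, ], c(placed$ox[p], placed$oy[p], placed$oz[p]),
                 h2[p, ]), numeric(1))
  placed$fallback <- fallback
  if (any(fallback))
    message(sum(fallback), " placement(s) used the ideal-geometry fallback")
  placed
}

# Ideal-geometry water at o_pos when no protons survive the shell filter:
# oriented along the mean O->H direction of the contributing observations
# when available, else along the body-frame default.
fallback_water <- function(o_pos, rows, model) {
  body <- water_body_sites(model)
  if (nrow(rows) > 0) {
    hh <- rbind(as.matrix(rows[, c("h1x", "h1y", "h1z")]),
                as.matrix(rows[, c("h2x", "h2y", "h2z")]))
    oo <- as.matrix(rows[, c("ox", "oy", "oz")])
    dirs <- hh - rbind(oo, oo)
    m <- colSums(dirs)
    if (vnorm(m) > 1e-8) {
      z <- unit(m)
      ref <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      x <- unit(ref - sum(ref * z) * z)
      y <- c(z[2] * x[3] - z[3] * x[2],
             z[3] * x[1] - z[1] * x[3],
             z[1] * x[2] - z[2] * x[1])
      R <- cbind(x, y, z)
      return(list(h1 = o_pos + as.numeric(R %*% body["h1", ]),
                  h2 = o_pos + as.numeric(R %*% body["h2", ])))
    }
  }
  list(h1 = o_pos + body["h1", ], h2 = o_pos + body["h2", ])
}
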
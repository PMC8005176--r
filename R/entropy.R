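# Nearest-neighbour entropy estimators (translational and orientational).
#
# Both are first-order Shannon-entropy estimators: each observation
# contributes the log of the volume claimed by its nearest neighbour, and
# Euler's constant corrects the asymptotic bias.  The translational search
# runs over the collapsed ensemble (all frames superposed) but only against
# observations from *other* frames, which is what the N_f factor inside the
# logarithm normalises for; the orientational search stays within the voxel.

# Cross-frame nearest-neighbour O-O distances.  `oxyz` is n x 3, `frames`
# the frame index per row.  `query` selects rows to compute (default all).
# Minimum-image distances when `box` is given.  Chunked so the distance
# matrix never exceeds chunk x n.
nn_cross_frame <- function(oxyz, frames, query = NULL, box = NULL,
                           chunk = 512L) {
  n <- nrow(oxyz)
  if (is.null(query)) query <- seq_len(n)
  out <- rep(Inf, length(query))
  if (n < 2) return(out)
  for (start in seq(1, length(query), by = chunk)) {
    idx <- query[start:min(start + chunk - 1L, length(query))]
    dx <- outer(oxyz[idx, 1], oxyz[, 1], "-")
    dy <- outer(oxyz[idx, 2], oxyz[, 2], "-")
    dz <- outer(oxyz[idx, 3], oxyz[, 3], "-")
    if (!is.null(box)) {
      dx <- min_image(dx, box[1])
      dy <- min_image(dy, box[2])
      dz <- min_image(dz, box[3])
    }
    d2 <- dx * dx + dy * dy + dz * dz
    d2[outer(frames[idx], frames, "==")] <- Inf
    out[start:(start + length(idx) - 1L)] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Translational entropy of one voxel
#'
#' First-order nearest-neighbour estimate
#' `R * (gamma + mean(log(N_f rho0 (4 pi / 3) d^3)))` over the voxel's
#' observations, where `d` is each observation's distance to the nearest
#' water oxygen of any *other* frame (collapsed-ensemble convention).  For
#' a uniform bulk at density `rho0` the estimate converges to zero.
#'
#' @param voxel_obs observation rows (as from [bin_waters()]) in the voxel.
#' @param all_obs all observations (the collapsed ensemble searched).
#' @param params a [gist_params()].
#' @param n_frames number of trajectory frames N_f.
#' @param box optional box edges for minimum-image distances.
#' @return entropy in kcal/(mol K); 0 with a warning when no cross-frame
#'   neighbour exists.
#' @export
trans_entropy <- function(voxel_obs, all_obs, params, n_frames, box = NULL) {
  if (nrow(voxel_obs) < 1) return(0)
  oxyz <- as.matrix(all_obs[, c("ox", "oy", "oz")])
  query <- match(interaction(voxel_obs$frame, voxel_obs$water, drop = TRUE),
                 interaction(all_obs$frame, all_obs$water, drop = TRUE))
  d <- nn_cross_frame(oxyz, all_obs$frame, query = query, box = box)
  if (any(!is.finite(d))) {
    warning("no cross-frame neighbour found; translational entropy undefined, set to 0")
    return(0)
  }
  trans_entropy_from_d(d, params, n_frames)
}

trans_entropy_from_d <- function(d, params, n_frames) {
  with(params, gas_constant *
         (euler_gamma + mean(log(n_frames * rho0 * (4 * pi / 3) * d^3))))
}

#' Orientational entropy of one voxel
#'
#' First-order nearest-neighbour estimate
#' `R * (gamma + mean(log(N_f domega^3 / (6 pi))))`, where `domega` is each
#' observation's smallest quaternion angular distance
#' `2 acos(|q_i . q_j|)` to any other observation in the same voxel.
#' Coinciding orientations give `domega = 0`; to keep the logarithm finite
#' these are floored at `omega_floor` and counted in the `n_floored`
#' attribute of the result.
#'
#' @param voxel_obs observation rows in the voxel (needs `qw qx qy qz`).
#' @param params a [gist_params()].
#' @param n_frames number of trajectory frames N_f.
#' @param omega_floor smallest admissible angular distance in radians.
#' @return entropy in kcal/(mol K); 0 with a warning when fewer than two
#'   observations occupy the voxel.
#' @export
orient_entropy <- function(voxel_obs, params, n_frames,
                           omega_floor = 1e-3) {
  n <- nrow(voxel_obs)
  if (n < 2) {
    warning("fewer than two observations in voxel; orientational entropy set to 0")
    return(0)
  }
  dw <- nn_quat_angles(as.matrix(voxel_obs[, c("qw", "qx", "qy", "qz")]))
  floored <- dw < omega_floor
  dw[floored] <- omega_floor
  s <- with(params, gas_constant *
              (euler_gamma + mean(log(n_frames * dw^3 / (6 * pi)))))
  attr(s, "n_floored") <- sum(floored)
  s
}

# Nearest angular distance per row of a quaternion matrix (n x 4).
nn_quat_angles <- function(Q) {
  dots <- abs(Q %*% t(Q))
  diag(dots) <- -Inf
  2 * acos(pmin(1, apply(dots, 1, max)))
}

#' Per-voxel entropy fields for a binned trajectory
#'
#' Computes the translational and orientational nearest-neighbour entropy
#' for every occupied voxel and attaches them to the grid (`s_trans`,
#' `s_orient`, kcal/(mol K); zero for empty voxels), plus per-observation
#' columns `d_trans` (Angstrom) and `d_omega` (radians).
#'
#' @param binned result of [bin_waters()] (or [accumulate_energies()]).
#' @param traj the trajectory the observations came from (supplies N_f and
#'   the box).
#' @param params a [gist_params()].
#' @param omega_floor floor for coinciding orientations, radians.
#' @return `binned` with entropy fields added.
#' @export
entropy_grid <- function(binned, traj, params = gist_params(),
                         omega_floor = 1e-3) {
  grid <- binned$grid
  obs <- binned$observations
  n_frames <- traj$n_frames
  grid$s_trans <- numeric(grid$n_voxels)
  grid$s_orient <- numeric(grid$n_voxels)
  if (nrow(obs) == 0) {
    binned$grid <- grid
    return(binned)
  }
  if (n_frames < 2) {
    warning("single-frame trajectory: translational entropy undefined, set to 0")
    obs$d_trans <- NA_real_
    obs$d_omega <- NA_real_
    binned$grid <- grid
    binned$observations <- obs
    return(binned)
  }
  oxyz <- as.matrix(obs[, c("ox", "oy", "oz")])
  d <- nn_cross_frame(oxyz, obs$frame, box = traj$box)
  obs$d_trans <- d
  fin <- is.finite(d)
  if (!all(fin))
    warning(sum(!fin), " observation(s) without a cross-frame neighbour ",
            "dropped from the translational entropy")
  st <- rowsum(ifelse(fin, log(n_frames * params$rho0 *
                                 (4 * pi / 3) * d^3), 0), obs$voxel)
  nfin <- rowsum(as.numeric(fin), obs$voxel)
  vx <- as.integer(rownames(st))
  ok <- nfin[, 1] > 0
  grid$s_trans[vx[ok]] <- params$gas_constant *
    (params$euler_gamma + st[ok, 1] / nfin[ok, 1])

  obs$d_omega <- NA_real_
  n_floored <- 0L
  multi <- vx[grid$counts[vx] >= 2]
  for (v in multi) {
    rows <- which(obs$voxel == v)
    dw <- nn_quat_angles(as.matrix(obs[rows, c("qw", "qx", "qy", "qz")]))
    n_floored <- n_floored + sum(dw < omega_floor)
    dw <- pmax(dw, omega_floor)
    obs$d_omega[rows] <- dw
    grid$s_orient[v] <- params$gas_constant *
      (params$euler_gamma + mean(log(n_frames * dw^3 / (6 * pi))))
  }
  if (n_floored > 0)
    message(n_floored, " coinciding orientation(s) floored at ",
            omega_floor, " rad")
  binned$grid <- grid
  binned$observations <- obs
  binned
}

#' Assemble per-voxel and total solvation free energies
#'
#' Per voxel (per-water basis):
#' `delta_a = delta_e_sw + delta_e_ww - T (s_trans + s_orient)`.
#' The total solvation free energy sums voxel contributions weighted by
#' their mean water content `N_r / N_f`, so an empty grid gives exactly
#' zero and a voxel holding one permanent water contributes its own
#' `delta_a`.
#'
#' @param binned result of [accumulate_energies()] + [entropy_grid()].
#' @param params a [gist_params()].
#' @return `binned` with `delta_a` and `density` (relative to `rho0`) per
#'   voxel and scalar `delta_a_solv` attached.
#' @export
assemble_free_energy <- function(binned, params = gist_params()) {
  grid <- binned$grid
  for (f in c("delta_e_sw", "delta_e_ww", "s_trans", "s_orient"))
    if (is.null(grid[[f]]))
      stop("grid lacks field ", f, "; run energies and entropies first")
  temp <- params$temperature
  grid$delta_a <- grid$delta_e_sw + grid$delta_e_ww -
    temp * (grid$s_trans + grid$s_orient)
  n_frames <- grid$n_frames
  vol <- grid$spacing^3
  grid$density <- grid$counts / (n_frames * vol * params$rho0)
  binned$grid <- grid
  binned$delta_a_solv <- sum(grid$delta_a * grid$counts / n_frames)
  binned
}
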
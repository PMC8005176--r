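#' Nonbonded pair energy between two sites
#'
#' Coulomb plus 12-6 Lennard-Jones with Lorentz-Berthelot combination
#' (arithmetic sigma, geometric epsilon):
#' `k_e q_a q_b / r + 4 eps_ab [(sig_ab/r)^12 - (sig_ab/r)^6]`,
#' with the minimum-image distance when a box is given.
#'
#' @param pos_a,pos_b site positions, xyz in Angstrom.
#' @param charge_a,charge_b partial charges in e.
#' @param sigma_a,sigma_b Lennard-Jones sigma in Angstrom.
#' @param epsilon_a,epsilon_b Lennard-Jones epsilon in kcal/mol.
#' @param params a [gist_params()] (supplies the Coulomb constant).
#' @param box optional orthorhombic box edges for minimum-image distances.
#' @return energy in kcal/mol.
#' @examples
#' p <- gist_params()
#' pair_energy(c(0, 0, 0), c(1, 0, 0), 1, -1, 0, 0, 0, 0, p)  # -332.0636
#' @export
pair_energy <- function(pos_a, pos_b, charge_a, charge_b,
                        sigma_a = 0, sigma_b = 0,
                        epsilon_a = 0, epsilon_b = 0,
                        params = gist_params(), box = NULL) {
  d <- pos_a - pos_b
  if (!is.null(box)) d <- min_image(d, box)
  r <- sqrt(sum(d * d))
  if (r == 0) stop("pair energy undefined at zero distance")
  e <- params$coulomb_constant * charge_a * charge_b / r
  eps <- sqrt(epsilon_a * epsilon_b)
  if (eps > 0) {
    sig <- (sigma_a + sigma_b) / 2
    sr6 <- (sig / r)^6
    e <- e + 4 * eps * (sr6^2 - sr6)
  }
  e
}

# Pairwise site-site energy matrix between site sets A (na x 3) and B
# (nb x 3) with charges/LJ vectors; `skip` is an optional logical matrix of
# pairs to exclude (set to 0).  Vectorised workhorse behind
# accumulate_energies().
site_energy_matrix <- function(A, B, qa, qb, sa, sb, ea, eb,
                               params, box = NULL, skip = NULL) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image(dx, box[1])
    dy <- min_image(dy, box[2])
    dz <- min_image(dz, box[3])
  }
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (!is.null(skip)) r[skip] <- Inf
  if (any(r == 0))
    stop("coincident distinct sites: zero interatomic distance")
  e <- params$coulomb_constant * outer(qa, qb) / r
  eps <- sqrt(outer(ea, eb))
  nz <- eps > 0
  if (any(nz)) {
    sig <- outer(sa, sb, "+") / 2
    sr6 <- (sig[nz] / r[nz])^6
    e[nz] <- e[nz] + 4 * eps[nz] * (sr6^2 - sr6)
  }
  e
}

#' Accumulate per-voxel solute-water and water-water energies
#'
#' For every binned water observation the solute-water energy `E_sw` is the
#' sum of the interactions of its three sites with all solute atoms, and
#' the water-water energy `E_ww` is half the sum of its interactions with
#' all other waters of the same frame (the 1/2 counts every pair once
#' globally).  Per voxel, `delta_e_sw` is the mean `E_sw` and `delta_e_ww`
#' the mean `E_ww` minus the bulk reference (`eww_ref/2` per observation by
#' default, see [gist_params()]), so bulk-like voxels read approximately
#' zero.  Voxels without observations carry zero energy.
#'
#' @param traj a [gw_trajectory()].
#' @param binned result of [bin_waters()] on `traj`.
#' @param params a [gist_params()].
#' @return `binned` with per-voxel fields `delta_e_sw`, `delta_e_ww` added
#'   to the grid and per-observation columns `e_sw`, `e_ww` added to the
#'   observations.
#' @export
accumulate_energies <- function(traj, binned, params = gist_params()) {
  grid <- binned$grid
  obs <- binned$observations
  at <- traj$topology$atoms
  w <- traj$topology$water_residues
  sidx <- traj$topology$solute_idx
  box <- traj$box
  nw <- if (is.null(w)) 0L else nrow(w)

  obs$e_sw <- numeric(nrow(obs))
  obs$e_ww <- numeric(nrow(obs))
  if (nw > 0 && nrow(obs) > 0) {
    wsites <- as.integer(t(w))            # o,h1,h2 per water, water-major
    site_water <- rep(seq_len(nw), each = 3)
    qs <- at$charge[wsites]; ss <- at$sigma[wsites]; es <- at$epsilon[wsites]
    qu <- at$charge[sidx];   su <- at$sigma[sidx];   eu <- at$epsilon[sidx]
    same_water <- outer(site_water, site_water, "==")
    U <- solute_coords(traj)
    obs_by_frame <- split(seq_len(nrow(obs)), obs$frame)
    for (fch in names(obs_by_frame)) {
      f <- as.integer(fch)
      rows <- obs_by_frame[[fch]]
      S <- matrix(traj$coords[wsites, , f], ncol = 3)
      esw_mat <- site_energy_matrix(S, U, qs, qu, ss, su, es, eu,
                                    params, box)
      esw_water <- rowsum(rowSums(esw_mat), site_water)[, 1]
      eww_mat <- site_energy_matrix(S, S, qs, qs, ss, ss, es, es,
                                    params, box, skip = same_water)
      eww_site <- rowsum(eww_mat, site_water)        # nw x 3nw
      eww_water <- rowSums(eww_site)                 # per water vs all others
      obs$e_sw[rows] <- esw_water[obs$water[rows]]
      obs$e_ww[rows] <- 0.5 * eww_water[obs$water[rows]]
    }
  }

  ref_sub <- if (params$eww_ref_mode == "half") params$eww_ref / 2 else
    params$eww_ref
  n_r <- grid$counts
  sum_sw <- numeric(grid$n_voxels)
  sum_ww <- numeric(grid$n_voxels)
  if (nrow(obs) > 0) {
    s1 <- rowsum(obs$e_sw, obs$voxel)
    s2 <- rowsum(obs$e_ww, obs$voxel)
    vx <- as.integer(rownames(s1))
    sum_sw[vx] <- s1[, 1]
    sum_ww[vx] <- s2[, 1]
  }
  grid$delta_e_sw <- ifelse(n_r > 0, sum_sw / pmax(n_r, 1), 0)
  grid$delta_e_ww <- ifelse(n_r > 0, sum_ww / pmax(n_r, 1) - ref_sub, 0)
  binned$grid <- grid
  binned$observations <- obs
  binned
}
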
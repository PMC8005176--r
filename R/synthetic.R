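#' Specification of a synthetic ground-truth trajectory
#'
#' Describes the statistical structure the GIST analysis assumes, with
#' known ground truth: a fixed (restrained) solute, a set of hydration
#' hotspots (high-occupancy sites with concentrated positions and
#' orientations) and a uniform bulk background at the water model's
#' reference density.  The generated trajectories exercise every pipeline
#' stage without molecular dynamics.
#'
#' The number of waters is constant over frames (as in an NVT ensemble):
#' one water per hotspot plus a bulk contingent sized so that the
#' accessible volume of the box carries `bulk_density`.  In frames where a
#' hotspot is unoccupied (probability `1 - p`) its water becomes an extra
#' bulk water for that frame.
#'
#' @param solute data.frame of positioned solute atoms with columns
#'   `name, element, x, y, z, charge, sigma, epsilon`; default is a 3-atom
#'   polar toy solute resembling a carbonyl fragment.
#' @param hotspots data.frame with one row per hotspot: `x, y, z` (centre,
#'   Angstrom), `sigma` (positional spread, Angstrom), `p` (per-frame
#'   occupancy probability), `qw, qx, qy, qz` (reference orientation
#'   quaternion), `angular_sigma` (orientation noise, degrees).  `NULL`
#'   for none; the default places three hotspots at hydrogen-bonding
#'   distance with occupancy 0.9, positional spread 0.3 Angstrom and
#'   8 degrees of angular noise.
#' @param bulk_density bulk number density in molecules/Angstrom^3
#'   (default: the model's `rho0`).
#' @param box_edge cubic box edge in Angstrom (default 12.4, ~60 bulk
#'   waters per frame at the reference density).
#' @param n_frames number of frames (default 200).
#' @param seed RNG seed; fixed seed implies bit-identical trajectories.
#' @param model a [water_model()].
#' @param exclusion_radius minimum distance of bulk waters from solute
#'   atoms and hotspot waters, Angstrom (default 2.4).
#' @return Object of class `gw_synthetic_spec`.
#' @export
synthetic_spec <- function(solute = default_toy_solute(),
                           hotspots = default_hotspots(),
                           bulk_density = NULL,
                           box_edge = 12.4,
                           n_frames = 200,
                           seed = 1,
                           model = water_model(),
                           exclusion_radius = 2.4) {
  if (is.null(bulk_density)) bulk_density <- model$rho0
  stopifnot(box_edge > 0, n_frames >= 1, bulk_density >= 0,
            exclusion_radius >= 0)
  if (!is.null(hotspots) && nrow(hotspots) > 0) {
    if (any(hotspots$p < 0 | hotspots$p > 1))
      stop("hotspot occupancy probabilities must lie in [0, 1]")
    if (any(hotspots$sigma < 0))
      stop("hotspot positional sigma must be non-negative")
    if (nrow(hotspots) > 1) {
      ctr <- as.matrix(hotspots[, c("x", "y", "z")])
      dmin <- min(stats::dist(ctr))
      min_sep <- 2 * sqrt(3) * 0.5   # two diagonals of the 0.5 A voxel
      if (dmin < min_sep)
        stop(sprintf(paste0("hotspots %.2f A apart are closer than two ",
                            "voxel diagonals (%.2f A): ground truth would ",
                            "be ambiguous"), dmin, min_sep))
    }
  }
  structure(list(solute = solute, hotspots = hotspots,
                 bulk_density = bulk_density, box_edge = box_edge,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 model = model, exclusion_radius = exclusion_radius),
            class = "gw_synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_toy_solute <- function() {
  data.frame(name = c("C1", "O1", "H1"),
             element = c("C", "O", "H"),
             x = c(0, 1.23, -0.95), y = c(0, 0, 0.55), z = c(0, 0, 0),
             charge = c(0.45, -0.60, 0.15),
             sigma = c(3.40, 2.96, 2.47),
             epsilon = c(0.086, 0.210, 0.0157))
}

#' @rdname synthetic_spec
#' @export
default_hotspots <- function() {
  q90x <- c(cos(pi / 4), sin(pi / 4), 0, 0)
  q90y <- c(cos(pi / 4), 0, sin(pi / 4), 0)
  data.frame(x = c(2.85, 2.55, -2.55),
             y = c(1.15, -1.35, 1.45),
             z = c(0.30, -0.40, 0.20),
             sigma = 0.3, p = 0.9,
             qw = c(1, q90x[1], q90y[1]),
             qx = c(0, q90x[2], q90y[2]),
             qy = c(0, q90x[3], q90y[3]),
             qz = c(0, q90x[4], q90y[4]),
             angular_sigma = 8)
}

#' Ground-truth table of a synthetic spec
#'
#' Deterministic readout of the true hotspot centres, orientations and
#' occupancies, used by recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with one row per hotspot (`site`, centre, sigma,
#'   occupancy, quaternion, angular noise); empty for a bulk-only spec.
#' @export
ground_truth <- function(spec) {
  h <- spec$hotspots
  if (is.null(h) || nrow(h) == 0)
    return(data.frame(site = integer(), x = numeric(), y = numeric(),
                      z = numeric(), sigma = numeric(), p = numeric(),
                      qw = numeric(), qx = numeric(), qy = numeric(),
                      qz = numeric(), angular_sigma = numeric()))
  cbind(data.frame(site = seq_len(nrow(h))),
        h[, c("x", "y", "z", "sigma", "p", "qw", "qx", "qy", "qz",
              "angular_sigma")])
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Per frame: each hotspot is occupied with its probability by one rigid
#' water at its centre plus isotropic Gaussian positional noise, oriented
#' at its reference orientation composed with a random-axis rotation of
#' Gaussian angle; unoccupied hotspot waters and the bulk contingent are
#' placed uniformly in the box outside an exclusion radius of the solute
#' and the occupied hotspot waters, with uniformly random orientations.
#' The solute is identical in every frame.
#'
#' @param spec a [synthetic_spec()].
#' @return A [gw_trajectory()] with the box recorded and `rho0` attached
#'   as an attribute.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gw_synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  model <- spec$model
  body <- water_body_sites(model)
  edge <- spec$box_edge
  sol <- spec$solute
  sol_xyz <- as.matrix(sol[, c("x", "y", "z")])
  nh <- if (is.null(spec$hotspots)) 0L else nrow(spec$hotspots)
  excl <- spec$exclusion_radius

  # Bulk contingent: density * accessible volume (Monte Carlo estimate of
  # the volume outside the solute exclusion region).
  n_bulk <- 0L
  if (spec$bulk_density > 0) {
    probe <- matrix(stats::runif(3 * 20000, -edge / 2, edge / 2), ncol = 3)
    free <- rep(TRUE, nrow(probe))
    for (a in seq_len(nrow(sol_xyz)))
      free <- free & (rowSums(sweep(probe, 2, sol_xyz[a, ], "-")^2) >
                        excl^2)
    n_bulk <- as.integer(round(spec$bulk_density * edge^3 * mean(free)))
  }
  nw <- nh + n_bulk

  atoms <- data.frame(
    index = 0:(nrow(sol) + 3L * nw - 1L),
    name = c(sol$name, rep(c("O", "H1", "H2"), max(nw, 0))),
    element = c(sol$element, rep(c("O", "H", "H"), max(nw, 0))),
    charge = c(sol$charge, rep(c(model$q_o, model$q_h, model$q_h), nw)),
    sigma = c(sol$sigma, rep(c(model$sigma_o, model$sigma_h,
                               model$sigma_h), nw)),
    epsilon = c(sol$epsilon, rep(c(model$epsilon_o, model$epsilon_h,
                                   model$epsilon_h), nw)),
    residue_id = c(rep(1L, nrow(sol)), rep(1L + seq_len(nw), each = 3)),
    residue_name = c(rep("LIG", nrow(sol)), rep("HOH", 3 * nw)),
    is_solute = c(rep(TRUE, nrow(sol)), rep(FALSE, 3 * nw)))
  topology <- gw_topology(atoms)

  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, c(n_atoms, 3, spec$n_frames))
  sol_rows <- seq_len(nrow(sol))
  for (f in seq_len(spec$n_frames)) {
    coords[sol_rows, , f] <- sol_xyz
    occupied_o <- matrix(numeric(0), 0, 3)
    extra_bulk <- 0L
    # hotspot waters
    for (hh in seq_len(nh)) {
      hs <- spec$hotspots[hh, ]
      rows <- nrow(sol) + (hh - 1L) * 3L + 1:3
      if (stats::runif(1) <= hs$p) {
        o <- c(hs$x, hs$y, hs$z) + stats::rnorm(3, sd = hs$sigma)
        Rref <- quat2mat(c(hs$qw, hs$qx, hs$qy, hs$qz))
        ax <- stats::rnorm(3)
        ang <- stats::rnorm(1, sd = deg2rad(hs$angular_sigma))
        Rn <- rotation_matrix(ax, ang)
        R <- Rn %*% Rref
        sites <- sweep(t(R %*% t(body)), 2, o, "+")
        coords[rows, , f] <- sites
        occupied_o <- rbind(occupied_o, o)
      } else {
        coords[rows, , f] <- NA_real_   # filled as bulk below
        extra_bulk <- extra_bulk + 1L
      }
    }
    # bulk waters (plus this frame's unoccupied hotspot waters); the
    # exclusion radius also applies between bulk waters so no frame holds
    # physically impossible overlaps
    need <- n_bulk + extra_bulk
    if (need > 0) {
      accepted <- matrix(numeric(0), 0, 3)
      guard <- 0L
      while (nrow(accepted) < need) {
        guard <- guard + 1L
        if (guard > 10000L)
          stop("bulk placement rejection sampling failed to converge")
        cand <- matrix(stats::runif(3 * 2 * need, -edge / 2, edge / 2),
                       ncol = 3)
        ok <- rep(TRUE, nrow(cand))
        for (a in seq_len(nrow(sol_xyz)))
          ok <- ok & (rowSums(sweep(cand, 2, sol_xyz[a, ], "-")^2) >
                        excl^2)
        if (nrow(occupied_o) > 0)
          for (a in seq_len(nrow(occupied_o)))
            ok <- ok & (rowSums(sweep(cand, 2, occupied_o[a, ], "-")^2) >
                          excl^2)
        for (ci in which(ok)) {
          if (nrow(accepted) >= need) break
          p <- cand[ci, ]
          clash <- FALSE
          if (nrow(accepted) > 0) {
            dmi <- min_image(sweep(accepted, 2, p, "-"), edge)
            clash <- min(rowSums(dmi^2)) <= excl^2
          }
          if (!clash) accepted <- rbind(accepted, p)
        }
      }
      accepted <- accepted[seq_len(need), , drop = FALSE]
      bulk_rows <- which(is.na(coords[topology$water_residues[, "o"], 1, f]))
      stopifnot(length(bulk_rows) == need)
      for (b in seq_len(need)) {
        wr <- topology$water_residues[bulk_rows[b], ]
        R <- quat2mat(random_quaternion())
        sites <- sweep(t(R %*% t(body)), 2, accepted[b, ], "+")
        coords[c(wr["o"], wr["h1"], wr["h2"]), , f] <- sites
      }
    }
  }
  traj <- gw_trajectory(topology, coords, box = rep(edge, 3))
  attr(traj, "rho0") <- spec$bulk_density
  traj
}

#' Read/write a synthetic spec as YAML
#'
#' @param spec a [synthetic_spec()].
#' @param path YAML path.
#' @return `write_synthetic_spec`: `path` invisibly;
#'   `read_synthetic_spec`: the spec.
#' @export
write_synthetic_spec <- function(spec, path) {
  x <- list(solute = as.list(spec$solute),
            hotspots = if (is.null(spec$hotspots)) NULL else
              as.list(spec$hotspots),
            bulk_density = spec$bulk_density,
            box_edge = spec$box_edge, n_frames = spec$n_frames,
            seed = spec$seed, exclusion_radius = spec$exclusion_radius,
            model = unclass(spec$model))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  x <- yaml::read_yaml(path)
  synthetic_spec(
    solute = as.data.frame(x$solute),
    hotspots = if (is.null(x$hotspots)) NULL else as.data.frame(x$hotspots),
    bulk_density = x$bulk_density, box_edge = x$box_edge,
    n_frames = x$n_frames, seed = x$seed,
    model = do.call(water_model, x$model),
    exclusion_radius = x$exclusion_radius)
}
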
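#' Run configuration
#'
#' All tunable settings of the workflow with their standard defaults:
#' 30 Angstrom cubic grid at 0.5 Angstrom spacing, 0.1 Angstrom fine grid
#' for protons, 5 degree angular window, 95% density-allocation target,
#' 300 K, TIP3P-like bulk references, and RDF coordination cut-offs of
#' 2.9 Angstrom (O) and 1.9 Angstrom (H).  Round-trips through YAML.
#'
#' @param grid_edge analysis grid edge, Angstrom.
#' @param spacing analysis voxel edge, Angstrom.
#' @param fine_spacing proton-grid spacing, Angstrom.
#' @param angle_tol H-O-H angular window half-width, degrees.
#' @param alloc_fraction density-allocation stop fraction in (0, 1].
#' @param temperature K.
#' @param eww_ref bulk water-water reference energy, kcal/mol.
#' @param rho0 bulk number density, molecules/Angstrom^3.
#' @param rdf_cutoff_o,rdf_cutoff_h RDF coordination cut-offs, Angstrom.
#' @param seed RNG seed for synthetic generation.
#' @param pdb,params,outdir input trajectory PDB, parameter sidecar CSV and
#'   output directory for the command wrappers.
#' @return Object of class `gw_config`.
#' @export
gw_config <- function(grid_edge = 30, spacing = 0.5, fine_spacing = 0.1,
                      angle_tol = 5, alloc_fraction = 0.95,
                      temperature = 300, eww_ref = -9.533, rho0 = 0.0334,
                      rdf_cutoff_o = 2.9, rdf_cutoff_h = 1.9,
                      seed = 1, pdb = NULL, params = NULL,
                      outdir = ".") {
  structure(list(grid_edge = grid_edge, spacing = spacing,
                 fine_spacing = fine_spacing, angle_tol = angle_tol,
                 alloc_fraction = alloc_fraction,
                 temperature = temperature, eww_ref = eww_ref,
                 rho0 = rho0, rdf_cutoff_o = rdf_cutoff_o,
                 rdf_cutoff_h = rdf_cutoff_h, seed = seed,
                 pdb = pdb, params = params, outdir = outdir),
            class = "gw_config")
}

#' @rdname gw_config
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname gw_config
#' @param config a `gw_config`.
#' @export
read_config <- function(path) {
  do.call(gw_config, yaml::read_yaml(path))
}

config_params <- function(config) {
  gist_params(temperature = config$temperature,
              model = water_model(rho0 = config$rho0,
                                  eww_ref = config$eww_ref))
}

# Grid for a trajectory: centred on the solute centroid, clamped to the
# box when one is present so every voxel lies inside it.
default_grid <- function(traj, config) {
  ctr <- colMeans(solute_coords(traj))
  edge <- rep_len(config$grid_edge, 3)
  if (!is.null(traj$box)) {
    edge <- pmin(edge, floor(traj$box / config$spacing) * config$spacing)
    ctr <- pmin(pmax(ctr, -traj$box / 2 + edge / 2), traj$box / 2 - edge / 2)
  }
  build_grid(ctr, edge, config$spacing)
}

#' Full per-voxel GIST analysis of a trajectory
#'
#' Bins the waters, accumulates solute-water and water-water energies,
#' estimates the translational and orientational nearest-neighbour
#' entropies, and assembles the per-voxel and total solvation free energy.
#'
#' @param traj a [gw_trajectory()].
#' @param config a [gw_config()].
#' @param grid optional pre-built grid; by default a grid centred on the
#'   solute (clamped inside the box when one is present).
#' @param thermo set `FALSE` to stop after binning (density only), e.g.
#'   when only placement counts are needed.
#' @return List with `grid` (all per-voxel fields), `observations`,
#'   `delta_a_solv` (kcal/mol, when `thermo`), `params`.
#' @export
gist_analysis <- function(traj, config = gw_config(), grid = NULL,
                          thermo = TRUE) {
  params <- config_params(config)
  if (is.null(grid)) grid <- default_grid(traj, config)
  res <- bin_waters(traj, grid)
  if (thermo) {
    res <- accumulate_energies(traj, res, params)
    res <- entropy_grid(res, traj, params)
    res <- assemble_free_energy(res, params)
  }
  res$params <- params
  res
}

#' Place, orient and rank water molecules from a GIST analysis
#'
#' Greedy density allocation of oxygen positions, proton assignment on the
#' fine grid, density-weighted free-energy assignment (when the analysis
#' carries thermodynamics) and ranking by solvation free energy.
#'
#' @param gist a [gist_analysis()] result.
#' @param traj the analysed trajectory.
#' @param config a [gw_config()].
#' @return List with `alloc` ([allocate_oxygens()] state) and `ranking`
#'   ([rank_waters()] result; `delta_a` is `NA` when the analysis had
#'   `thermo = FALSE`).
#' @export
place_waters <- function(gist, traj, config = gw_config()) {
  alloc <- allocate_oxygens(gist$grid,
                            target_fraction = config$alloc_fraction)
  placed <- orient_waters(alloc, gist$observations,
                          model = config_params(config)$model,
                          fine_spacing = config$fine_spacing,
                          angle_tol = config$angle_tol)
  if (!is.null(gist$grid$delta_a)) {
    placed$delta_a <- vapply(placed$id, function(id)
      assign_delta_a(alloc$contributions[[id]], gist$grid, alloc$quantum),
      numeric(1))
  } else {
    placed$delta_a <- NA_real_
  }
  ranking <- rank_waters(placed, solute_coords(traj))
  list(alloc = alloc, ranking = ranking)
}

# Command wrappers ----------------------------------------------------------

load_traj <- function(config) {
  if (is.null(config$pdb) || is.null(config$params))
    stop("config must name the trajectory `pdb` and parameter `params` files")
  traj <- read_trajectory(config$pdb, config$params)
  attr(traj, "rho0") <- config$rho0
  traj
}

#' Pipeline commands
#'
#' Thin wrappers tying the pipeline stages to files, used by the
#' command-line interface: `cmd_gist` writes the per-voxel grid artifacts
#' (tidy CSV plus OpenDX density and free-energy grids), `cmd_place`
#' writes the placement table and ranking chart CSV, `cmd_select` writes a
#' microsolvated cluster PDB, `cmd_rdf` writes solute-water RDF tables and
#' `cmd_synth` generates a synthetic fixture trajectory.
#'
#' @param config a [gw_config()] naming `pdb`, `params` and `outdir`.
#' @return Invisibly, the paths written (or for `cmd_place`/`cmd_gist` the
#'   result objects with paths attached).
#' @export
cmd_gist <- function(config) {
  traj <- load_traj(config)
  gist <- gist_analysis(traj, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outdir,
                     c("gist_voxels.csv", "density.dx", "delta_a.dx"))
  write_grid_csv(gist$grid, paths[1])
  write_dx(gist$grid, gist$grid$density, paths[2], name = "water density")
  write_dx(gist$grid, gist$grid$delta_a, paths[3],
           name = "solvation free energy")
  message(sprintf("delta_A_solv = %.3f kcal/mol", gist$delta_a_solv))
  invisible(list(gist = gist, paths = paths))
}

#' @rdname cmd_gist
#' @export
cmd_place <- function(config) {
  traj <- load_traj(config)
  gist <- gist_analysis(traj, config)
  pw <- place_waters(gist, traj, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outdir, c("placements.csv", "chart.csv"))
  write_placement_csv(pw$ranking, paths[1], alloc = pw$alloc)
  export_chart(pw$ranking, paths[2])
  invisible(list(placement = pw, gist = gist, traj = traj, paths = paths))
}

#' @rdname cmd_gist
#' @param n number of top-ranked waters for the cluster.
#' @export
cmd_select <- function(config, n) {
  res <- cmd_place(config)
  path <- file.path(config$outdir, sprintf("cluster_n%d.pdb", n))
  select_and_write_cluster(res$placement$ranking, res$traj, path, n = n)
  invisible(path)
}

#' @rdname cmd_gist
#' @export
cmd_rdf <- function(config) {
  traj <- load_traj(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outdir, c("rdf_O.csv", "rdf_H.csv"))
  ro <- compute_rdf(traj, site = "O", cutoff = config$rdf_cutoff_o)
  rh <- compute_rdf(traj, site = "H", cutoff = config$rdf_cutoff_h)
  write_rdf_csv(ro, paths[1])
  write_rdf_csv(rh, paths[2])
  message(sprintf("n_O(%.2f A) = %.3f, n_H(%.2f A) = %.3f",
                  ro$cutoff, ro$n_at_cutoff, rh$cutoff, rh$n_at_cutoff))
  invisible(paths)
}

#' @rdname cmd_gist
#' @param spec a [synthetic_spec()]; when `NULL`, the default 3-hotspot
#'   spec with the config's seed.
#' @export
cmd_synth <- function(config, spec = NULL) {
  if (is.null(spec)) spec <- synthetic_spec(seed = config$seed)
  traj <- generate_trajectory(spec)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$outdir,
                     c("synthetic.pdb", "synthetic_params.csv",
                       "synthetic_truth.csv"))
  write_trajectory(traj, paths[1], params_path = paths[2])
  utils::write.csv(ground_truth(spec), paths[3], row.names = FALSE)
  invisible(paths)
}
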
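#' Build a topology from a per-atom parameter table
#'
#' The parameter table is the sidecar of the multi-model PDB trajectory: one
#' row per atom, in file order, carrying the force-field data a PDB cannot
#' (partial charge, Lennard-Jones sigma/epsilon, solute flag).
#'
#' @param atoms data.frame with columns `index` (0-based, dense, unique),
#'   `name`, `element`, `charge` (e), `sigma` (Angstrom), `epsilon`
#'   (kcal/mol), `residue_id`, `residue_name`, `is_solute` (logical or 0/1).
#' @return An object of class `gw_topology` with elements `atoms`
#'   (normalised table), `water_residues` (matrix with columns `o`, `h1`,
#'   `h2` of 1-based atom rows, one row per water) and `solute_idx`
#'   (1-based atom rows of the solute).
#' @export
gw_topology <- function(atoms) {
  req <- c("index", "name", "element", "charge", "sigma", "epsilon",
           "residue_id", "residue_name", "is_solute")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  atoms <- atoms[order(atoms$index), req, drop = FALSE]
  atoms$is_solute <- as.logical(atoms$is_solute)
  n <- nrow(atoms)
  if (n == 0) stop("empty parameter table")
  if (!identical(as.integer(atoms$index), 0:(n - 1))) {
    missing_idx <- setdiff(0:max(atoms$index), atoms$index)
    if (length(missing_idx) > 0)
      stop("parameters missing for atom index ",
           paste(missing_idx, collapse = ", "))
    stop("atom indices must be unique, dense and 0-based")
  }
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0))
    stop("Lennard-Jones sigma and epsilon must be non-negative")
  if (any(is.na(atoms$is_solute)))
    stop("every atom needs a solute/solvent role")
  solute_idx <- which(atoms$is_solute)
  if (length(solute_idx) == 0) stop("topology has no solute atoms")

  solv <- atoms[!atoms$is_solute, , drop = FALSE]
  wres <- NULL
  if (nrow(solv) > 0) {
    by_res <- split(which(!atoms$is_solute), solv$residue_id)
    wres <- t(vapply(names(by_res), function(rid) {
      rows <- by_res[[rid]]
      el <- toupper(atoms$element[rows])
      if (length(rows) != 3 || sum(el == "O") != 1 || sum(el == "H") != 2)
        stop("solvent residue ", rid,
             " is not a 3-site water (needs one O and two H)")
      c(o = rows[el == "O"], rows[el == "H"])
    }, integer(3)))
    colnames(wres) <- c("o", "h1", "h2")
    wres <- wres[order(wres[, "o"]), , drop = FALSE]
  }
  structure(list(atoms = atoms,
                 water_residues = wres,
                 solute_idx = solute_idx),
            class = "gw_topology")
}

#' @export
print.gw_topology <- function(x, ...) {
  cat(sprintf("gw_topology: %d atoms (%d solute, %d waters)\n",
              nrow(x$atoms), length(x$solute_idx),
              if (is.null(x$water_residues)) 0L else nrow(x$water_residues)))
  invisible(x)
}

#' Construct a trajectory of a restrained solute in rigid water
#'
#' @param topology a [gw_topology()].
#' @param coords numeric array of dimension (n_atoms, 3, n_frames) in
#'   Angstrom, lab frame.
#' @param box optional orthorhombic box edge lengths in Angstrom (length-3
#'   vector, constant over frames).
#' @param check if `TRUE` (default) enforce the restrained-solute invariant:
#'   no solute atom may move by more than `rigid_tol` between any two frames.
#' @param rigid_tol rigidity tolerance in Angstrom (default 1e-3, the
#'   precision of PDB coordinates).
#' @return An object of class `gw_trajectory` with fields `topology`,
#'   `coords`, `box`, `n_frames`.
#' @export
gw_trajectory <- function(topology, coords, box = NULL, check = TRUE,
                          rigid_tol = 1e-3) {
  stopifnot(inherits(topology, "gw_topology"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an (n_atoms, 3, n_frames) array")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("coordinate count does not match topology atom count")
  n_frames <- dim(coords)[3]
  if (n_frames < 1) stop("trajectory needs at least one frame")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0))
      stop("box must be three positive edge lengths")
  }
  traj <- structure(list(topology = topology, coords = coords,
                         box = box, n_frames = n_frames),
                    class = "gw_trajectory")
  if (check) check_rigid_solute(traj, tol = rigid_tol)
  traj
}

# Reject trajectories whose solute moves: the whole analysis assumes a
# restrained solute (lab-frame grids, no alignment).
check_rigid_solute <- function(traj, tol = 1e-3) {
  s <- traj$topology$solute_idx
  if (traj$n_frames == 1) return(invisible(0))
  ref <- traj$coords[s, , 1, drop = FALSE]
  disp <- 0
  for (f in 2:traj$n_frames) {
    d <- traj$coords[s, , f, drop = FALSE] - ref
    disp <- max(disp, sqrt(max(rowSums(matrix(d, ncol = 3)^2))))
  }
  if (disp > tol)
    stop(sprintf(paste0("solute is not rigid: max displacement %.4g A ",
                        "exceeds tolerance %.4g A"), disp, tol))
  invisible(disp)
}

#' @export
print.gw_trajectory <- function(x, ...) {
  cat(sprintf("gw_trajectory: %d frames, %d atoms (%d waters)%s\n",
              x$n_frames, nrow(x$topology$atoms),
              if (is.null(x$topology$water_residues)) 0L
              else nrow(x$topology$water_residues),
              if (is.null(x$box)) ""
              else sprintf(", box %.2f x %.2f x %.2f A",
                           x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Read a multi-model PDB trajectory with its parameter sidecar
#'
#' Reads MODEL/ENDMDL blocks (consistent atom ordering required) through
#' `bio3d::read.pdb()` and joins the per-atom force-field parameters from
#' the sidecar CSV.  An orthorhombic box is picked up from a CRYST1 record
#' when present.  The restrained-solute invariant is checked on read.
#'
#' @param pdb_path path of the multi-model PDB file.
#' @param params_path path of the parameter CSV with header
#'   `index,name,element,charge,sigma,epsilon,residue_id,residue_name,is_solute`.
#' @param rigid_tol solute-rigidity tolerance in Angstrom.
#' @return A [gw_trajectory()].
#' @export
read_trajectory <- function(pdb_path, params_path, rigid_tol = 1e-3) {
  atoms <- utils::read.csv(params_path, stringsAsFactors = FALSE)
  topology <- gw_topology(atoms)
  pdb <- bio3d::read.pdb(pdb_path, multi = TRUE, verbose = FALSE)
  n_atom_pdb <- nrow(pdb$atom)
  n <- nrow(topology$atoms)
  if (n_atom_pdb != n)
    stop(sprintf(paste0("parameter table covers %d atoms but the PDB has ",
                        "%d per model; first unmatched atom: %s"),
                 n, n_atom_pdb,
                 if (n_atom_pdb > n) pdb$atom$elety[n + 1]
                 else topology$atoms$name[n_atom_pdb + 1]))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  coords <- array(NA_real_, c(n, 3, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  box <- read_cryst1(pdb_path)
  gw_trajectory(topology, coords, box = box, rigid_tol = rigid_tol)
}

# Orthorhombic box from the CRYST1 record (bio3d does not expose it).
read_cryst1 <- function(pdb_path) {
  lines <- readLines(pdb_path, n = 200L)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  edges <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
  angles <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                         substr(cl[1], 48, 54)))
  if (any(is.na(edges)) || any(edges <= 0)) return(NULL)
  if (any(abs(angles - 90) > 1e-3))
    stop("only orthorhombic boxes are supported (CRYST1 angles must be 90)")
  edges
}

#' Write a trajectory as a multi-model PDB (+ optional parameter sidecar)
#'
#' @param traj a [gw_trajectory()].
#' @param path output PDB path.
#' @param params_path optional path for the parameter CSV sidecar; when
#'   given, the file written is accepted by [read_trajectory()].
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, params_path = NULL) {
  stopifnot(inherits(traj, "gw_trajectory"))
  if (traj$n_frames < 1) stop("cannot write a trajectory with no frames")
  at <- traj$topology$atoms
  n <- nrow(at)
  xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
  if (traj$n_frames == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$residue_id, resid = at$residue_name,
                   elety = at$name, elesy = at$element,
                   chain = rep("A", n))
  if (traj$n_frames == 1) {
    # keep the MODEL/ENDMDL framing also for single-frame trajectories
    lines <- readLines(path)
    first <- grep("^(ATOM|HETATM)", lines)[1]
    lines <- append(lines, "MODEL        1", after = first - 1)
    lines <- append(lines, "ENDMDL",
                    after = max(grep("^(ATOM|HETATM|TER)", lines)))
    writeLines(lines, path)
  }
  if (!is.null(traj$box)) {
    cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                  traj$box[1], traj$box[2], traj$box[3], 90, 90, 90)
    writeLines(c(cr, readLines(path)), path)
  }
  if (!is.null(params_path)) write_atom_params(at, params_path)
  invisible(path)
}

#' Write the per-atom parameter sidecar CSV
#'
#' @param atoms the `atoms` table of a [gw_topology()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_atom_params <- function(atoms, path) {
  out <- atoms
  out$is_solute <- as.integer(out$is_solute)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Convenience accessors -----------------------------------------------------

# Oxygen coordinates of all waters in one frame: matrix n_waters x 3.
water_oxygens <- function(traj, frame) {
  w <- traj$topology$water_residues
  matrix(traj$coords[w[, "o"], , frame], ncol = 3)
}

solute_coords <- function(traj, frame = 1) {
  m <- traj$coords[traj$topology$solute_idx, , frame, drop = FALSE]
  matrix(m, ncol = 3)
}
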
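#' Solute-solvent radial distribution function
#'
#' Shell-normalised g(r) between selected solute atoms and a water site
#' (O or H), with the running coordination number n(r).  Normalisation is
#' against the bulk reference density `rho0` (doubled for the H site, two
#' sites per water), so an ideal-gas solvent at `rho0` gives g(r) ~ 1.
#' The coordination integral is reported at a configurable cut-off
#' (defaults: 2.9 Angstrom for O, 1.9 Angstrom for H, the canonical first-
#' maximum cut-offs).
#'
#' @param traj a [gw_trajectory()].
#' @param solute_atoms 1-based atom rows of the solute atoms to use as
#'   reference centres (default: all solute atoms).
#' @param site `"O"` or `"H"`: which water site to histogram.
#' @param bin_width histogram bin width in Angstrom.
#' @param r_max histogram range in Angstrom.
#' @param cutoff distance at which the coordination number is reported;
#'   default 2.9 (O) or 1.9 (H).
#' @return Object of class `gw_rdf`: data.frame `table` with `r` (bin
#'   centre), `g`, `n`, plus `cutoff` and `n_at_cutoff`.
#' @export
compute_rdf <- function(traj, solute_atoms = NULL, site = c("O", "H"),
                        bin_width = 0.1, r_max = 8,
                        cutoff = NULL) {
  site <- match.arg(site)
  stopifnot(bin_width > 0, r_max > bin_width)
  if (is.null(cutoff)) cutoff <- if (site == "O") 2.9 else 1.9
  if (is.null(solute_atoms)) solute_atoms <- traj$topology$solute_idx
  if (length(solute_atoms) == 0) stop("empty solute atom selection")
  w <- traj$topology$water_residues
  if (is.null(w) || nrow(w) == 0) stop("trajectory has no waters")
  srows <- if (site == "O") w[, "o"] else c(w[, "h1"], w[, "h2"])
  site_mult <- if (site == "O") 1 else 2
  breaks <- seq(0, r_max, by = bin_width)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  n_cut <- 0
  box <- traj$box
  for (f in seq_len(traj$n_frames)) {
    P <- matrix(traj$coords[srows, , f], ncol = 3)
    U <- matrix(traj$coords[solute_atoms, , f], ncol = 3)
    dx <- outer(U[, 1], P[, 1], "-")
    dy <- outer(U[, 2], P[, 2], "-")
    dz <- outer(U[, 3], P[, 3], "-")
    if (!is.null(box)) {
      dx <- min_image(dx, box[1])
      dy <- min_image(dy, box[2])
      dz <- min_image(dz, box[3])
    }
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    h <- graphics::hist(d[d < r_max], breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
    n_cut <- n_cut + sum(d <= cutoff)
  }
  norm <- traj$n_frames * length(solute_atoms)
  r_lo <- breaks[-(nb + 1)]
  r_hi <- breaks[-1]
  shell_vol <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
  rho_ref <- site_mult * attr_rho0(traj)
  g <- counts / (norm * shell_vol * rho_ref)
  structure(list(table = data.frame(r = (r_lo + r_hi) / 2, g = g,
                                    n = cumsum(counts) / norm),
                 site = site, cutoff = cutoff,
                 n_at_cutoff = n_cut / norm),
            class = "gw_rdf")
}

# Reference density used for RDF normalisation; trajectories may carry one
# via attr(traj, "rho0"), otherwise the TIP3P-like default applies.
attr_rho0 <- function(traj) {
  r <- attr(traj, "rho0")
  if (is.null(r)) water_model()$rho0 else r
}

#' @export
print.gw_rdf <- function(x, ...) {
  cat(sprintf("gw_rdf (%s site): %d bins, n(%.2f A) = %.3f\n",
              x$site, nrow(x$table), x$cutoff, x$n_at_cutoff))
  invisible(x)
}

#' Write an RDF table as CSV
#' @param rdf a [compute_rdf()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rdf_csv <- function(rdf, path) {
  utils::write.csv(rdf$table, path, row.names = FALSE)
  invisible(path)
}
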
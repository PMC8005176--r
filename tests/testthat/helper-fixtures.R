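# In-code fixture builders shared by the tests.

# Parameter table for one 1-atom solute plus nw TIP3P-like waters.
fix_atoms <- function(nw, solute_charge = 0, solute_sigma = 0,
                      solute_epsilon = 0) {
  n <- 1L + 3L * nw
  data.frame(
    index = 0:(n - 1L),
    name = c("C1", rep(c("O", "H1", "H2"), nw)),
    element = c("C", rep(c("O", "H", "H"), nw)),
    charge = c(solute_charge, rep(c(-0.834, 0.417, 0.417), nw)),
    sigma = c(solute_sigma, rep(c(3.15061, 0, 0), nw)),
    epsilon = c(solute_epsilon, rep(c(0.1521, 0, 0), nw)),
    residue_id = c(1L, rep(1L + seq_len(nw), each = 3)),
    residue_name = c("LIG", rep("HOH", 3 * nw)),
    is_solute = c(TRUE, rep(FALSE, 3 * nw)))
}

# Rigid TIP3P-like water sites (O, H1, H2) at oxygen position `o`, rotated
# by matrix R; geometry written out explicitly, independent of the package.
water_sites_at <- function(o, R = diag(3)) {
  half <- (104.5 / 2) * pi / 180
  b <- rbind(c(0, 0, 0),
             0.9572 * c(sin(half), 0, cos(half)),
             0.9572 * c(-sin(half), 0, cos(half)))
  sweep(t(R %*% t(b)), 2, o, "+")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Trajectory with one fixed solute atom at `solute_pos` and per-frame water
# site lists; `waters[[f]]` is a list of 3x3 site matrices.
fix_traj <- function(waters, solute_pos = c(0, 0, 0), box = NULL,
                     atoms = NULL) {
  n_frames <- length(waters)
  nw <- length(waters[[1]])
  if (is.null(atoms)) atoms <- fix_atoms(nw)
  coords <- array(NA_real_, c(1 + 3 * nw, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[1, , f] <- solute_pos
    for (w in seq_len(nw))
      coords[1 + (w - 1) * 3 + 1:3, , f] <- waters[[f]][[w]]
  }
  gw_trajectory(gw_topology(atoms), coords, box = box)
}

# A canonical small 3-hotspot synthetic run shared between expensive tests
# (memoised within the session).
fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}
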
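#' Distance class of a placed water
#'
#' Minimum distance from the placed oxygen to any solute atom, classified
#' as `near` (d < 3 Angstrom, first solvation shell at hydrophilic sites),
#' `mid` (3 <= d < 6, second shell or first shell at hydrophobic sites) or
#' `bulk` (d >= 6, essentially non-interacting).  Boundaries go to the
#' outer class.
#'
#' @param o_pos placed oxygen position, xyz.
#' @param solute_xyz solute coordinates, n x 3 matrix.
#' @param thresholds the two class boundaries in Angstrom, default
#'   `c(3, 6)`.
#' @return character scalar with attribute `distance` (Angstrom).
#' @export
classify_distance <- function(o_pos, solute_xyz, thresholds = c(3, 6)) {
  solute_xyz <- matrix(solute_xyz, ncol = 3)
  if (nrow(solute_xyz) == 0) stop("empty solute")
  d <- min(sqrt(rowSums(sweep(solute_xyz, 2, o_pos, "-")^2)))
  cls <- if (d < thresholds[1]) "near" else
    if (d < thresholds[2]) "mid" else "bulk"
  attr(cls, "distance") <- d
  cls
}

#' Rank placed waters by solvation free energy
#'
#' Sorts ascending by `delta_a` (most favourable first); ties are broken
#' by smaller distance to the solute, then by placement order.  Each water
#' is assigned its distance class.
#'
#' @param placed data.frame of oriented placements ([orient_waters()])
#'   with a `delta_a` column.
#' @param solute_xyz solute coordinates, n x 3.
#' @param thresholds distance-class boundaries, Angstrom.
#' @return Object of class `gw_ranking`: the placement table ordered by
#'   rank with columns `rank`, `delta_a`, `distance`, `class` added.
#' @export
rank_waters <- function(placed, solute_xyz, thresholds = c(3, 6)) {
  stopifnot(!is.null(placed$delta_a))
  solute_xyz <- matrix(solute_xyz, ncol = 3)
  n <- nrow(placed)
  dist <- numeric(n)
  cls <- character(n)
  for (p in seq_len(n)) {
    c1 <- classify_distance(c(placed$ox[p], placed$oy[p], placed$oz[p]),
                            solute_xyz, thresholds)
    dist[p] <- attr(c1, "distance")
    cls[p] <- c1
  }
  placed$distance <- dist
  placed$class <- cls
  ord <- order(placed$delta_a, placed$distance, seq_len(n))
  placed <- placed[ord, , drop = FALSE]
  placed$rank <- seq_len(n)
  rownames(placed) <- NULL
  structure(list(waters = placed, thresholds = thresholds,
                 solute_xyz = solute_xyz),
            class = "gw_ranking")
}

#' @export
print.gw_ranking <- function(x, ...) {
  tb <- table(factor(x$waters$class, levels = c("near", "mid", "bulk")))
  cat(sprintf("gw_ranking: %d waters (%d near, %d mid, %d bulk)\n",
              nrow(x$waters), tb["near"], tb["mid"], tb["bulk"]))
  if (nrow(x$waters) > 0)
    cat(sprintf("  best delta_a %.2f kcal/mol at %.2f A\n",
                x$waters$delta_a[1], x$waters$distance[1]))
  invisible(x)
}

gw_class_colors <- c(near = "orange", mid = "blue", bulk = "red")

#' Export the ranking bar-chart data as CSV
#'
#' One row per placed water with `rank`, `delta_a` (bar height),
#' `distance`, `class` and the class colour (near = orange, mid = blue,
#' bulk = red).
#'
#' @param ranking a [rank_waters()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_chart <- function(ranking, path) {
  w <- ranking$waters
  if (nrow(w) == 0) stop("empty ranking")
  df <- data.frame(rank = w$rank, delta_a = w$delta_a,
                   distance = w$distance, class = w$class,
                   color = unname(gw_class_colors[w$class]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bar chart of the ranked waters
#'
#' Static version of the selection chart: bar height is the solvation free
#' energy, colour encodes the distance class.
#'
#' @param x a [rank_waters()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.gw_ranking <- function(x, ...) {
  w <- x$waters
  graphics::barplot(w$delta_a, names.arg = w$rank,
                    col = gw_class_colors[w$class], border = NA,
                    xlab = "rank", ylab = "delta A (kcal/mol)", ...)
  graphics::legend("bottomright", legend = names(gw_class_colors),
                   fill = gw_class_colors, bty = "n")
  invisible(x)
}

#' Write the full placement table as CSV
#'
#' Rank, free energy, distance, class, O and H coordinates and the
#' contributing-voxel list (`i,j,k:count` items separated by `;`).
#'
#' @param ranking a [rank_waters()] result.
#' @param alloc the matching [allocate_oxygens()] result (for the
#'   contributing voxels); optional.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_placement_csv <- function(ranking, path, alloc = NULL) {
  w <- ranking$waters
  df <- data.frame(rank = w$rank, delta_a = w$delta_a,
                   distance = w$distance, class = w$class,
                   ox = w$ox, oy = w$oy, oz = w$oz,
                   h1x = w$h1x, h1y = w$h1y, h1z = w$h1z,
                   h2x = w$h2x, h2y = w$h2y, h2z = w$h2z,
                   fallback = w$fallback)
  if (!is.null(alloc)) {
    df$contributing_voxels <- vapply(w$id, function(id) {
      ct <- alloc$contributions[[id]]
      paste(sprintf("%d %d %d:%g", ct$i, ct$j, ct$k, ct$count),
            collapse = ";")
    }, character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a microsolvated solute-water cluster as PDB
#'
#' The solute followed by the top-`n` ranked waters (residue `HOH`, atoms
#' O/H1/H2), as a single-structure PDB readable by standard viewers.
#' Alternatively a selection rule can be given: a `delta_a` ceiling and/or
#' an allowed set of distance classes.
#'
#' @param ranking a [rank_waters()] result.
#' @param traj the source trajectory (solute atoms and names).
#' @param path output PDB path.
#' @param n number of top-ranked waters to keep (0 allowed); ignored when
#'   `delta_a_max` or `classes` is given.
#' @param delta_a_max keep only waters with `delta_a <=` this ceiling.
#' @param classes keep only waters in these distance classes.
#' @return `path` invisibly, with attribute `n_waters`.
#' @export
select_and_write_cluster <- function(ranking, traj, path, n = NULL,
                                     delta_a_max = NULL, classes = NULL) {
  w <- ranking$waters
  if (!is.null(delta_a_max) || !is.null(classes)) {
    keep <- rep(TRUE, nrow(w))
    if (!is.null(delta_a_max)) keep <- keep & w$delta_a <= delta_a_max
    if (!is.null(classes)) keep <- keep & w$class %in% classes
    w <- w[keep, , drop = FALSE]
  } else {
    if (is.null(n)) stop("give n or a selection rule")
    if (n < 0 || n > nrow(w)) stop("n out of range 0..", nrow(w))
    w <- w[seq_len(n), , drop = FALSE]
  }
  at <- traj$topology$atoms[traj$topology$solute_idx, , drop = FALSE]
  sxyz <- solute_coords(traj)
  nw <- nrow(w)
  xyz <- rbind(sxyz,
               do.call(rbind, lapply(seq_len(nw), function(p) rbind(
                 c(w$ox[p], w$oy[p], w$oz[p]),
                 c(w$h1x[p], w$h1y[p], w$h1z[p]),
                 c(w$h2x[p], w$h2y[p], w$h2z[p])))))
  resno <- c(at$residue_id,
             rep(max(at$residue_id) + seq_len(nw), each = 3))
  resid <- c(at$residue_name, rep("HOH", 3 * nw))
  elety <- c(at$name, rep(c("O", "H1", "H2"), nw))
  elesy <- c(at$element, rep(c("O", "H", "H"), nw))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = resno, resid = resid, elety = elety,
                   elesy = elesy, chain = rep("A", length(resno)))
  out <- invisible(path)
  attr(out, "n_waters") <- nw
  out
}
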
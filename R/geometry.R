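# Small geometry helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at a vertex between two points
#'
#' Returns the angle a-vertex-b in degrees, the convention used for the
#' H-O-H angle of a placed water.
#'
#' @param a,vertex,b numeric xyz vectors in Angstrom.
#' @return angle in degrees.
#' @export
vertex_angle <- function(a, vertex, b) {
  u <- unit(a - vertex)
  v <- unit(b - vertex)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Rotation matrix for a rotation of `angle` radians about unit axis `axis`
# (Rodrigues formula).
rotation_matrix <- function(axis, angle) {
  a <- unit(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation matrix (columns = body axes in the lab frame) -> unit quaternion
# (w, x, y, z) with w >= 0.  Shepperd's method, numerically safe.
mat2quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q <- q / vnorm(q)
  if (q[1] < 0) q <- -q
  q
}

quat2mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Angular distance between two orientations
#'
#' The minimal rotation angle taking one orientation into the other,
#' `2 * acos(|q1 . q2|)`, in radians within `[0, pi]`.  This is the
#' orientational nearest-neighbour metric used by the entropy estimator.
#'
#' @param q1,q2 unit quaternions as length-4 numeric vectors (w, x, y, z).
#' @return angle in radians.
#' @export
quat_angle <- function(q1, q2) {
  2 * acos(min(1, abs(sum(q1 * q2))))
}

#' Orientation quaternion of a rigid water
#'
#' Defines a body frame from the three sites: z along the O->H bisector, x
#' along the H1-H2 difference (orthogonalised against z), y completing the
#' right-handed frame.  The two hydrogens are first put into a canonical
#' order (lexicographic by x, then y, then z coordinate) so that the C2v
#' symmetry of water cannot make two physically identical orientations map
#' to different quaternions.
#'
#' @param o,h1,h2 xyz positions of the oxygen and the two hydrogens.
#' @return unit quaternion (w, x, y, z) with non-negative scalar part.
#' @export
water_quaternion <- function(o, h1, h2) {
  swap <- (h1[1] > h2[1]) ||
    (h1[1] == h2[1] && (h1[2] > h2[2] ||
                          (h1[2] == h2[2] && h1[3] > h2[3])))
  if (swap) { tmp <- h1; h1 <- h2; h2 <- tmp }
  z <- unit(unit(h1 - o) + unit(h2 - o))
  u <- h1 - h2
  x <- unit(u - sum(u * z) * z)
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  mat2quat(cbind(x, y, z))
}

# Site coordinates of a rigid water in its body frame: O at origin, the
# H-O-H bisector along +z, hydrogens in the xz-plane.
water_body_sites <- function(model) {
  half <- deg2rad(model$hoh_angle_eq) / 2
  o <- c(0, 0, 0)
  h1 <- model$oh_length * c(sin(half), 0, cos(half))
  h2 <- model$oh_length * c(-sin(half), 0, cos(half))
  rbind(o = o, h1 = h1, h2 = h2)
}

# Random unit quaternion (uniform over rotations).
random_quaternion <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  if (q[1] < 0) q <- -q
  q
}

# Minimum-image displacement components.  `d` is a numeric vector/matrix of
# raw coordinate differences along one axis, `edge` the box edge.
min_image <- function(d, edge) {
  d - edge * round(d / edge)
}
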
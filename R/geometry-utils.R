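# Small 3D vector helpers shared across the package. Points are numeric
# length-3 vectors (mm); point sets are n x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) {
    abort(sprintf("degenerate %s: zero or non-finite length", what),
          class = "hipmorph_degenerate")
  }
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary unit axis
#'
#' Right-handed (counter-clockwise looking down the axis toward the origin)
#' rotation by `angle_deg` degrees about `axis`, via the Rodrigues formula.
#'
#' @param axis numeric length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return A 3 x 3 proper rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  u <- unitize(axis, "rotation axis")
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, -u[3], u[2],
                u[3], 0, -u[1],
                -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Apply rotation R about a pivot point to an n x 3 matrix of points.
rotate_points <- function(pts, R, pivot = c(0, 0, 0)) {
  pts <- as_point_matrix(pts)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, "+")
}

as_point_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) abort("points must have 3 columns (x, y, z)")
  dimnames(x) <- NULL
  x
}

# Best-fit plane of an n x 3 point set: list(centroid, normal) with the
# normal the smallest singular vector (unsigned).
best_fit_plane <- function(pts) {
  pts <- as_point_matrix(pts)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3], sv = sv$d)
}
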
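#' Femoral head sphere
#'
#' @param center numeric length-3 center (mm).
#' @param radius positive radius (mm).
#' @param rms optional fit residual RMS (mm).
#' @param n optional number of points the sphere was fitted to.
#' @return An object of class `head_sphere`.
#' @export
head_sphere <- function(center, radius, rms = NA_real_, n = NA_integer_) {
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center))) {
    abort("center must be a finite length-3 point", class = "hipmorph_schema")
  }
  if (!is.finite(radius) || radius <= 0) {
    abort("radius must be positive and finite", class = "hipmorph_schema")
  }
  structure(list(center = center, radius = radius, rms = rms, n = n),
            class = "head_sphere")
}

#' @export
print.head_sphere <- function(x, ...) {
  cat(sprintf("<head_sphere> center (%.3f, %.3f, %.3f) mm, radius %.3f mm",
              x$center[1], x$center[2], x$center[3], x$radius))
  if (is.finite(x$rms)) cat(sprintf(", fit RMS %.4g mm (n = %d)", x$rms, x$n))
  cat("\n")
  invisible(x)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a 3D point cloud: an algebraic (Kasa) linear fit provides
#' the starting values, followed by Gauss-Newton refinement of the geometric
#' objective `sum((|p - c| - r)^2)`. Deterministic for a fixed input.
#'
#' @param points an n x 3 matrix (or data frame with x, y, z columns) of
#'   points in mm, n >= 4, not all coplanar.
#' @return A [head_sphere()] with `rms` (root-mean-square orthogonal
#'   residual, mm) and `n` filled in.
#' @examples
#' dirs <- matrix(rnorm(300), ncol = 3)
#' dirs <- dirs / sqrt(rowSums(dirs^2))
#' fit_head_sphere(sweep(24 * dirs, 2, c(10, -20, 5), "+"))
#' @export
fit_head_sphere <- function(points) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < 4) {
    abort("sphere fit needs at least 4 points", class = "hipmorph_degenerate")
  }
  # Algebraic fit: |p|^2 = 2 p.c + (r^2 - |c|^2), linear in (c, k).
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sv <- svd(A)
  if (sv$d[4] < 1e-10 * sv$d[1]) {
    abort("sphere fit is degenerate: points are coplanar or otherwise rank-deficient",
          class = "hipmorph_degenerate")
  }
  beta <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  ctr <- beta[1:3]
  r2 <- beta[4] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0) {
    abort("sphere fit failed: non-positive squared radius", class = "hipmorph_degenerate")
  }
  r <- sqrt(r2)

  # Gauss-Newton on the geometric residuals.
  for (it in seq_len(50)) {
    d <- sweep(pts, 2, ctr)
    dist <- sqrt(rowSums(d^2))
    if (any(dist < 1e-9)) break
    res <- dist - r
    J <- cbind(-d / dist, -1)
    step <- tryCatch(solve(crossprod(J), -crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    ctr <- ctr + step[1:3]
    r <- r + step[4]
    if (max(abs(step)) < 1e-12 * max(r, 1)) break
  }
  dist <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  head_sphere(ctr, r, rms = sqrt(mean((dist - r)^2)), n = n)
}

#' Acetabular rim curve
#'
#' An ordered, closed polyline of at least 12 points on (or near) the femoral
#' head sphere, tracing the acetabular rim.
#'
#' @param points an n x 3 matrix (or data frame) of rim points in mm, in
#'   curve order; the closing edge from the last to the first point is
#'   implicit.
#' @return An object of class `rim_curve`.
#' @export
rim_curve <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 12) {
    abort("rim curve needs at least 12 points", class = "hipmorph_schema")
  }
  if (any(!is.finite(pts))) {
    abort("rim curve contains non-finite coordinates", class = "hipmorph_schema")
  }
  structure(list(points = pts, closed = TRUE), class = "rim_curve")
}

#' Arc-length uniform rim resampling
#'
#' Resamples the closed rim polyline at `n` stations equally spaced in
#' cumulative chord length, wrapping the closing edge. Total arc length is
#' preserved to well within 0.1 percent for smooth rims.
#'
#' @param rim a [rim_curve()].
#' @param n number of output points, >= 12.
#' @return A [rim_curve()] with `n` points.
#' @export
resample_rim <- function(rim, n) {
  stopifnot(inherits(rim, "rim_curve"))
  if (n < 12) abort("resample_rim needs n >= 12", class = "hipmorph_schema")
  pts <- rbind(rim$points, rim$points[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) abort("rim curve has zero length", class = "hipmorph_degenerate")
  target <- seq(0, total, length.out = n + 1)[-(n + 1)]
  out <- vapply(1:3, function(j) approx(s, pts[, j], xout = target)$y,
                numeric(n))
  rim_curve(matrix(out, ncol = 3))
}

rim_arc_length <- function(rim) {
  pts <- rbind(rim$points, rim$points[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Orient a rim counter-clockwise as seen from the superior (+z of the neutral
# frame) direction, using the polygon's area-vector sign.
orient_rim_ccw <- function(rim, z_axis) {
  pts <- rim$points
  ctr <- colMeans(pts)
  q <- sweep(pts, 2, ctr)
  qn <- rbind(q[-1, , drop = FALSE], q[1, , drop = FALSE])
  area_vec <- c(
    sum(q[, 2] * qn[, 3] - q[, 3] * qn[, 2]),
    sum(q[, 3] * qn[, 1] - q[, 1] * qn[, 3]),
    sum(q[, 1] * qn[, 2] - q[, 2] * qn[, 1])
  ) / 2
  if (sum(area_vec * z_axis) < 0) rim$points <- rim$points[nrow(pts):1, ]
  rim
}

#' One hip: head sphere, rim curve, landmarks, metadata
#'
#' The central container of the pipeline. The neutral (default-posture)
#' pelvic frame is built from the landmarks at construction time and kept as
#' the fixed reference in which all measurements are expressed; [apply_pose()]
#' rotates the pelvic structures but never this reference.
#'
#' @param side `"left"` or `"right"`.
#' @param sex `"male"`, `"female"`, or `"unknown"`.
#' @param sphere a [head_sphere()].
#' @param rim a [rim_curve()]; re-oriented counter-clockwise viewed from
#'   superior on construction.
#' @param landmarks a [landmark_set()].
#' @param hip_id optional identifier string.
#' @param subject_id optional subject identifier.
#' @param mesh_ref optional path to the surface mesh the sphere was fitted to.
#' @param tol_rim rim-on-sphere tolerance as a fraction of the head radius
#'   (default 0.02).
#' @return An object of class `hip_model`.
#' @export
hip_model <- function(side, sex = "unknown", sphere, rim, landmarks,
                      hip_id = NULL, subject_id = NULL, mesh_ref = NULL,
                      tol_rim = 0.02) {
  side <- match.arg(side, c("left", "right"))
  sex <- match.arg(sex, c("male", "female", "unknown"))
  stopifnot(inherits(sphere, "head_sphere"), inherits(rim, "rim_curve"))
  landmarks <- validate_landmark_set(landmarks)
  frame <- build_app_frame(landmarks)

  dist <- abs(sqrt(rowSums(sweep(rim$points, 2, sphere$center)^2)) - sphere$radius)
  worst <- which.max(dist)
  if (dist[worst] > tol_rim * sphere$radius) {
    abort(sprintf(
      "rim point %d lies %.3f mm off the head sphere (tolerance %.3f mm)",
      worst, dist[worst], tol_rim * sphere$radius), class = "hipmorph_validation")
  }
  hc <- landmarks[[paste0("head_center_", side)]]
  if (vnorm(hc - sphere$center) >= sphere$radius) {
    abort(sprintf(
      "side mismatch: fitted head center is %.1f mm from the %s-side landmark (radius %.1f mm)",
      vnorm(hc - sphere$center), side, sphere$radius), class = "hipmorph_validation")
  }
  rim <- orient_rim_ccw(rim, frame$z_axis)

  structure(
    list(hip_id = hip_id %||% paste0(side, "_hip"), subject_id = subject_id,
         side = side, sex = sex, sphere = sphere, rim = rim,
         landmarks = landmarks, frame = frame, mesh_ref = mesh_ref,
         app_tilt_deg = 0),
    class = "hip_model"
  )
}

#' @export
print.hip_model <- function(x, ...) {
  cat(sprintf("<hip_model> %s: %s %s hip, %d rim points, tilt %+g deg\n",
              x$hip_id, x$sex, x$side, nrow(x$rim$points), x$app_tilt_deg))
  print(x$sphere)
  invisible(x)
}

side_sign <- function(model) if (model$side == "right") 1 else -1
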
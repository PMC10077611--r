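#' Pelvic landmark set
#'
#' Bundles the five landmarks the pipeline needs: both anterior superior iliac
#' spines (ASIS), the midpoint of the pubic tubercles, and both femoral head
#' centers. The first three define the anterior pelvic plane (APP); the head
#' centers anchor the inter-head axis about which pelvic tilt is applied.
#'
#' @param asis_left,asis_right,pubic_mid,head_center_left,head_center_right
#'   numeric length-3 points in mm.
#' @return An object of class `landmark_set` (named list of points).
#' @examples
#' lm <- landmark_set(
#'   asis_left = c(-120, 0, 0), asis_right = c(120, 0, 0),
#'   pubic_mid = c(0, 0, -80),
#'   head_center_left = c(-90, -10, -60), head_center_right = c(90, -10, -60)
#' )
#' build_app_frame(lm)
#' @export
landmark_set <- function(asis_left, asis_right, pubic_mid,
                         head_center_left, head_center_right) {
  lm <- list(
    asis_left = as.numeric(asis_left),
    asis_right = as.numeric(asis_right),
    pubic_mid = as.numeric(pubic_mid),
    head_center_left = as.numeric(head_center_left),
    head_center_right = as.numeric(head_center_right)
  )
  bad <- names(lm)[vapply(lm, function(p) length(p) != 3 || any(!is.finite(p)), logical(1))]
  if (length(bad)) {
    abort(paste0("landmarks must be finite length-3 points; offending: ",
                 paste(bad, collapse = ", ")), class = "hipmorph_schema")
  }
  validate_landmark_set(structure(lm, class = "landmark_set"))
}

validate_landmark_set <- function(lm) {
  scale <- max(vnorm(lm$asis_right - lm$asis_left), 1)
  n <- cross3(lm$asis_right - lm$asis_left, lm$pubic_mid - lm$asis_left)
  if (vnorm(n) < 1e-8 * scale^2) {
    abort("APP landmarks (ASIS pair and pubic midpoint) are collinear: plane is degenerate",
          class = "hipmorph_degenerate")
  }
  if (vnorm(lm$head_center_right - lm$head_center_left) < 1e-8 * scale) {
    abort("femoral head centers coincide: inter-head axis is degenerate",
          class = "hipmorph_degenerate")
  }
  lm
}

#' Construct the APP-anchored pelvic coordinate frame
#'
#' Builds the default-posture coordinate system used by every measurement:
#' the X-axis runs along the line between the femoral head centers (left to
#' right), the Z-axis is the direction perpendicular to X lying in the APP
#' (signed superiorly), and the Y-axis completes the right-handed triad
#' (pointing anteriorly). The origin is the midpoint of the head centers.
#'
#' @param landmarks a [landmark_set()].
#' @return An object of class `pelvis_frame`: list with `origin`, unit axes
#'   `x_axis`, `y_axis`, `z_axis`, and `app_normal` (anterior-pointing unit
#'   normal of the APP).
#' @export
build_app_frame <- function(landmarks) {
  lm <- validate_landmark_set(landmarks)
  x_axis <- unitize(lm$head_center_right - lm$head_center_left, "inter-head axis")
  origin <- (lm$head_center_left + lm$head_center_right) / 2

  app_normal <- unitize(
    cross3(lm$asis_right - lm$asis_left, lm$pubic_mid - lm$asis_left),
    "APP normal"
  )
  # Anterior sign: the APP landmarks sit anterior to the inter-head line.
  app_centroid <- (lm$asis_left + lm$asis_right + lm$pubic_mid) / 3
  if (sum(app_normal * (app_centroid - origin)) < 0) app_normal <- -app_normal

  z_axis <- unitize(cross3(app_normal, x_axis), "Z axis")
  # Superior sign: toward the ASIS side of the pubic midpoint.
  asis_mid <- (lm$asis_left + lm$asis_right) / 2
  if (sum(z_axis * (asis_mid - lm$pubic_mid)) < 0) z_axis <- -z_axis
  y_axis <- cross3(z_axis, x_axis)

  structure(
    list(origin = origin, x_axis = x_axis, y_axis = y_axis, z_axis = z_axis,
         app_normal = app_normal),
    class = "pelvis_frame"
  )
}

#' @export
print.pelvis_frame <- function(x, ...) {
  cat("<pelvis_frame>\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) mm\n", x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(sprintf("  %s: (%+.4f, %+.4f, %+.4f)\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  }
  invisible(x)
}

#' APP tilt pose
#'
#' Rotation of the pelvis about the inter-head axis (the frame's X-axis line
#' through the head-center midpoint). Positive angles tilt the pelvis
#' anteriorly: the superior axis tips toward the anterior axis
#' (`z_axis -> +y_axis` at +90 degrees). Both femoral head centers lie on the
#' rotation axis and are fixed points of every pose.
#'
#' @param frame a [build_app_frame()] result.
#' @param angle_deg tilt angle in degrees (positive = anterior/forward).
#' @return An object of class `tilt_pose`: list with `app_tilt_deg`,
#'   3 x 3 `rotation`, and `pivot`.
#' @export
make_tilt_pose <- function(frame, angle_deg) {
  stopifnot(inherits(frame, "pelvis_frame"))
  if (!is.numeric(angle_deg) || length(angle_deg) != 1 || !is.finite(angle_deg)) {
    abort("angle_deg must be a single finite number", class = "hipmorph_schema")
  }
  # Right-hand rotation about +x takes y toward z (posterior tilt); anterior
  # tilt is therefore rotation by -angle about +x.
  structure(
    list(app_tilt_deg = angle_deg,
         rotation = rotation_about_axis(frame$x_axis, -angle_deg),
         pivot = frame$origin),
    class = "tilt_pose"
  )
}

pose_points <- function(pts, pose) {
  rotate_points(pts, pose$rotation, pose$pivot)
}

pose_point <- function(p, pose) {
  drop(pose_points(matrix(p, 1), pose))
}

#' Apply an APP tilt pose to a hip model
#'
#' Rigidly rotates the pelvic structures (acetabular rim curve and pelvic
#' landmarks) by the pose. The femur stays in the default posture: the head
#' sphere's center lies on the rotation axis and is unchanged, and the
#' model's reference frame (`model$frame`) remains the neutral default-posture
#' frame in which all measurements are expressed.
#'
#' @param model a [hip_model()].
#' @param pose a [make_tilt_pose()] result.
#' @return The posed `hip_model`; `model$app_tilt_deg` accumulates the angle.
#' @export
apply_pose <- function(model, pose) {
  stopifnot(inherits(model, "hip_model"), inherits(pose, "tilt_pose"))
  model$rim$points <- pose_points(model$rim$points, pose)
  for (nm in c("asis_left", "asis_right", "pubic_mid",
               "head_center_left", "head_center_right")) {
    model$landmarks[[nm]] <- pose_point(model$landmarks[[nm]], pose)
  }
  model$sphere$center <- pose_point(model$sphere$center, pose)
  model$app_tilt_deg <- (model$app_tilt_deg %||% 0) + pose$app_tilt_deg
  model
}

#' Measurement configuration
#'
#' Tunable parameters of the tilt sweep and the three measurements.
#'
#' @param tilt_grid strictly increasing tilt angles in degrees; default
#'   -30 to +30 in 5-degree steps.
#' @param false_profile_deg false-profile rotation for the ACEA construction,
#'   in (0, 90); default 65.
#' @param physiologic_range the assumed physiologic APP tilt span in degrees;
#'   default `c(-10, 5)`.
#' @param rim_sampling_n number of arc-length-uniform rim samples used for
#'   extremal-point searches and coverage; >= 360, default 3600.
#' @param area_grid_resolution grid cell edge (mm) of the horizontal-plane
#'   area integration; default 0.15.
#' @return An object of class `measurement_config`.
#' @export
measurement_config <- function(tilt_grid = seq(-30, 30, by = 5),
                               false_profile_deg = 65,
                               physiologic_range = c(-10, 5),
                               rim_sampling_n = 3600,
                               area_grid_resolution = 0.15) {
  if (length(tilt_grid) < 1 || any(!is.finite(tilt_grid)) ||
      is.unsorted(tilt_grid, strictly = TRUE)) {
    abort("tilt_grid must be strictly increasing finite angles", class = "hipmorph_schema")
  }
  if (!(false_profile_deg > 0 && false_profile_deg < 90)) {
    abort("false_profile_deg must lie in (0, 90)", class = "hipmorph_schema")
  }
  if (rim_sampling_n < 360) {
    abort("rim_sampling_n must be >= 360", class = "hipmorph_schema")
  }
  if (!(area_grid_resolution > 0)) {
    abort("area_grid_resolution must be positive", class = "hipmorph_schema")
  }
  structure(
    list(tilt_grid = as.numeric(tilt_grid),
         false_profile_deg = false_profile_deg,
         physiologic_range = as.numeric(physiologic_range),
         rim_sampling_n = as.integer(rim_sampling_n),
         area_grid_resolution = area_grid_resolution),
    class = "measurement_config"
  )
}
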
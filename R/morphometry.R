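# Center-edge angles and horizontal-plane coverage. All measurements are
# expressed in the model's fixed default-posture frame (model$frame): the
# pelvis is tilted by apply_pose() while the cutting planes and the vertical
# reference stay put, which is what makes the measures tilt-dependent.

pick_extremal <- function(coords, score, tie_tol = 1e-9) {
  top <- which(score >= max(score) - tie_tol * max(1, abs(max(score))))
  top[which.max(coords[top, 3])]  # tie-break: more superior
}

#' Most laterally protruding rim point
#'
#' The rim point maximizing the signed lateral coordinate (positive x for
#' right hips, negative x for left hips) in the neutral frame; ties broken
#' superiorly. The maximized functional is linear, so the maximum over the
#' closed polyline is attained at a vertex and the search over the rim's
#' vertices is exact (resampling could only interpolate within chords).
#'
#' @param model a [hip_model()] in the pose to be measured.
#' @param config a [measurement_config()].
#' @return A length-3 point (mm, original coordinates).
#' @export
lateral_rim_point <- function(model, config = measurement_config()) {
  pts <- model$rim$points
  w <- sweep(pts, 2, model$sphere$center)
  fr <- model$frame
  coords <- cbind(w %*% fr$x_axis, w %*% fr$y_axis, w %*% fr$z_axis)
  idx <- pick_extremal(coords, side_sign(model) * coords[, 1])
  pts[idx, ]
}

#' Most anterolaterally protruding rim point
#'
#' The rim point maximizing the projection onto the false-profile direction
#' `u = s cos(fp) x + sin(fp) y` (s the laterality sign, fp the false-profile
#' angle, default 65 degrees); ties broken superiorly. As for
#' [lateral_rim_point()], the linear functional attains its maximum at a rim
#' vertex, so the vertex search is exact. With fp = 0 this reduces to
#' [lateral_rim_point()].
#'
#' @inheritParams lateral_rim_point
#' @return A length-3 point (mm, original coordinates).
#' @export
anterolateral_rim_point <- function(model, config = measurement_config()) {
  pts <- model$rim$points
  w <- sweep(pts, 2, model$sphere$center)
  fr <- model$frame
  coords <- cbind(w %*% fr$x_axis, w %*% fr$y_axis, w %*% fr$z_axis)
  fp <- deg2rad(config$false_profile_deg)
  score <- side_sign(model) * cos(fp) * coords[, 1] + sin(fp) * coords[, 2]
  idx <- pick_extremal(coords, score)
  pts[idx, ]
}

signed_edge_angle <- function(model, edge, lateral_dir_frame) {
  w <- edge - model$sphere$center
  fr <- model$frame
  wf <- c(sum(w * fr$x_axis), sum(w * fr$y_axis), sum(w * fr$z_axis))
  num <- sum(wf[1:2] * lateral_dir_frame[1:2])
  den <- wf[3]
  if (abs(num) < 1e-12 && abs(den) < 1e-12) {
    abort("undefined center-edge angle: edge coincides with the in-plane projection of the center",
          class = "hipmorph_degenerate")
  }
  rad2deg(atan2(num, den))
}

#' Lateral center-edge angle (LCEA)
#'
#' Angle, in the cutting plane parallel to the neutral-orientation APP through
#' the most lateral rim point, between the vertical reference (the neutral
#' superior axis) and the head-center-to-edge line: the in-plane angle after
#' dropping the plane-normal (neutral anterior) component of the center-edge
#' vector. Signed: positive when the edge is lateral to the vertical through
#' the center, negative (dysplastic) when medial.
#'
#' @inheritParams lateral_rim_point
#' @return Angle in degrees.
#' @export
measure_lcea <- function(model, config = measurement_config()) {
  e <- lateral_rim_point(model, config)
  signed_edge_angle(model, e, c(side_sign(model), 0, 0))
}

#' Anterior center-edge angle (ACEA)
#'
#' Angle, in the cutting plane parallel to the 65-degree-rotated APP
#' (false-profile orientation) through the most anterolateral rim point,
#' between the vertical reference and the head-center-to-edge line. Because
#' the dropped plane normal is orthogonal to both the vertical and the
#' false-profile direction, this reduces to
#' `atan2((e - c) . u, (e - c) . z)`.
#'
#' @inheritParams lateral_rim_point
#' @return Angle in degrees.
#' @export
measure_acea <- function(model, config = measurement_config()) {
  e <- anterolateral_rim_point(model, config)
  fp <- deg2rad(config$false_profile_deg)
  signed_edge_angle(model, e, c(side_sign(model) * cos(fp), sin(fp), 0))
}

#' Horizontal-plane acetabular coverage
#'
#' Fraction of the superior-hemisphere silhouette of the femoral head (a disk
#' of area pi r^2 in the neutral horizontal plane) covered by the acetabulum.
#' The covered region is the rim-bounded spherical region containing the cup
#' pole, clipped to the superior hemisphere before projection; overhang
#' beyond the equator silhouette adds no area. Computed by midpoint counting
#' on a deterministic horizontal grid (cell edge `config$area_grid_resolution`
#' mm), with the rim represented as a single-valued colatitude profile about
#' the cup axis (the signed best-fit rim-plane normal).
#'
#' @inheritParams lateral_rim_point
#' @return Coverage fraction in `[0, 1]`.
#' @export
compute_coverage <- function(model, config = measurement_config()) {
  fr <- model$frame
  ctr <- model$sphere$center
  r <- model$sphere$radius
  rim <- resample_rim(model$rim, config$rim_sampling_n)

  # Rim directions from the head center, in neutral-frame coordinates.
  d <- sweep(rim$points, 2, ctr)
  dn <- d / sqrt(rowSums(d^2))
  df <- cbind(dn %*% fr$x_axis, dn %*% fr$y_axis, dn %*% fr$z_axis)

  # Cup axis: best-fit rim plane normal, signed toward the cup pole side.
  pl <- best_fit_plane(df)
  axis <- pl$normal
  if (sum(axis * pl$centroid) < 0) axis <- -axis

  # In-cup basis about the axis.
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(ref - sum(ref * axis) * axis, "cup basis")
  e2 <- cross3(axis, e1)
  th_rim <- acos(pmin(1, pmax(-1, df %*% axis)))
  ps_rim <- atan2(df %*% e2, df %*% e1)
  o <- order(ps_rim)
  ps_rim <- ps_rim[o]
  th_rim <- th_rim[o]
  keep <- c(TRUE, diff(ps_rim) > 1e-12)
  ps_rim <- ps_rim[keep]
  th_rim <- th_rim[keep]
  if (length(ps_rim) < 3) {
    abort("rim collapses to a point or line about the cup axis", class = "hipmorph_degenerate")
  }

  # Midpoint grid over the superior-hemisphere silhouette (neutral x-y disk).
  h <- config$area_grid_resolution
  g <- seq(-r + h / 2, r - h / 2, by = h)
  gx <- rep(g, times = length(g))
  gy <- rep(g, each = length(g))
  in_disk <- gx * gx + gy * gy < r * r
  gx <- gx[in_disk]
  gy <- gy[in_disk]
  gz <- sqrt(pmax(0, r * r - gx * gx - gy * gy))
  # Unit directions of superior-hemisphere surface points, frame coordinates.
  q <- cbind(gx, gy, gz) / r
  th_q <- acos(pmin(1, pmax(-1, q %*% axis)))
  ps_q <- atan2(q %*% e2, q %*% e1)
  th_max <- approx(c(ps_rim - 2 * pi, ps_rim, ps_rim + 2 * pi),
                   rep(th_rim, 3), xout = ps_q)$y
  mean(th_q <= th_max)
}

#' Sweep a hip over the APP tilt grid
#'
#' Applies each tilt pose in `config$tilt_grid` to the neutral model and
#' measures LCEA, ACEA, and coverage at that pose. The neutral record equals
#' direct measurement of the unposed model.
#'
#' @param model a [hip_model()] in the neutral pose.
#' @param config a [measurement_config()].
#' @return A tibble of class `tilt_sweep` with columns `hip_id`,
#'   `subject_id`, `side`, `sex`, `app_tilt_deg`, `lcea_deg`, `acea_deg`,
#'   `coverage`, one row per grid angle, ordered by angle.
#' @examples
#' hip <- generate_hip(synthetic_hip_params(seed = 1))
#' tilt_sweep(hip, measurement_config(tilt_grid = c(-10, 0, 10),
#'                                    area_grid_resolution = 0.5))
#' @export
tilt_sweep <- function(model, config = measurement_config()) {
  stopifnot(inherits(model, "hip_model"))
  if (abs(model$app_tilt_deg) > 1e-9) {
    abort("tilt_sweep expects a model in the neutral pose", class = "hipmorph_validation")
  }
  rows <- purrr::map(config$tilt_grid, function(ang) {
    posed <- apply_pose(model, make_tilt_pose(model$frame, ang))
    tryCatch(
      tibble::tibble(
        app_tilt_deg = ang,
        lcea_deg = measure_lcea(posed, config),
        acea_deg = measure_acea(posed, config),
        coverage = compute_coverage(posed, config)
      ),
      error = function(e) {
        abort(sprintf("measurement failed at APP tilt %+g deg: %s",
                      ang, conditionMessage(e)), class = "hipmorph_validation")
      }
    )
  })
  out <- dplyr::bind_cols(
    tibble::tibble(hip_id = model$hip_id,
                   subject_id = model$subject_id %||% NA_character_,
                   side = model$side, sex = model$sex),
    dplyr::bind_rows(rows)
  )
  class(out) <- c("tilt_sweep", class(out))
  attr(out, "config") <- config
  out
}

#' Measure a list of hips over the tilt grid
#'
#' @param models list of [hip_model()]s.
#' @param config a [measurement_config()].
#' @return A `tilt_sweep` tibble with one row per hip and grid angle.
#' @export
measure_cohort <- function(models, config = measurement_config()) {
  out <- dplyr::bind_rows(purrr::map(models, tilt_sweep, config = config))
  class(out) <- c("tilt_sweep", class(out))
  attr(out, "config") <- config
  out
}

#' Pivot sweep results to the long cohort-table format
#'
#' @param sweep a `tilt_sweep` tibble (wide: one column per measure).
#' @return A long tibble with columns `hip_id`, `subject_id`, `side`, `sex`,
#'   `app_tilt_deg`, `measure` (`"acea"`, `"lcea"`, `"coverage"`), `value`.
#' @export
as_cohort_table <- function(sweep) {
  out <- tidyr::pivot_longer(
    tibble::as_tibble(sweep),
    cols = c("acea_deg", "lcea_deg", "coverage"),
    names_to = "measure", values_to = "value"
  )
  out$measure <- sub("_deg$", "", out$measure)
  out
}
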
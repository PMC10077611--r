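# Parametric synthetic hips with closed-form ground truth. The generator is
# the validation bed for the measurement engine: spherical femoral heads with
# a single-harmonic rim-colatitude modulation, which is (to first order) a
# circular rim on a cup axis tipped by the modulation amplitude toward the
# modulation phase.

canonical_landmarks <- function() {
  landmark_set(
    asis_left = c(-120, 0, 0), asis_right = c(120, 0, 0),
    pubic_mid = c(0, 0, -80),
    head_center_left = c(-90, -10, -60), head_center_right = c(90, -10, -60)
  )
}

#' Synthetic hip parameters
#'
#' Generative parameters for one parametric hip. The rim at azimuth `psi`
#' (measured from the lateral direction toward anterior) has colatitude
#' `theta(psi) = rim_colatitude_deg + rim_mod_amp_deg * cos(psi - rim_mod_phase_deg)`
#' plus independent per-point noise. The default phase of -90 degrees puts
#' the deepest rim posteriorly (anterior-wall deficiency), which tips the
#' equivalent cup axis posteriorly by about the modulation amplitude and
#' hence targets a coverage peak near `+rim_mod_amp_deg` of anterior APP
#' tilt.
#'
#' @param head_radius femoral head radius, mm.
#' @param rim_colatitude_deg mean rim colatitude theta0, degrees.
#' @param rim_mod_amp_deg azimuthal modulation amplitude A, degrees;
#'   `0 < theta0 - A` and `theta0 + A < 90` required.
#' @param rim_mod_phase_deg azimuth of maximum colatitude (deepest coverage),
#'   degrees from lateral toward anterior.
#' @param cup_tilt_deg rigid sagittal pre-tilt of the whole cup, degrees
#'   (positive anterior, same convention as the APP tilt).
#' @param rim_noise_deg SD of per-point colatitude jitter, degrees.
#' @param n_rim_points number of rim points (>= 12).
#' @param side `"right"` or `"left"`.
#' @param sex hip sex label.
#' @param seed integer seed (RNG state is restored afterwards); `NULL` uses
#'   the current RNG stream.
#' @return An object of class `synthetic_hip_params`.
#' @export
synthetic_hip_params <- function(head_radius = 24,
                                 rim_colatitude_deg = 40,
                                 rim_mod_amp_deg = 10,
                                 rim_mod_phase_deg = -90,
                                 cup_tilt_deg = 0,
                                 rim_noise_deg = 0.3,
                                 n_rim_points = 360,
                                 side = "right",
                                 sex = "unknown",
                                 seed = NULL) {
  if (!(head_radius > 0)) abort("head_radius must be positive", class = "hipmorph_schema")
  if (rim_mod_amp_deg < 0) abort("rim_mod_amp_deg must be >= 0", class = "hipmorph_schema")
  if (!(rim_colatitude_deg - rim_mod_amp_deg > 0 &&
        rim_colatitude_deg + rim_mod_amp_deg < 90)) {
    abort("rim colatitude +/- modulation must stay within (0, 90) degrees",
          class = "hipmorph_schema")
  }
  if (rim_noise_deg < 0) abort("rim_noise_deg must be >= 0", class = "hipmorph_schema")
  if (n_rim_points < 12) abort("n_rim_points must be >= 12", class = "hipmorph_schema")
  structure(
    list(head_radius = head_radius, rim_colatitude_deg = rim_colatitude_deg,
         rim_mod_amp_deg = rim_mod_amp_deg, rim_mod_phase_deg = rim_mod_phase_deg,
         cup_tilt_deg = cup_tilt_deg, rim_noise_deg = rim_noise_deg,
         n_rim_points = as.integer(n_rim_points),
         side = match.arg(side, c("right", "left")),
         sex = match.arg(sex, c("male", "female", "unknown")),
         seed = seed),
    class = "synthetic_hip_params"
  )
}

#' Generate one parametric hip
#'
#' Places the head sphere at the canonical head center for the requested
#' side, lays the rim about the superior cup axis with the single-harmonic
#' colatitude profile, applies the rigid cup pre-tilt, and attaches canonical
#' landmarks. Deterministic given `params$seed`.
#'
#' The ground-truth record (attribute `"ground_truth"`) stores the parameters,
#' the coverage-peak target tilt, and -- for the axisymmetric noiseless case
#' (A = noise = cup_tilt = 0) -- the closed-form neutral measurements
#' LCEA = ACEA = theta0 and coverage = sin^2(theta0).
#'
#' @param params a [synthetic_hip_params()].
#' @param hip_id,subject_id optional identifiers.
#' @return A [hip_model()]; ground truth in `attr(model, "ground_truth")`.
#' @export
generate_hip <- function(params, hip_id = NULL, subject_id = NULL) {
  stopifnot(inherits(params, "synthetic_hip_params"))
  lm <- canonical_landmarks()
  frame <- build_app_frame(lm)
  s <- if (params$side == "right") 1 else -1
  ctr <- lm[[paste0("head_center_", params$side)]]
  r <- params$head_radius

  psi <- seq(0, 2 * pi, length.out = params$n_rim_points + 1)[-(params$n_rim_points + 1)]
  noise <- if (params$rim_noise_deg > 0) {
    if (!is.null(params$seed)) {
      withr::with_seed(params$seed, rnorm(length(psi), 0, params$rim_noise_deg))
    } else {
      rnorm(length(psi), 0, params$rim_noise_deg)
    }
  } else {
    0
  }
  theta <- deg2rad(params$rim_colatitude_deg +
                     params$rim_mod_amp_deg * cos(psi - deg2rad(params$rim_mod_phase_deg)) +
                     noise)
  # Directions: azimuth 0 = lateral (s * x), +90 = anterior (y); pole = z.
  dirs <- outer(sin(theta) * cos(psi), s * frame$x_axis) +
    outer(sin(theta) * sin(psi), frame$y_axis) +
    outer(cos(theta), frame$z_axis)
  pts <- sweep(r * dirs, 2, ctr, "+")
  if (abs(params$cup_tilt_deg) > 0) {
    R <- rotation_about_axis(frame$x_axis, -params$cup_tilt_deg)
    pts <- rotate_points(pts, R, ctr)
  }

  model <- hip_model(
    side = params$side, sex = params$sex,
    sphere = head_sphere(ctr, r),
    rim = rim_curve(pts), landmarks = lm,
    hip_id = hip_id %||% paste0("synthetic_", params$side),
    subject_id = subject_id
  )
  axisym <- params$rim_mod_amp_deg == 0 && params$rim_noise_deg == 0 &&
    params$cup_tilt_deg == 0
  attr(model, "ground_truth") <- list(
    params = params,
    coverage_peak_tilt_deg =
      -params$rim_mod_amp_deg * sin(deg2rad(params$rim_mod_phase_deg)) -
      params$cup_tilt_deg,
    lcea_neutral_deg = if (axisym) params$rim_colatitude_deg else NA_real_,
    acea_neutral_deg = if (axisym) params$rim_colatitude_deg else NA_real_,
    coverage_neutral = if (axisym) sin(deg2rad(params$rim_colatitude_deg))^2 else NA_real_
  )
  model
}

#' Cohort specification
#'
#' Generative description of a bilateral cohort. Per-sex parameter
#' distributions are normal with the given means and SDs; bilateral subjects
#' share subject-level parameters, with the left hip mirrored and given small
#' independent jitter. The male-female difference in mean rim colatitude
#' (`sex_effect_deg`, default 3) is the generative sex effect: men larger in
#' all three measures.
#'
#' @param n_male_subjects,n_female_subjects subject counts (>= 1).
#' @param bilateral generate both hips per subject?
#' @param female_colatitude_deg female mean rim colatitude, degrees.
#' @param sex_effect_deg male mean colatitude minus female, degrees.
#' @param colatitude_sd_deg between-subject colatitude SD, degrees.
#' @param mod_amp_deg,mod_amp_sd_deg rim modulation amplitude mean and SD.
#' @param mod_phase_deg,mod_phase_sd_deg modulation phase mean (degrees;
#'   -90 = posterior) and SD.
#' @param head_radius_male,head_radius_female,head_radius_sd_mm head radius
#'   means and SD, mm.
#' @param rim_noise_deg per-point rim jitter SD, degrees.
#' @param bilateral_jitter_deg SD of the left-right colatitude jitter.
#' @param n_rim_points rim points per hip.
#' @param seed cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_male_subjects = 38, n_female_subjects = 33,
                        bilateral = TRUE,
                        female_colatitude_deg = 37, sex_effect_deg = 3,
                        colatitude_sd_deg = 5,
                        mod_amp_deg = 10, mod_amp_sd_deg = 2,
                        mod_phase_deg = -90, mod_phase_sd_deg = 8,
                        head_radius_male = 25, head_radius_female = 22,
                        head_radius_sd_mm = 1.2,
                        rim_noise_deg = 0.3,
                        bilateral_jitter_deg = 1,
                        n_rim_points = 360,
                        seed = 20230405) {
  if (n_male_subjects < 1 || n_female_subjects < 1) {
    abort("subject counts must be >= 1", class = "hipmorph_schema")
  }
  sds <- c(colatitude_sd_deg, mod_amp_sd_deg, mod_phase_sd_deg,
           head_radius_sd_mm, rim_noise_deg, bilateral_jitter_deg)
  if (any(sds < 0)) abort("SDs must be >= 0", class = "hipmorph_schema")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a bilateral synthetic cohort
#'
#' Draws per-subject parameters from the sex-specific distributions and
#' generates one or two hips per subject. Fully determined by `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `models` (list of [hip_model()]) and `ground_truth`
#'   (tibble of per-hip generative parameters).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_male_subjects = 2,
#'                                       n_female_subjects = 2, seed = 7))
#' length(cohort$models)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sexes <- c(rep("male", spec$n_male_subjects), rep("female", spec$n_female_subjects))
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

  build <- function() {
    models <- list()
    gt <- list()
    for (i in seq_along(sexes)) {
      sex <- sexes[i]
      subject_id <- sprintf("S%03d", i)
      theta0 <- rnorm(1, spec$female_colatitude_deg +
                        if (sex == "male") spec$sex_effect_deg else 0,
                      spec$colatitude_sd_deg)
      amp <- clamp(rnorm(1, spec$mod_amp_deg, spec$mod_amp_sd_deg), 0, 25)
      phase <- rnorm(1, spec$mod_phase_deg, spec$mod_phase_sd_deg)
      radius <- max(rnorm(1, if (sex == "male") spec$head_radius_male else
                            spec$head_radius_female,
                          spec$head_radius_sd_mm), 10)
      sides <- if (spec$bilateral) c("right", "left") else "right"
      for (side in sides) {
        th <- clamp(theta0 + if (side == "left" && spec$bilateral)
                      rnorm(1, 0, spec$bilateral_jitter_deg) else 0,
                    5 + amp, 85 - amp)
        am <- clamp(amp + if (side == "left" && spec$bilateral)
                      rnorm(1, 0, spec$bilateral_jitter_deg / 2) else 0,
                    0, min(th - 5, 84 - th))
        params <- synthetic_hip_params(
          head_radius = radius, rim_colatitude_deg = th,
          rim_mod_amp_deg = am, rim_mod_phase_deg = phase,
          rim_noise_deg = spec$rim_noise_deg,
          n_rim_points = spec$n_rim_points, side = side, sex = sex,
          seed = NULL
        )
        hip_id <- sprintf("%s_%s", subject_id, substr(side, 1, 1))
        model <- generate_hip(params, hip_id = hip_id, subject_id = subject_id)
        models[[hip_id]] <- model
        gt[[hip_id]] <- tibble::tibble(
          hip_id = hip_id, subject_id = subject_id, side = side, sex = sex,
          head_radius = radius, rim_colatitude_deg = th, rim_mod_amp_deg = am,
          rim_mod_phase_deg = phase, rim_noise_deg = spec$rim_noise_deg,
          coverage_peak_tilt_deg =
            attr(model, "ground_truth")$coverage_peak_tilt_deg
        )
      }
    }
    list(models = models, ground_truth = dplyr::bind_rows(gt))
  }

  if (!is.null(spec$seed)) withr::with_seed(spec$seed, build()) else build()
}
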
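# Independent oracle implementations for cross-checking the measurement
# engine. Deliberately coded along different routes than the package:
# explicit component matrices instead of Rodrigues, acos/sign instead of
# atan2, generative rim profiles instead of fitted cup axes.

DEG <- pi / 180

# Anterior-tilt rotation about +x (superior axis tips anteriorly for
# positive angles), as an explicit component matrix.
oracle_tilt_matrix <- function(angle_deg) {
  a <- -angle_deg * DEG
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

# Brute-force LCEA on a raw rim point matrix in canonical (identity-frame)
# coordinates: exhaustive lateral argmax, explicit projection, acos angle.
oracle_lcea <- function(rim_pts, center, s = 1) {
  w <- sweep(rim_pts, 2, center)
  i <- which.max(s * w[, 1])
  v <- w[i, ]
  v[2] <- 0  # drop the anterior (cut-plane normal) component
  ang <- acos(v[3] / sqrt(sum(v^2))) / DEG
  ang * sign(s * v[1])
}

# Brute-force ACEA: exhaustive argmax along the false-profile direction,
# explicit plane projection, acos angle signed by the false-profile side.
oracle_acea <- function(rim_pts, center, s = 1, fp_deg = 65) {
  u <- c(s * cos(fp_deg * DEG), sin(fp_deg * DEG), 0)
  nrm <- c(-s * sin(fp_deg * DEG), cos(fp_deg * DEG), 0)
  w <- sweep(rim_pts, 2, center)
  i <- which.max(w %*% u)
  v <- w[i, ] - sum(w[i, ] * nrm) * nrm
  ang <- acos(v[3] / sqrt(sum(v^2))) / DEG
  ang * sign(sum(v * u))
}

# Monte-Carlo coverage for a *generated* hip, using the generative rim
# profile (no fitted cup axis): samples the superior-hemisphere silhouette
# uniformly and tests colatitude about the posed generative cup frame.
oracle_coverage_mc <- function(params, tilt_deg = 0, n_mc = 200000, seed = 99) {
  stopifnot(params$rim_noise_deg == 0)
  s <- if (params$side == "right") 1 else -1
  M <- oracle_tilt_matrix(tilt_deg) %*% oracle_tilt_matrix(params$cup_tilt_deg)
  axis <- M %*% c(0, 0, 1)
  e1 <- M %*% c(s, 0, 0)
  e2 <- M %*% c(0, 1, 0)
  withr::with_seed(seed, {
    u <- matrix(stats::runif(2 * n_mc * 1.4, -1, 1), ncol = 2)
    u <- u[u[, 1]^2 + u[, 2]^2 < 1, , drop = FALSE][seq_len(n_mc), ]
  })
  q <- cbind(u, sqrt(1 - u[, 1]^2 - u[, 2]^2))
  th <- acos(pmin(1, pmax(-1, q %*% axis)))
  ps <- atan2(q %*% e2, q %*% e1)
  th_max <- (params$rim_colatitude_deg +
               params$rim_mod_amp_deg *
                 cos(ps - params$rim_mod_phase_deg * DEG)) * DEG
  mean(th <= th_max)
}

# Direct nonlinear least-squares sphere fit through stats::optim.
oracle_sphere_fit <- function(pts) {
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(pts, 2, p[1:3])^2))
    sum((d - p[4])^2)
  }
  ctr0 <- colMeans(pts)
  init <- c(ctr0, mean(sqrt(rowSums(sweep(pts, 2, ctr0)^2))))
  stats::optim(init, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))$par
}

# ICC(2,1) through the stats::aov mean-squares decomposition.
oracle_icc_aov <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  # anova() warns about F-tests on exact fits; only the mean squares are used
  av <- suppressWarnings(stats::anova(stats::aov(y ~ subj + rater, data = df)))
  msr <- av["subj", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Convenience builders -------------------------------------------------------

# Paired data with an exact sample Pearson correlation r.
make_cor_data <- function(r, n = 40, seed = 9) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    e <- rnorm(n)
  })
  x <- (x - mean(x)) / sd(x)
  e <- residuals(stats::lm(e ~ x))
  e <- e / sd(e)
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fib_sphere_points <- function(n = 100) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(1 - z^2)
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

axisym_hip <- function(theta_deg, r = 24, side = "right", n = 3600) {
  generate_hip(synthetic_hip_params(
    head_radius = r, rim_colatitude_deg = theta_deg,
    rim_mod_amp_deg = 0, rim_noise_deg = 0, n_rim_points = n, side = side
  ))
}

random_rigid_motion <- function() {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, 0, 50))
}

transform_hip <- function(model, R, t) {
  mv <- function(p) drop(R %*% p) + t
  lm <- model$landmarks
  lm2 <- landmark_set(mv(lm$asis_left), mv(lm$asis_right), mv(lm$pubic_mid),
                      mv(lm$head_center_left), mv(lm$head_center_right))
  hip_model(side = model$side, sex = model$sex,
            sphere = head_sphere(mv(model$sphere$center), model$sphere$radius),
            rim = rim_curve(sweep(model$rim$points %*% t(R), 2, t, "+")),
            landmarks = lm2, hip_id = model$hip_id)
}

mirror_hip <- function(model) {
  mv <- function(p) p * c(-1, 1, 1)
  lm <- model$landmarks
  lm2 <- landmark_set(mv(lm$asis_right), mv(lm$asis_left), mv(lm$pubic_mid),
                      mv(lm$head_center_right), mv(lm$head_center_left))
  hip_model(side = if (model$side == "right") "left" else "right",
            sex = model$sex,
            sphere = head_sphere(mv(model$sphere$center), model$sphere$radius),
            rim = rim_curve(model$rim$points %*% diag(c(-1, 1, 1))),
            landmarks = lm2, hip_id = model$hip_id)
}

fast_config <- function(...) {
  measurement_config(area_grid_resolution = 0.4, ...)
}
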
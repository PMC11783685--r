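## Synthetic skeletons and test-retest studies with known ground truth.
##
## A stick-figure skeleton (ankle-knee-hip-shoulder chain) is posed at an
## exactly known joint angle and projected through a pinhole camera standing
## at the protocol geometry (lens 55 cm above the floor, 2.05 m from the
## participant, 720p frame). The skeleton is posed in a plane parallel to
## the image plane — the lateral view for sagittal movements, the frontal
## view for rotations — so projection is a similarity transform and the
## pixel-space angle equals the requested angle exactly, which is what makes
## exhaustive round-trip testing possible. Gaussian pixel noise then
## emulates keypoint-detection error, and whole studies (participants x
## sessions x movements x methods) are generated with known between-subject,
## within-subject and measurement variance components.

#' Camera geometry of the standardized recording setup
#'
#' @param height_cm Lens height above the floor (protocol: 55).
#' @param distance_m Horizontal lens-participant distance (protocol: 2.05).
#' @param width_px,height_px Frame resolution (protocol: 1280x720).
#' @param hfov_deg Horizontal field of view in degrees. Default 78, a
#'   typical wide-angle webcam: narrower lenses cannot keep a standing
#'   adult's shoulder inside a 720p frame at 2.05 m.
#' @return A `camera_setup` list with the derived focal length in pixels.
#' @export
camera_setup <- function(height_cm = 55, distance_m = 2.05,
                         width_px = 1280, height_px = 720, hfov_deg = 78) {
  if (height_cm <= 0 || distance_m <= 0 || width_px <= 0 || height_px <= 0 ||
      hfov_deg <= 0 || hfov_deg >= 180) {
    abort_validation("camera dimensions must be positive (hfov in (0, 180))")
  }
  structure(list(
    height_cm = height_cm, distance_m = distance_m,
    width_px = width_px, height_px = height_px, hfov_deg = hfov_deg,
    focal_px = (width_px / 2) / tan(hfov_deg / 2 * pi / 180)
  ), class = "camera_setup")
}

# body segment lengths as fractions of stature (standard anthropometric
# tables; stature default matches a young-adult cohort mean)
#' Segment anthropometry of the simulated participant
#'
#' @param stature_cm Standing height; default 177.5.
#' @param trunk_frac,thigh_frac,shank_frac Segment lengths as fractions of
#'   stature (defaults 0.30, 0.245, 0.246).
#' @return An `anthropometry` list with segment lengths in meters.
#' @export
anthropometry <- function(stature_cm = 177.5, trunk_frac = 0.30,
                          thigh_frac = 0.245, shank_frac = 0.246) {
  if (stature_cm <= 0 || trunk_frac <= 0 || thigh_frac <= 0 || shank_frac <= 0) {
    abort_validation("anthropometry values must be positive")
  }
  h <- stature_cm / 100
  structure(list(stature_cm = stature_cm,
                 trunk_m = trunk_frac * h,
                 thigh_m = thigh_frac * h,
                 shank_m = shank_frac * h),
            class = "anthropometry")
}

# world (X lateral right, Y up from floor, meters) -> pixel coordinates;
# the whole skeleton sits in the fronto-parallel plane Z = distance
world_to_px <- function(xy, camera) {
  f <- camera$focal_px
  z <- camera$distance_m
  c(x = camera$width_px / 2 + f * xy[1] / z,
    y = camera$height_px / 2 - f * (xy[2] - camera$height_cm / 100) / z)
}

#' Project a posed skeleton to a pose frame at an exact joint angle
#'
#' Poses the standing skeleton so the requested movement reads exactly
#' `angle_deg` under the matching measurement geometry, then projects every
#' joint to pixels. Sagittal movements are posed in the lateral view (trunk
#' vertical for hip movements; thigh vertical for knee flexion), rotations
#' in the frontal view as an ankle displacement of the full shank with a
#' vertical drop of `shank * cos(theta)` — the 2D proxy for axial femoral
#' rotation that the right-triangle measurement actually sees.
#'
#' @param movement One of [rom_movements()].
#' @param angle_deg Requested true angle, inside [rom_angle_limits()].
#' @param anthropometry An [anthropometry()].
#' @param camera A [camera_setup()].
#' @param side Measured leg (flips the frontal-view displacement direction).
#' @param frame_index,timestamp Frame metadata.
#' @return A [pose_frame()] whose measured angle reproduces `angle_deg`
#'   exactly (before whole-degree rounding).
#' @export
project_skeleton <- function(movement, angle_deg,
                             anthropometry = poserom::anthropometry(),
                             camera = camera_setup(), side = "left",
                             frame_index = 0L, timestamp = 0) {
  movement <- match.arg(movement, rom_movements())
  lim <- rom_angle_limits()[[movement]]
  if (angle_deg < lim[1] || angle_deg > lim[2]) {
    abort_validation("%s angle %.1f outside anatomical range [%g, %g]",
                     movement, angle_deg, lim[1], lim[2])
  }
  a <- anthropometry
  b <- angle_deg * pi / 180
  # upright reference chain, world coords (X lateral/forward in-plane, Y up)
  ankle <- c(0, 0)
  knee  <- c(0, a$shank_m)
  hip   <- c(0, a$shank_m + a$thigh_m)
  shoulder <- c(0, a$shank_m + a$thigh_m + a$trunk_m)

  if (movement == "hip_flexion" || movement == "hip_extension") {
    dirx <- if (movement == "hip_flexion") 1 else -1
    knee <- hip + a$thigh_m * c(dirx * sin(b), -cos(b))
    ankle <- knee + c(0, -a$shank_m)          # shank hangs vertical
  } else if (movement == "knee_flexion") {
    ankle <- knee + a$shank_m * c(sin(b), -cos(b))
  } else {
    # frontal view: left-leg inner rotation displaces the ankle toward
    # image right (world +X), outer toward image left; mirrored on the right
    dirx <- if (movement == "hip_inner_rotation") 1 else -1
    if (side == "right") dirx <- -dirx
    ankle <- knee + a$shank_m * c(dirx * sin(b), -cos(b))
  }

  pts <- list(shoulder = shoulder, hip = hip, knee = knee, ankle = ankle)
  px <- lapply(pts, world_to_px, camera = camera)
  res <- c(camera$width_px, camera$height_px)
  for (j in names(px)) {
    if (px[[j]]["x"] < 0 || px[[j]]["x"] > res[1] ||
        px[[j]]["y"] < 0 || px[[j]]["y"] > res[2]) {
      abort_framing(
        "projected %s keypoint falls outside the %dx%d frame; widen hfov_deg or move the camera back",
        j, res[1], res[2])
    }
  }
  pose_frame(lapply(px, function(p) keypoint(p["x"], p["y"])),
             frame_index = frame_index, timestamp = timestamp,
             resolution = res)
}

#' Perturb keypoints with Gaussian detection noise
#'
#' Adds independent N(0, sigma_px^2) noise to every coordinate of every
#' keypoint, emulating keypoint-detector jitter. `sigma_px = 0` returns the
#' frame unchanged. Randomness comes from R's global RNG; seed upstream for
#' reproducibility.
#'
#' @param frame A [pose_frame()].
#' @param sigma_px Noise SD in pixels, `>= 0`.
#' @return The perturbed frame.
#' @export
add_detection_noise <- function(frame, sigma_px) {
  if (sigma_px < 0) abort_validation("sigma_px must be >= 0")
  if (sigma_px == 0) return(frame)
  frame$keypoints <- lapply(frame$keypoints, function(kp) {
    kp + stats::rnorm(2, 0, sigma_px)
  })
  frame
}

#' Default movement population parameters for simulated cohorts
#'
#' Anatomically plausible active-ROM population means and between-subject
#' SDs for healthy young adults (degrees). These are simulation defaults
#' documented by the package, not cohort estimates.
#'
#' @return Tibble with columns movement, mu, sigma_b.
#' @export
default_movement_params <- function() {
  tibble::tibble(
    movement = rom_movements(),
    mu      = c(105, 125, 18, 35, 33),
    sigma_b = c(10, 10, 6, 8, 8)
  )
}

#' Configuration of a simulated test-retest study
#'
#' @param n_participants Cohort size (protocol: 30).
#' @param movements Tibble with columns `movement`, `mu`, `sigma_b`
#'   (degrees); defaults to [default_movement_params()].
#' @param sigma_w Within-subject (session-to-session, 24 h) SD, degrees.
#' @param sigma_px Keypoint detection noise SD, pixels.
#' @param landmark_sigma_px Manual landmark placement noise SD, pixels.
#' @param landmark_offset_px Constant anatomical offset of reference
#'   landmarks from the detected joint centres, pixels along +x (probes
#'   systematic method bias; default 0).
#' @param side Measured leg.
#' @param anthropometry,camera Simulation geometry.
#' @param seed Integer seed; all randomness in [generate_study()] flows
#'   from it.
#' @return A `study_gen_config` list.
#' @export
study_gen_config <- function(n_participants = 30,
                             movements = default_movement_params(),
                             sigma_w = 3, sigma_px = 2,
                             landmark_sigma_px = 2, landmark_offset_px = 0,
                             side = "left",
                             anthropometry = poserom::anthropometry(),
                             camera = camera_setup(), seed = 1L) {
  if (any(c(sigma_w, sigma_px, landmark_sigma_px) < 0)) {
    abort_validation("noise SDs must be >= 0")
  }
  if (n_participants < 1) abort_validation("n_participants must be >= 1")
  if (!all(c("movement", "mu", "sigma_b") %in% names(movements))) {
    abort_validation("movements needs columns movement, mu, sigma_b")
  }
  if (any(movements$sigma_b < 0)) abort_validation("sigma_b must be >= 0")
  structure(list(
    n_participants = as.integer(n_participants), movements = movements,
    sigma_w = sigma_w, sigma_px = sigma_px,
    landmark_sigma_px = landmark_sigma_px,
    landmark_offset_px = landmark_offset_px, side = side,
    anthropometry = anthropometry, camera = camera, seed = as.integer(seed)
  ), class = "study_gen_config")
}

# draw from N(mu, sd) truncated to [lo, hi] by resampling; returns value and
# the number of rejected draws
draw_truncated <- function(mu, sd, lo, hi) {
  rejects <- 0L
  repeat {
    v <- stats::rnorm(1, mu, sd)
    if (v >= lo && v <= hi) return(list(value = v, rejects = rejects))
    rejects <- rejects + 1L
    if (rejects > 1000L) {
      abort_validation("cannot draw an anatomically possible angle for mu=%.1f sd=%.1f", mu, sd)
    }
  }
}

# Monte-Carlo estimate of the angle-domain SD induced by sigma_px of
# keypoint noise at a representative angle of the movement
estimate_angle_noise <- function(movement, angle_deg, sigma_px,
                                 anthropometry, camera, side = "left",
                                 n_draws = 2000) {
  if (sigma_px == 0) return(0)
  frame <- project_skeleton(movement, angle_deg, anthropometry, camera, side)
  needed <- movement_required_joints(movement)
  vals <- vapply(seq_len(n_draws), function(i) {
    nf <- add_detection_noise(frame, sigma_px)
    pts <- stats::setNames(lapply(needed, frame_keypoint, frame = nf), needed)
    movement_angle(movement, pts, side)
  }, numeric(1))
  stats::sd(vals)
}

# reference landmarks derived from the true (noiseless) joint pixel centres
reference_points_for <- function(movement, frame, offset_px, sigma_px) {
  joints <- movement_required_joints(movement)
  names_map <- movement_landmarks(movement)
  pts <- lapply(seq_along(joints), function(i) {
    kp <- frame$keypoints[[joints[i]]]
    keypoint(kp["x"] + offset_px + stats::rnorm(1, 0, sigma_px),
             kp["y"] + stats::rnorm(1, 0, sigma_px))
  })
  # joint roles map 1:1 onto the movement's landmark names:
  # sagittal hip: knee->epicondyle, hip->trochanter, shoulder->humeral head;
  # knee: hip->trochanter, knee->epicondyle, ankle->malleolus;
  # rotation: knee->patella midpoint, ankle->talocrural centre
  role_order <- switch(movement,
    hip_flexion   = ,
    hip_extension = c(knee = "lateral_femoral_epicondyle",
                      hip = "greater_trochanter", shoulder = "humeral_head"),
    knee_flexion  = c(hip = "greater_trochanter",
                      knee = "lateral_femoral_epicondyle",
                      ankle = "lateral_malleolus"),
    c(knee = "patella_midpoint", ankle = "talocrural_centre"))
  stats::setNames(pts, unname(role_order[joints]))
}

#' Generate a complete synthetic test-retest study
#'
#' Emulates the measurement protocol: each participant's true angle per
#' movement is drawn from N(mu, sigma_b^2); each session's realized angle
#' adds N(0, sigma_w^2) biological day-to-day variation; the app measurement
#' is the whole-degree reading of the noisy projected frame in both
#' sessions; the reference measurement (session 1 only, as in the validity
#' protocol) applies the landmark geometry to the same session-1 frame with
#' landmark placement noise. Draws falling outside the anatomical range are
#' re-sampled and counted; more than 1% re-sampling triggers a config
#' warning. Reference timestamps postdate all app timestamps, mirroring the
#' blinded workflow.
#'
#' @param config A [study_gen_config()].
#' @return List with `study` (the `study_table`) and `ground_truth` (latent
#'   angles, per-movement measurement-noise SD `sigma_meas`, theoretical ICC
#'   `sigma_b^2 / (sigma_b^2 + sigma_w^2 + sigma_meas^2)`, re-sample count,
#'   seed and config echo).
#' @export
generate_study <- function(config = study_gen_config()) {
  stopifnot(inherits(config, "study_gen_config"))
  set.seed(config$seed)
  lims <- rom_angle_limits()
  mv <- config$movements
  base_ts <- as.numeric(as.POSIXct("2024-01-08T09:00:00Z",
                                   format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  day <- 86400

  sigma_meas <- stats::setNames(vapply(seq_len(nrow(mv)), function(i) {
    estimate_angle_noise(mv$movement[i], mv$mu[i], config$sigma_px,
                         config$anthropometry, config$camera, config$side)
  }, numeric(1)), mv$movement)

  rows <- vector("list", config$n_participants * nrow(mv) * 3L)
  latents <- vector("list", config$n_participants * nrow(mv))
  frames_out <- list()
  landmark_rows <- list()
  resamples <- 0L
  r <- 0L; l <- 0L; fr <- 0L
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    for (i in seq_len(nrow(mv))) {
      m <- mv$movement[i]
      lim <- lims[[m]]
      d <- draw_truncated(mv$mu[i], mv$sigma_b[i], lim[1], lim[2])
      theta_true <- d$value; resamples <- resamples + d$rejects
      theta_s <- numeric(2)
      app_angle <- numeric(2)
      s1_frame <- NULL
      for (s in 1:2) {
        ds <- draw_truncated(theta_true, config$sigma_w, lim[1], lim[2])
        theta_s[s] <- ds$value; resamples <- resamples + ds$rejects
        ts <- base_ts + (s - 1) * day + (p - 1) * 600 + (i - 1) * 60
        frame <- project_skeleton(m, theta_s[s], config$anthropometry,
                                  config$camera, config$side,
                                  frame_index = 0L, timestamp = ts)
        noisy <- add_detection_noise(frame, config$sigma_px)
        rec <- measure_frame(noisy, m, side = config$side,
                             participant_id = pid, session = s)
        app_angle[s] <- rec$angle_deg
        r <- r + 1L; rows[[r]] <- rec
        noisy$frame_index <- fr
        fr <- fr + 1L
        frames_out[[fr]] <- noisy
        if (s == 1) s1_frame <- frame
      }
      # reference on the session-1 frame, performed after all app readings
      ref_pts <- reference_points_for(m, s1_frame, config$landmark_offset_px,
                                      config$landmark_sigma_px)
      ref <- reference_angle(landmark_set(m, ref_pts), side = config$side,
                             participant_id = pid, session = 1L,
                             timestamp = base_ts + 2 * day + (p - 1) * 600 + (i - 1) * 60)
      r <- r + 1L; rows[[r]] <- ref
      landmark_rows[[r]] <- tibble::tibble(
        participant_id = pid, session = 1L, movement = m,
        point_name = names(ref_pts),
        x_px = vapply(ref_pts, `[[`, numeric(1), "x"),
        y_px = vapply(ref_pts, `[[`, numeric(1), "y"),
        timestamp = ref$timestamp)
      l <- l + 1L
      latents[[l]] <- tibble::tibble(
        participant_id = pid, movement = m, theta_true = theta_true,
        theta_session1 = theta_s[1], theta_session2 = theta_s[2],
        app_session1 = app_angle[1], app_session2 = app_angle[2],
        reference_session1 = ref$angle_deg)
    }
  }
  total_draws <- config$n_participants * nrow(mv) * 3L
  if (resamples > 0.01 * total_draws) {
    warning(sprintf(
      "%d/%d latent draws re-sampled (>1%%): movement means/SDs sit close to anatomical limits",
      resamples, total_draws))
  }
  theo_icc <- mv$sigma_b^2 /
    (mv$sigma_b^2 + config$sigma_w^2 + sigma_meas[mv$movement]^2)
  list(
    study = study_table(dplyr::bind_rows(rows)),
    frames = frames_out,
    landmarks = dplyr::bind_rows(landmark_rows),
    ground_truth = list(
      seed = config$seed,
      latents = dplyr::bind_rows(latents),
      sigma_meas = sigma_meas,
      theoretical_icc = stats::setNames(theo_icc, mv$movement),
      n_resampled = resamples,
      config = config[c("n_participants", "sigma_w", "sigma_px",
                        "landmark_sigma_px", "landmark_offset_px", "side")]
    )
  )
}
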
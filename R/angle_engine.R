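## Joint-angle geometry on 2D pixel keypoints.
##
## Sagittal movements (hip flexion/extension, knee flexion) use a triangle of
## three keypoints: the interior angle alpha at the measured joint comes from
## the law of cosines and the reported range of motion is beta = 180 - alpha,
## so a straight (neutral) segment chain reads 0 degrees. Hip rotations use a
## right triangle between the knee, the ankle and the vertical pixel line
## dropped from the knee: theta = atan(|dx| / dy).

# tolerated floating-point excursion of the cosine outside [-1, 1]
.cos_clamp_tol <- 1e-12

seg_len <- function(p, q) sqrt(sum((p - q)^2))

#' Interior angle at a vertex by the law of cosines
#'
#' Computes the angle at `vertex` subtended by points `a` and `b`:
#' `alpha = acos((|v-a|^2 + |v-b|^2 - |a-b|^2) / (2 |v-a| |v-b|))`, in
#' degrees. The result lies in `[0, 180]` and is invariant to translation,
#' rotation and uniform scaling of the three points. The cosine is clamped
#' to `[-1, 1]` to absorb floating-point excursion up to 1e-12; a larger
#' excursion is an error.
#'
#' @param vertex,a,b Keypoints (named vectors `c(x=, y=)`, see [keypoint()]).
#' @return Angle in degrees.
#' @export
angle_at_vertex <- function(vertex, a, b) {
  la <- seg_len(vertex, a)
  lb <- seg_len(vertex, b)
  if (la == 0 || lb == 0) {
    abort_degenerate("zero-length limb segment: %s coincides with the vertex",
                     if (la == 0) "point a" else "point b")
  }
  lab <- seg_len(a, b)
  cosa <- (la^2 + lb^2 - lab^2) / (2 * la * lb)
  if (cosa > 1 + .cos_clamp_tol || cosa < -1 - .cos_clamp_tol) {
    abort_degenerate("cosine excursion %.3e exceeds tolerance; degenerate geometry",
                     abs(cosa) - 1)
  }
  cosa <- min(1, max(-1, cosa))
  acos(cosa) * 180 / pi
}

#' Hip sagittal range of motion (flexion / extension)
#'
#' The knee, hip and shoulder keypoints form a triangle; the interior angle
#' alpha at the hip between the hip-knee and hip-shoulder lines gives the
#' hip flexion or extension angle `beta = 180 - alpha`. Upright neutral
#' posture (collinear knee-hip-shoulder) reads 0.
#'
#' @param knee,hip,shoulder Keypoints.
#' @return ROM in degrees, in `[0, 180]`.
#' @export
hip_sagittal_rom <- function(knee, hip, shoulder) {
  180 - angle_at_vertex(hip, knee, shoulder)
}

#' Knee flexion range of motion
#'
#' The hip, knee and ankle keypoints form a triangle; the reported knee
#' flexion is `beta = 180 - alpha` with alpha the interior angle at the
#' knee. A straight leg reads 0.
#'
#' @param hip,knee,ankle Keypoints.
#' @return ROM in degrees, in `[0, 180]`.
#' @export
knee_flexion_rom <- function(hip, knee, ankle) {
  180 - angle_at_vertex(knee, hip, ankle)
}

#' Hip rotation angle from the frontal view
#'
#' A right triangle is formed by the knee, the ankle and the vertical pixel
#' line dropped from the knee: `theta = atan(|x_ankle - x_knee| /
#' (y_ankle - y_knee))` in degrees. The ankle must lie strictly below the
#' knee in the image (larger y). Unlike the sagittal angles, theta is
#' measured against the image vertical and is therefore deliberately NOT
#' invariant to rotating the frame.
#'
#' Direction convention (the protocol reports magnitudes; the label is a
#' package convention): for the left leg seen from the front, an ankle
#' displaced toward image right of the knee is labelled `"inner"`, toward
#' image left `"outer"`; mirrored for the right leg. A perfectly vertical
#' shank is `"neutral"`.
#'
#' @param knee,ankle Keypoints.
#' @param side `"left"` or `"right"` measured leg.
#' @return List with `theta_deg` in `[0, 90)` and `direction`
#'   (`"inner"`, `"outer"` or `"neutral"`).
#' @export
hip_rotation_rom <- function(knee, ankle, side = c("left", "right")) {
  side <- match.arg(side)
  if (all(ankle == knee)) {
    abort_degenerate("knee and ankle keypoints coincide")
  }
  dy <- ankle[["y"]] - knee[["y"]]
  if (dy <= 0) {
    abort_posture("ankle must be strictly below the knee in the image (dy = %.2f px)", dy)
  }
  dx <- ankle[["x"]] - knee[["x"]]
  theta <- atan(abs(dx) / dy) * 180 / pi
  direction <- if (dx == 0) "neutral"
  else if (side == "left") {
    if (dx > 0) "inner" else "outer"
  } else {
    if (dx < 0) "inner" else "outer"
  }
  list(theta_deg = theta, direction = direction)
}

# round half away from zero, the tie rule a clinician uses reading a
# goniometer scale (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

frame_keypoint <- function(frame, joint) {
  kp <- frame$keypoints[[joint]]
  if (is.null(kp)) {
    abort_missing_kp("frame %d is missing required keypoint '%s'",
                     frame$frame_index, joint)
  }
  kp
}

# movement-specific geometry, unrounded (shared by app and reference paths)
movement_angle <- function(movement, points, side = "left") {
  switch(movement,
    hip_flexion   = ,
    hip_extension = hip_sagittal_rom(points$knee, points$hip, points$shoulder),
    knee_flexion  = knee_flexion_rom(points$hip, points$knee, points$ankle),
    hip_inner_rotation = ,
    hip_outer_rotation =
      hip_rotation_rom(points$knee, points$ankle, side)$theta_deg,
    abort_validation(sprintf("unknown movement '%s'", movement))
  )
}

#' Measure a movement's angle on one pose frame
#'
#' Applies the movement's geometry to the frame's keypoints and rounds to
#' the nearest whole degree (ties away from zero), as the on-screen
#' application reports. Missing required keypoints and degenerate
#' geometries are errors, never silently clamped: they indicate tracking
#' failure.
#'
#' @param frame A [pose_frame()].
#' @param movement One of [rom_movements()].
#' @param side Measured leg, `"left"` (default) or `"right"`.
#' @param participant_id,session Metadata copied into the record.
#' @return One-row `study_table` record with `method = "app"` and a whole
#'   degree `angle_deg`.
#' @export
measure_frame <- function(frame, movement, side = "left",
                          participant_id = "P", session = 1L) {
  movement <- match.arg(movement, rom_movements())
  needed <- movement_required_joints(movement)
  points <- stats::setNames(lapply(needed, frame_keypoint, frame = frame), needed)
  raw <- movement_angle(movement, points, side)
  study_table(tibble::tibble(
    participant_id = participant_id,
    session = as.integer(session),
    movement = movement,
    method = "app",
    angle_deg = round_half_away(raw),
    timestamp = frame$timestamp
  ))
}

#' Save a measurement to the study log with its source frame
#'
#' Appends the record to the study table (duplicate keys are an integrity
#' error) and persists the source frame under
#' `{participant}_{session}_{movement}.png` in `frame_store`, so the saved
#' frame can later serve as the reference picture for manual landmarking.
#' The PNG is a rendered plot of the keypoint skeleton.
#'
#' @param measurement One-row `study_table` record.
#' @param log A `study_table` to append to.
#' @param frame The [pose_frame()] the measurement came from, or `NULL` to
#'   skip frame persistence.
#' @param frame_store Directory for saved frames (created if needed).
#' @return The updated `study_table`.
#' @export
save_measurement <- function(measurement, log = study_table(), frame = NULL,
                             frame_store = NULL) {
  measurement <- study_table(measurement)
  if (nrow(measurement) != 1) abort_validation("measurement must be one record")
  out <- study_table(dplyr::bind_rows(tibble::as_tibble(log),
                                      tibble::as_tibble(measurement)))
  if (!is.null(frame) && !is.null(frame_store)) {
    dir.create(frame_store, showWarnings = FALSE, recursive = TRUE)
    fname <- file.path(frame_store, sprintf("%s_%d_%s.png",
                                            measurement$participant_id,
                                            measurement$session,
                                            measurement$movement))
    grDevices::png(fname, width = frame$resolution[1] / 2,
                   height = frame$resolution[2] / 2)
    on.exit(grDevices::dev.off(), add = TRUE)
    xs <- vapply(frame$keypoints, `[[`, numeric(1), "x")
    ys <- vapply(frame$keypoints, `[[`, numeric(1), "y")
    graphics::plot(xs, ys, xlim = c(0, frame$resolution[1]),
                   ylim = c(frame$resolution[2], 0), pch = 19, col = "blue",
                   xlab = "x (px)", ylab = "y (px)", asp = 1,
                   main = sprintf("%s s%d %s", measurement$participant_id,
                                  measurement$session, measurement$movement))
    graphics::text(xs, ys, names(frame$keypoints), pos = 4)
  }
  out
}
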
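## Reference-picture angles from manually placed anatomical landmarks.
##
## An operator marks bony landmarks on the saved frame (the landmarks a
## clinician would use with a universal goniometer); the angles are then
## computed with EXACTLY the same geometry as the keypoint path — the two
## methods differ only in where the points come from, never in the math.

# landmark names expected per movement, in role order
movement_landmarks <- function(movement) {
  switch(movement,
    hip_flexion   = ,
    hip_extension = c("greater_trochanter", "lateral_femoral_epicondyle",
                      "humeral_head"),
    knee_flexion  = c("greater_trochanter", "lateral_femoral_epicondyle",
                      "lateral_malleolus"),
    hip_inner_rotation = ,
    hip_outer_rotation = c("patella_midpoint", "talocrural_centre"),
    abort_validation(sprintf("unknown movement '%s'", movement))
  )
}

#' Construct a landmark set for one movement
#'
#' Sagittal hip movements use the greater trochanter (hip role, the vertex),
#' lateral femoral epicondyle (knee role) and the humeral-head midpoint
#' (shoulder role). Knee flexion uses greater trochanter (hip role), lateral
#' femoral epicondyle (knee role, the vertex) and lateral malleolus (ankle
#' role). Rotations use the patella midpoint (knee role) and the centre of
#' the talocrural articular space (ankle role).
#'
#' @param movement One of [rom_movements()].
#' @param points Named list of [keypoint()] values; names must be exactly
#'   the movement's landmark names (3 for sagittal/knee, 2 for rotations).
#' @return A `landmark_set` object.
#' @export
landmark_set <- function(movement, points) {
  movement <- match.arg(movement, rom_movements())
  expected <- movement_landmarks(movement)
  if (length(points) != length(expected) ||
      !setequal(names(points), expected)) {
    abort_validation("movement '%s' needs exactly landmarks {%s}, got {%s}",
                     movement, paste(expected, collapse = ", "),
                     paste(names(points), collapse = ", "))
  }
  structure(list(movement = movement, points = points[expected]),
            class = "landmark_set")
}

# landmark -> keypoint-role mapping for the shared geometry
landmarks_as_joints <- function(ls) {
  p <- ls$points
  switch(ls$movement,
    hip_flexion   = ,
    hip_extension = list(hip = p$greater_trochanter,
                         knee = p$lateral_femoral_epicondyle,
                         shoulder = p$humeral_head),
    knee_flexion  = list(hip = p$greater_trochanter,
                         knee = p$lateral_femoral_epicondyle,
                         ankle = p$lateral_malleolus),
    hip_inner_rotation = ,
    hip_outer_rotation = list(knee = p$patella_midpoint,
                              ankle = p$talocrural_centre)
  )
}

#' Reference angle from manually placed landmarks
#'
#' Runs the movement's angle geometry on operator-placed landmark
#' coordinates and rounds to the nearest 1 degree (same tie rule as the app
#' path), yielding a `method = "reference"` record.
#'
#' @param landmarks A [landmark_set()].
#' @param side Measured leg.
#' @param participant_id,session,timestamp Metadata copied into the record.
#' @return One-row `study_table` record with `method = "reference"`.
#' @export
reference_angle <- function(landmarks, side = "left",
                            participant_id = "P", session = 1L,
                            timestamp = 0) {
  if (!inherits(landmarks, "landmark_set")) {
    abort_validation("landmarks must be a landmark_set")
  }
  raw <- movement_angle(landmarks$movement, landmarks_as_joints(landmarks), side)
  study_table(tibble::tibble(
    participant_id = participant_id,
    session = as.integer(session),
    movement = landmarks$movement,
    method = "reference",
    angle_deg = round_half_away(raw),   # 1 degree resolution
    timestamp = as.numeric(timestamp)
  ))
}

#' Read an operator landmark file
#'
#' CSV schema: `participant_id,session,movement,point_name,x_px,y_px`, one
#' row per placed landmark. Timestamps of landmark placement may be supplied
#' in an optional `timestamp` column (ISO-8601).
#'
#' @param path CSV file path.
#' @return Tibble of landmark rows.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) abort_format("file not found: %s", path)
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = "c", session = "i", movement = "c", point_name = "c",
    x_px = "d", y_px = "d", .default = "c"), progress = FALSE)
  req <- c("participant_id", "session", "movement", "point_name", "x_px", "y_px")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort_format("landmark CSV missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  if ("timestamp" %in% names(df)) df$timestamp <- iso_to_seconds(df$timestamp)
  df
}

#' Compute reference angles for every marked frame in a landmark table
#'
#' @param landmark_df Tibble from [read_landmarks()].
#' @param side Measured leg.
#' @return `study_table` of `method = "reference"` records.
#' @export
reference_angles <- function(landmark_df, side = "left") {
  groups <- split(landmark_df,
                  paste(landmark_df$participant_id, landmark_df$session,
                        landmark_df$movement, sep = "\r"))
  rows <- lapply(groups, function(g) {
    pts <- stats::setNames(
      lapply(seq_len(nrow(g)), function(i) keypoint(g$x_px[i], g$y_px[i])),
      g$point_name)
    ts <- if ("timestamp" %in% names(g)) max(g$timestamp) else 0
    reference_angle(landmark_set(g$movement[1], pts), side = side,
                    participant_id = g$participant_id[1],
                    session = g$session[1], timestamp = ts)
  })
  study_table(dplyr::bind_rows(rows))
}
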
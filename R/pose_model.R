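#' @keywords internal
"_PACKAGE"

## Joint and movement vocabulary ------------------------------------------

#' Joints required by the angle engine
#'
#' The four keypoints the measurement geometry uses: shoulder, hip, knee and
#' ankle of the measured side. The side itself (left in the standard
#' protocol) is study metadata, not part of the geometry.
#'
#' @return Character vector of joint names.
#' @export
rom_joints <- function() c("shoulder", "hip", "knee", "ankle")

#' Movements in protocol order
#'
#' The five active movements of the measurement protocol, in the fixed order
#' they are performed: hip flexion, knee flexion, hip extension, hip inner
#' rotation, hip outer rotation.
#'
#' @return Character vector of movement names.
#' @export
rom_movements <- function() {
  c("hip_flexion", "knee_flexion", "hip_extension",
    "hip_inner_rotation", "hip_outer_rotation")
}

#' Anatomically plausible active ROM limits, degrees
#'
#' Used by the synthetic projector to reject impossible requested angles and
#' by the study generator to truncate latent draws.
#'
#' @return Named list of `c(lo, hi)` per movement.
#' @export
rom_angle_limits <- function() {
  list(
    hip_flexion        = c(0, 130),
    hip_extension      = c(0, 40),
    hip_inner_rotation = c(0, 60),
    hip_outer_rotation = c(0, 60),
    knee_flexion       = c(0, 150)
  )
}

# keypoints a movement's geometry needs
movement_required_joints <- function(movement) {
  switch(movement,
    hip_flexion        = c("knee", "hip", "shoulder"),
    hip_extension      = c("knee", "hip", "shoulder"),
    knee_flexion       = c("hip", "knee", "ankle"),
    hip_inner_rotation = c("knee", "ankle"),
    hip_outer_rotation = c("knee", "ankle"),
    abort_validation(sprintf("unknown movement '%s'", movement))
  )
}

## Error helpers -----------------------------------------------------------

abort_class <- function(class) {
  function(msg, ...) rlang::abort(sprintf(msg, ...), class = class)
}
abort_format     <- abort_class("poserom_format_error")
abort_parse      <- abort_class("poserom_parse_error")
abort_integrity  <- abort_class("poserom_integrity_error")
abort_validation <- abort_class("poserom_validation_error")
abort_degenerate <- abort_class("poserom_degenerate_geometry_error")
abort_posture    <- abort_class("poserom_invalid_posture_error")
abort_missing_kp <- abort_class("poserom_missing_keypoint_error")
abort_domain     <- abort_class("poserom_domain_error")
abort_insufficient <- abort_class("poserom_insufficient_data_error")
abort_framing    <- abort_class("poserom_framing_error")

## Keypoints and frames ----------------------------------------------------

#' Construct a 2D keypoint in pixel coordinates
#'
#' Image convention: origin at the top-left corner, x increases rightward,
#' y increases downward. All geometry in the package is written against this
#' convention.
#'
#' @param x_px,y_px Finite pixel coordinates.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
keypoint <- function(x_px, y_px) {
  if (!is.numeric(x_px) || !is.numeric(y_px) ||
      !is.finite(x_px) || !is.finite(y_px)) {
    abort_validation("keypoint coordinates must be finite numbers")
  }
  c(x = as.numeric(x_px), y = as.numeric(y_px))
}

#' Construct a single pose frame
#'
#' A pose frame is one video frame's named 2D keypoints, with its index,
#' timestamp (seconds) and frame resolution. Keypoints may be missing; a
#' frame is only rejected when a requested measurement needs an absent
#' keypoint.
#'
#' @param keypoints Named list of [keypoint()] values; names drawn from
#'   [rom_joints()].
#' @param frame_index Integer frame number, `>= 0`.
#' @param timestamp Time in seconds (numeric).
#' @param resolution `c(width_px, height_px)`; defaults to 1280x720.
#' @return An object of class `pose_frame`.
#' @export
pose_frame <- function(keypoints, frame_index = 0L, timestamp = 0,
                       resolution = c(1280L, 720L)) {
  if (frame_index < 0) abort_validation("frame_index must be >= 0")
  bad <- setdiff(names(keypoints), rom_joints())
  if (length(bad)) abort_validation("unknown joint name(s): %s",
                                    paste(bad, collapse = ", "))
  structure(
    list(frame_index = as.integer(frame_index),
         timestamp = as.numeric(timestamp),
         keypoints = keypoints,
         resolution = as.numeric(resolution)),
    class = "pose_frame"
  )
}

#' @export
print.pose_frame <- function(x, ...) {
  cat(sprintf("<pose_frame #%d t=%.3fs %dx%d>\n", x$frame_index, x$timestamp,
              x$resolution[1], x$resolution[2]))
  for (j in names(x$keypoints)) {
    kp <- x$keypoints[[j]]
    cat(sprintf("  %-9s (%.2f, %.2f)\n", j, kp["x"], kp["y"]))
  }
  invisible(x)
}

pose_csv_cols <- function() {
  c("frame_index", "timestamp",
    as.vector(t(outer(rom_joints(), c("x", "y"), paste, sep = "_"))))
}

frame_to_row <- function(frame) {
  row <- as.list(rep(NA_real_, length(pose_csv_cols())))
  names(row) <- pose_csv_cols()
  row$frame_index <- frame$frame_index
  row$timestamp <- frame$timestamp
  for (j in names(frame$keypoints)) {
    row[[paste0(j, "_x")]] <- frame$keypoints[[j]][["x"]]
    row[[paste0(j, "_y")]] <- frame$keypoints[[j]][["y"]]
  }
  row
}

row_to_frame <- function(row, resolution, origin = "row") {
  kps <- list()
  for (j in rom_joints()) {
    x <- row[[paste0(j, "_x")]]
    y <- row[[paste0(j, "_y")]]
    if (is.na(x) && is.na(y)) next           # absent keypoint: legal
    if (is.na(x) || is.na(y)) {
      abort_parse("frame_index %s: keypoint '%s' has only one of %s_x/%s_y (%s)",
                  row[["frame_index"]], j, j, j, origin)
    }
    kps[[j]] <- keypoint(x, y)
  }
  pose_frame(kps, frame_index = row[["frame_index"]],
             timestamp = row[["timestamp"]], resolution = resolution)
}

#' Read a stream of pose frames
#'
#' CSV schema: columns `frame_index,timestamp,shoulder_x,shoulder_y,hip_x,
#' hip_y,knee_x,knee_y,ankle_x,ankle_y` (header required; an absent keypoint
#' is a pair of empty cells). The JSON mirror is an array of objects with the
#' same field names. Frames are returned sorted by ascending `frame_index`.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @param resolution Frame resolution attached to every frame.
#' @return List of [pose_frame()] objects.
#' @export
read_pose_frames <- function(path, format = c("auto", "csv", "json"),
                             resolution = c(1280L, 720L)) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) abort_format("file not found: %s", path)

  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    missing_cols <- setdiff(pose_csv_cols(), names(df))
    if (length(missing_cols)) {
      abort_format("keypoint CSV missing required column(s): %s",
                   paste(missing_cols, collapse = ", "))
    }
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- tibble::as_tibble(recs)
    missing_cols <- setdiff(c("frame_index", "timestamp"), names(df))
    if (length(missing_cols)) {
      abort_format("keypoint JSON missing required field(s): %s",
                   paste(missing_cols, collapse = ", "))
    }
    for (col in setdiff(pose_csv_cols(), names(df))) df[[col]] <- NA_real_
  }
  if (nrow(df) == 0) return(list())

  parse_num <- function(col, i) {
    v <- df[[col]][i]
    if (is.na(v) || (is.character(v) && !nzchar(trimws(v)))) return(NA_real_)
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) {
      abort_parse("line %d: non-numeric value '%s' in field '%s'", i + 1L, v, col)
    }
    out
  }
  frames <- lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(stats::setNames(pose_csv_cols(), pose_csv_cols()),
                  parse_num, i = i)
    if (is.na(row$frame_index)) {
      abort_parse("line %d: missing frame_index", i + 1L)
    }
    row_to_frame(row, resolution, origin = sprintf("line %d", i + 1L))
  })
  frames[order(vapply(frames, function(f) f$frame_index, integer(1)))]
}

#' Write a stream of pose frames
#'
#' @param frames List of [pose_frame()] objects.
#' @inheritParams read_pose_frames
#' @return `path`, invisibly.
#' @export
write_pose_frames <- function(frames, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  df <- dplyr::bind_rows(lapply(frames, function(f) tibble::as_tibble(frame_to_row(f))))
  if (format == "csv") {
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  }
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else
    abort_format("cannot guess format from extension '%s'; pass format=", ext)
}

## Study tables ------------------------------------------------------------

#' Construct / validate a study table
#'
#' A study table collects saved angle measurements across participants,
#' sessions (1 = test, 2 = retest, 24 h apart in the standard protocol),
#' movements and methods (`"app"` = keypoint-based measurement in whole
#' degrees; `"reference"` = manual landmark measurement at 1 degree
#' resolution). At most one record may exist per
#' (participant, session, movement, method).
#'
#' @param df Data frame with columns `participant_id`, `session`, `movement`,
#'   `method`, `angle_deg`, `timestamp` (seconds, numeric).
#' @return A `study_table` tibble.
#' @export
study_table <- function(df = NULL) {
  cols <- c("participant_id", "session", "movement", "method",
            "angle_deg", "timestamp")
  if (is.null(df) || nrow(df) == 0) {
    df <- tibble::tibble(participant_id = character(), session = integer(),
                         movement = character(), method = character(),
                         angle_deg = double(), timestamp = double())
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    abort_format("study table missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df)[cols]
  df$participant_id <- as.character(df$participant_id)
  df$session <- as.integer(df$session)
  df$angle_deg <- as.numeric(df$angle_deg)
  df$timestamp <- as.numeric(df$timestamp)
  if (nrow(df)) {
    if (!all(df$session %in% c(1L, 2L))) {
      abort_validation("session must be 1 or 2")
    }
    if (!all(df$movement %in% rom_movements())) {
      abort_validation("unknown movement(s): %s",
                       paste(setdiff(df$movement, rom_movements()), collapse = ", "))
    }
    if (!all(df$method %in% c("app", "reference"))) {
      abort_validation("method must be 'app' or 'reference'")
    }
    key <- paste(df$participant_id, df$session, df$movement, df$method)
    if (anyDuplicated(key)) {
      abort_integrity("duplicate record key(s): %s",
                      paste(unique(key[duplicated(key)]), collapse = "; "))
    }
    app <- df$angle_deg[df$method == "app"]
    if (length(app) && any(app != round(app))) {
      abort_validation("app angles must be whole degrees")
    }
    sag <- df$movement %in% c("hip_flexion", "hip_extension", "knee_flexion")
    if (any(df$angle_deg[sag] < 0 | df$angle_deg[sag] > 180) ||
        any(df$angle_deg[!sag] < 0 | df$angle_deg[!sag] > 90)) {
      abort_validation("angle_deg outside admissible range (0-180 sagittal, 0-90 rotation)")
    }
  }
  class(df) <- c("study_table", class(df))
  df
}

#' Read a study table from CSV or JSON
#'
#' File schema: `participant_id,session,movement,method,angle_deg,timestamp`
#' with ISO-8601 timestamps in files (converted to seconds in memory). An
#' empty file yields an empty table with a warning.
#'
#' @inheritParams read_pose_frames
#' @return A `study_table` tibble.
#' @export
read_study_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) abort_format("file not found: %s", path)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(
      participant_id = "c", session = "i", movement = "c", method = "c",
      angle_deg = "d", timestamp = "c"), progress = FALSE)
  } else {
    df <- tibble::as_tibble(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
  }
  if (nrow(df) == 0) {
    warning("empty study table file: ", path)
    return(study_table())
  }
  df$timestamp <- iso_to_seconds(df$timestamp)
  study_table(df)
}

#' Write a study table to CSV or JSON
#'
#' @param table A `study_table`.
#' @inheritParams read_pose_frames
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  table <- study_table(table)
  out <- tibble::as_tibble(table)
  out$timestamp <- seconds_to_iso(out$timestamp)
  if (format == "csv") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

# ISO-8601 UTC <-> seconds since epoch; whole-second resolution is used
# throughout generated data so file round-trips are exact.
seconds_to_iso <- function(s) {
  format(as.POSIXct(s, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}
iso_to_seconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- as.numeric(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  if (any(is.na(out) & !is.na(x))) {
    abort_parse("unparseable ISO-8601 timestamp(s): %s",
                paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  }
  out
}
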
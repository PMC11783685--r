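# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own code paths.

# vector-angle oracle: atan2 of |cross| and dot, never the law of cosines
oracle_angle <- function(vertex, a, b) {
  va <- a - vertex
  vb <- b - vertex
  cross <- va[["x"]] * vb[["y"]] - va[["y"]] * vb[["x"]]
  atan2(abs(cross), sum(va * vb)) * 180 / pi
}

# ICC(A,1) oracle: mean squares straight from stats::aov, then the
# published agreement formula
oracle_icc_a1 <- function(s1, s2) {
  n <- length(s1)
  df <- data.frame(score = c(s1, s2),
                   subj = factor(rep(seq_len(n), 2)),
                   sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subj + sess, data = df))[[1]][, "Mean Sq"]
  (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / n)
}

rand_kp <- function(w = 1280, h = 720) keypoint(runif(1, 0, w), runif(1, 0, h))

# a frame with an exactly straight standing posture
straight_frame <- function() {
  pose_frame(list(shoulder = keypoint(400, 100), hip = keypoint(400, 300),
                  knee = keypoint(400, 500), ankle = keypoint(400, 700)))
}

# minimal valid study table: one participant, both sessions + reference,
# blinding-consistent timestamps
tiny_study <- function(app1, app2, ref, movement = "knee_flexion",
                       participants = NULL) {
  n <- length(app1)
  if (is.null(participants)) participants <- sprintf("P%02d", seq_len(n))
  study_table(tibble::tibble(
    participant_id = rep(participants, 3),
    session = rep(c(1L, 2L, 1L), each = n),
    movement = movement,
    method = rep(c("app", "app", "reference"), each = n),
    angle_deg = c(app1, app2, ref),
    timestamp = rep(c(1000, 87400, 200000), each = n) + seq_len(n)
  ))
}
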
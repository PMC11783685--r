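test_that("law-of-cosines vertex angle matches hand geometry", {
  expect_equal(angle_at_vertex(keypoint(0, 0), keypoint(1, 0), keypoint(0, 1)), 90)
  expect_equal(angle_at_vertex(keypoint(0, 0), keypoint(1, 0), keypoint(-1, 0)), 180)
  expect_equal(angle_at_vertex(keypoint(0, 0), keypoint(1, 0), keypoint(2, 0)), 0)
  expect_error(angle_at_vertex(keypoint(0, 0), keypoint(0, 0), keypoint(1, 1)),
               class = "poserom_degenerate_geometry_error")
})

test_that("sagittal ROM operators reproduce canonical postures", {
  # straight posture reads zero
  expect_equal(hip_sagittal_rom(keypoint(100, 400), keypoint(100, 200),
                                keypoint(100, 0)), 0)
  expect_equal(knee_flexion_rom(keypoint(100, 0), keypoint(100, 200),
                                keypoint(100, 400)), 0)
  # right-angle postures read 90
  expect_equal(hip_sagittal_rom(keypoint(300, 200), keypoint(100, 200),
                                keypoint(100, 0)), 90)
  expect_equal(knee_flexion_rom(keypoint(100, 0), keypoint(100, 200),
                                keypoint(300, 200)), 90)
})

test_that("angle operators agree with an independent vector-angle oracle", {
  set.seed(42)
  for (i in 1:1000) {
    v <- rand_kp(); a <- rand_kp(); b <- rand_kp()
    expect_lt(abs(angle_at_vertex(v, a, b) - oracle_angle(v, a, b)), 1e-9)
  }
  # composed operators: beta = 180 - alpha against the same oracle
  for (i in 1:200) {
    k <- rand_kp(); h <- rand_kp(); s <- rand_kp()
    expect_lt(abs(hip_sagittal_rom(k, h, s) - (180 - oracle_angle(h, k, s))), 1e-9)
    expect_lt(abs(knee_flexion_rom(s, k, h) - (180 - oracle_angle(k, s, h))), 1e-9)
  }
})

test_that("angles are invariant to translation, rotation and uniform scale", {
  set.seed(7)
  rot <- function(p, th) keypoint(cos(th) * p[["x"]] - sin(th) * p[["y"]],
                                  sin(th) * p[["x"]] + cos(th) * p[["y"]])
  for (i in 1:100) {
    v <- rand_kp(); a <- rand_kp(); b <- rand_kp()
    base <- angle_at_vertex(v, a, b)
    shift <- keypoint(runif(1, -500, 500), runif(1, -500, 500))
    s <- runif(1, 0.1, 10)
    th <- runif(1, 0, 2 * pi)
    expect_equal(angle_at_vertex(v + shift, a + shift, b + shift), base,
                 tolerance = 1e-9)
    expect_equal(angle_at_vertex(v * s, a * s, b * s), base, tolerance = 1e-9)
    expect_equal(angle_at_vertex(rot(v, th), rot(a, th), rot(b, th)), base,
                 tolerance = 1e-8)
  }
})

test_that("hip rotation measures against the image vertical", {
  expect_equal(hip_rotation_rom(keypoint(100, 100), keypoint(100, 300))$theta_deg, 0)
  r <- hip_rotation_rom(keypoint(100, 100), keypoint(300, 300), side = "left")
  expect_equal(r$theta_deg, 45)
  expect_equal(r$direction, "inner")
  # inverse construction: place the ankle to realize an exact 20 degrees
  r20 <- hip_rotation_rom(keypoint(100, 100),
                          keypoint(100 + 200 * tan(20 * pi / 180), 300))
  expect_lt(abs(r20$theta_deg - 20), 1e-9)
  # direction convention mirrors across sides and x displacement
  expect_equal(hip_rotation_rom(keypoint(100, 100), keypoint(50, 300),
                                side = "left")$direction, "outer")
  expect_equal(hip_rotation_rom(keypoint(100, 100), keypoint(50, 300),
                                side = "right")$direction, "inner")
  expect_equal(hip_rotation_rom(keypoint(100, 100), keypoint(100, 300))$direction,
               "neutral")

  expect_error(hip_rotation_rom(keypoint(100, 300), keypoint(100, 100)),
               class = "poserom_invalid_posture_error")
  expect_error(hip_rotation_rom(keypoint(100, 100), keypoint(100, 100)),
               class = "poserom_degenerate_geometry_error")
})

test_that("rotation angle is NOT invariant to rotating the frame", {
  knee <- keypoint(100, 100); ankle <- keypoint(150, 300)
  base <- hip_rotation_rom(knee, ankle)$theta_deg
  # rotate both points 30 degrees about the knee: theta must change,
  # because the reference is the image vertical, not a body axis
  th <- 30 * pi / 180
  d <- ankle - knee
  ankle_rot <- keypoint(knee[["x"]] + cos(th) * d[["x"]] - sin(th) * d[["y"]],
                        knee[["y"]] + sin(th) * d[["x"]] + cos(th) * d[["y"]])
  expect_gt(abs(hip_rotation_rom(knee, ankle_rot)$theta_deg - base), 1)
})

test_that("ROM responds monotonically to the geometry", {
  # beta decreases as alpha increases
  alphas <- seq(10, 170, by = 10)
  betas <- vapply(alphas, function(a) {
    th <- a * pi / 180
    hip_sagittal_rom(keypoint(cos(th) * 100, sin(th) * 100), keypoint(0, 0),
                     keypoint(100, 0))
  }, numeric(1))
  expect_true(all(diff(betas) < 0))
  # theta strictly increases with |dx| at fixed vertical drop
  thetas <- vapply(seq(0, 500, by = 50), function(dx) {
    hip_rotation_rom(keypoint(600, 100), keypoint(600 + dx, 400))$theta_deg
  }, numeric(1))
  expect_true(all(diff(thetas) > 0))
})

test_that("measure_frame applies the geometry then whole-degree rounding", {
  expect_equal(measure_frame(straight_frame(), "knee_flexion")$angle_deg, 0)
  # exact 89.5001-degree hip angle rounds up to 90
  f <- project_skeleton("hip_flexion", 89.5001)
  expect_equal(measure_frame(f, "hip_flexion")$angle_deg, 90)
  # and the half-down neighbour rounds down
  f <- project_skeleton("hip_flexion", 89.4999)
  expect_equal(measure_frame(f, "hip_flexion")$angle_deg, 89)

  set.seed(11)
  for (i in 1:300) {
    m <- sample(rom_movements(), 1)
    lim <- rom_angle_limits()[[m]]
    f <- add_detection_noise(project_skeleton(m, runif(1, lim[1] + 5, lim[2] - 5)), 3)
    got <- measure_frame(f, m)$angle_deg
    kp <- f$keypoints
    raw <- switch(m,
      hip_flexion = , hip_extension = hip_sagittal_rom(kp$knee, kp$hip, kp$shoulder),
      knee_flexion = knee_flexion_rom(kp$hip, kp$knee, kp$ankle),
      hip_rotation_rom(kp$knee, kp$ankle)$theta_deg)
    expect_identical(got, sign(raw) * floor(abs(raw) + 0.5))
  }
})

test_that("save_measurement logs records, persists frames and rejects duplicates", {
  store <- withr::local_tempdir()
  f <- straight_frame()
  rec <- measure_frame(f, "knee_flexion", participant_id = "P01")
  log <- save_measurement(rec, frame = f, frame_store = store)
  expect_equal(nrow(log), 1)
  expect_true(file.exists(file.path(store, "P01_1_knee_flexion.png")))
  expect_error(save_measurement(rec, log, f, store),
               class = "poserom_integrity_error")

  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(log, path)
  expect_equal(tibble::as_tibble(read_study_table(path)),
               tibble::as_tibble(log))
})
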
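test_that("ICC(A,1) reproduces the independent ANOVA oracle on a toy table", {
  s1 <- c(10, 20, 30, 40)
  s2 <- c(12, 18, 32, 38)
  # frozen value computed beforehand with the aov-based oracle
  expect_equal(icc_two_way_random(s1, s2)$icc, 0.987124463519313,
               tolerance = 1e-12)
  expect_equal(icc_two_way_random(s1, s2)$icc, unname(oracle_icc_a1(s1, s2)),
               tolerance = 1e-12)
  # and on random tables of several sizes
  set.seed(3)
  for (n in c(5, 12, 30)) {
    a <- rnorm(n, 50, 10); b <- a + rnorm(n, 1, 4)
    expect_equal(icc_two_way_random(a, b)$icc, unname(oracle_icc_a1(a, b)),
                 tolerance = 1e-12)
  }
})

test_that("ICC agreement behaviour: perfection, offsets, invariances", {
  s1 <- c(10, 20, 30, 40)
  expect_equal(icc_two_way_random(s1, s1)$icc, 1)
  # absolute agreement penalises a constant session offset
  offset5 <- icc_two_way_random(s1, s1 + 5)$icc
  expect_lt(offset5, 1)
  # ...increasingly with the offset size
  iccs <- vapply(c(0, 2, 5, 10, 20),
                 function(o) icc_two_way_random(s1, s1 + o)$icc, numeric(1))
  expect_true(all(diff(iccs) < 0))
  # the consistency variant ignores the offset entirely
  expect_equal(icc_two_way_random(s1, s1 + 5, type = "consistency")$icc, 1)

  # invariance under common shift and positive scaling of ALL scores
  set.seed(8)
  a <- rnorm(10, 40, 8); b <- a + rnorm(10, 0, 3)
  base <- icc_two_way_random(a, b)$icc
  expect_equal(icc_two_way_random(a + 17, b + 17)$icc, base, tolerance = 1e-12)
  expect_equal(icc_two_way_random(a * 2.5, b * 2.5)$icc, base, tolerance = 1e-12)

  fit <- icc_two_way_random(a, b)
  expect_true(fit$ci_low <= fit$icc && fit$icc <= fit$ci_high)
  expect_lte(fit$icc, 1)
})

test_that("ICC input validation", {
  expect_error(icc_two_way_random(1:2, 1:2),
               class = "poserom_insufficient_data_error")
  expect_error(icc_two_way_random(rep(5, 4), rep(5, 4)),
               class = "poserom_domain_error")
  expect_error(icc_two_way_random(1:4, 1:5),
               class = "poserom_validation_error")
})

test_that("SEM and MDC closed forms", {
  scores <- 1:6
  expect_equal(sem(scores, icc = 1), 0)
  scaled <- scores / sd(scores) * 10            # pooled SD exactly 10
  expect_equal(sem(scaled, icc = 0.75), 5, tolerance = 1e-12)
  expect_error(sem(scores, icc = 1.2), class = "poserom_domain_error")
  expect_error(sem(scores, icc = -0.1), class = "poserom_domain_error")

  expect_equal(mdc(0), 0)
  expect_equal(mdc(1), sqrt(2) * 1.96)
  expect_equal(mdc(5), 5 * sqrt(2) * 1.96)
  expect_error(mdc(-1), class = "poserom_domain_error")
  # constant ratio property
  sems <- c(0.1, 0.5, 1, 3, 7)
  expect_equal(mdc(sems) / sems, rep(2.77186, 5), tolerance = 1e-5)
})

test_that("reliability classifications follow the Landis-Koch bands", {
  expect_equal(classify_icc(0.93), "almost perfect")
  expect_equal(classify_icc(0.82), "almost perfect")
  expect_equal(classify_icc(0.83), "almost perfect")
  expect_equal(classify_icc(0.81), "almost perfect")   # band edge inclusive
  expect_equal(classify_icc(0.74), "substantial")
  expect_equal(classify_icc(c(0.60, 0.41)), c("moderate", "moderate"))
  expect_equal(classify_icc(0.30), "fair")
  expect_equal(classify_icc(0.05), "slight")
  expect_warning(lab <- classify_icc(-0.2), "negative")
  expect_equal(lab, "slight")
})

test_that("correlation strength classifications", {
  expect_equal(classify_r(c(0.99, 0.98, 0.90)), rep("very strong", 3))
  expect_equal(classify_r(c(0.87, 0.85, 0.70)), rep("strong", 3))
  expect_equal(classify_r(0.55), "moderate")
  expect_equal(classify_r(0.35), "weak")
  expect_equal(classify_r(0.10), "very weak")
  expect_equal(classify_r(-0.95), "very strong")       # magnitude based
})

test_that("Pearson correlation matches the covariance-definition oracle", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 3), 1)
  expect_equal(pearson_r(x, -x), -1)
  # frozen hand-computed value for {(1,2),(2,1),(3,4),(4,3)}
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "poserom_domain_error")
  expect_error(pearson_r(1:2, 1:2), class = "poserom_insufficient_data_error")
})

test_that("Bland-Altman agreement statistics", {
  same <- bland_altman(c(10, 20, 30), c(10, 20, 30))
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  expect_equal(same$n_outside_loa, 0)

  ba <- bland_altman(c(9, 20, 31), c(10, 20, 30))  # differences -1, 0, 1
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))
  expect_equal(ba$n_outside_loa, 0)

  # bias equals the difference of the method means; LoA width is 3.92 SD(d)
  set.seed(21)
  app <- rnorm(50, 100, 10); ref <- rnorm(50, 98, 10)
  ba <- bland_altman(app, ref)
  expect_equal(ba$bias, mean(app) - mean(ref))
  expect_equal(ba$loa_high - ba$loa_low, 3.92 * sd(app - ref))
  expect_equal(ba$means, (app + ref) / 2)
  expect_error(bland_altman(1:3, 1:4), class = "poserom_validation_error")
})

test_that("reliability and validity result rows assemble the right pieces", {
  set.seed(13)
  a <- round(rnorm(20, 100, 10)); b <- round(a + rnorm(20, 0, 4))
  rr <- reliability_result("knee_flexion", a, b)
  fit <- icc_two_way_random(a, b)
  expect_equal(rr$icc, fit$icc)
  expect_equal(rr$s_pooled, sd(c(a, b)))
  expect_equal(rr$sem, sd(c(a, b)) * sqrt(1 - max(0, min(1, fit$icc))))
  expect_equal(rr$mdc, rr$sem * sqrt(2) * 1.96)
  expect_equal(rr$icc_class, classify_icc(fit$icc))

  vr <- validity_result("knee_flexion", a, b)
  expect_equal(vr$r, pearson_r(a, b))
  expect_equal(vr$bias, mean(a - b))
})
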
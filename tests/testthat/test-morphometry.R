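test_that("measured AI matches the generator's analytic ground truth", {
  p <- shoulder_params()
  p$acromial_overhang_mm <- overhang_from_ai(0.69, p)
  g <- generate_shoulder(p)
  m <- measure_ai(g$shoulder)
  expect_lt(abs(m$AI - 0.69), 0.01)
  expect_lt(abs(m$GA_mm - g$truth$GA_mm), 1e-6)
  expect_lt(abs(m$GH_mm - g$truth$GH_mm), 1e-6)
  expect_equal(m$AI, m$GA_mm / m$GH_mm, tolerance = 1e-12)
})

test_that("the default geometry reproduces the reference morphometrics", {
  g <- generate_shoulder()
  m <- measure_ai(g$shoulder)
  expect_lt(abs(m$GH_mm - 49.5), 1e-6)
  expect_lt(abs(m$AI - 0.668), 0.005)
})

test_that("AI equals 1 when the acromion reaches the lateral cortex", {
  p <- shoulder_params()
  p$acromial_overhang_mm <- 2 * p$head_radius_mm + p$glenoid_offset_mm
  g <- generate_shoulder(p)
  m <- measure_ai(g$shoulder)
  expect_equal(m$AI, 1.0, tolerance = 1e-9)
})

test_that("measurement is deterministic and jitter is seed-reproducible", {
  g <- generate_shoulder()
  a <- measure_ai(g$shoulder)
  b <- measure_ai(g$shoulder)
  expect_identical(a$AI, b$AI)
  j1 <- measure_ai(g$shoulder, jitter_sd_mm = 0.5, seed = 9)
  j2 <- measure_ai(g$shoulder, jitter_sd_mm = 0.5, seed = 9)
  j3 <- measure_ai(g$shoulder, jitter_sd_mm = 0.5, seed = 10)
  expect_identical(j1$AI, j2$AI)
  expect_false(j1$AI == j3$AI)
})

test_that("AI is invariant to rigid motion and uniform scaling", {
  g <- generate_shoulder()
  m0 <- measure_ai(g$shoulder)
  set.seed(13)
  R <- random_rotation(); t <- runif(3, -50, 50)
  sh <- g$shoulder
  fr <- lapply(sh$humerus$frame, function(v) drop(R %*% v))
  sh$humerus <- transform_mesh(sh$humerus, R, t); sh$humerus$frame <- fr
  sh$scapula <- transform_mesh(sh$scapula, R, t); sh$scapula$frame <- fr
  m1 <- measure_ai(sh)
  expect_lt(abs(m1$AI - m0$AI), 1e-9)
  sc <- g$shoulder
  sc$humerus$vertices <- 1.7 * sc$humerus$vertices
  sc$scapula$vertices <- 1.7 * sc$scapula$vertices
  m2 <- measure_ai(sc)
  expect_lt(abs(m2$AI - m0$AI), 1e-9)
  expect_lt(abs(m2$GA_mm - 1.7 * m0$GA_mm), 1e-9)
})

test_that("AI increases strictly with the overhang parameter", {
  ais <- vapply(seq(25, 45, by = 5), function(ov) {
    g <- generate_shoulder(shoulder_params(acromial_overhang_mm = ov))
    measure_ai(g$shoulder)$AI
  }, numeric(1))
  expect_true(all(diff(ais) > 0))
})

test_that("reliability study: perfect agreement without jitter, decaying with it", {
  set.seed(41)
  co <- generate_cohort(cohort_spec(n_shoulders = 10, seed = 3))
  shoulders <- lapply(co$shoulders, `[[`, "shoulder")
  r0 <- reliability_study(shoulders, jitter_sd_mm = 0, seed = 1)
  for (m in r0$icc) expect_equal(m$icc, 1.0, tolerance = 1e-9)
  rs <- reliability_study(shoulders, jitter_sd_mm = 0.3, seed = 1)
  rl <- reliability_study(shoulders, jitter_sd_mm = 5, seed = 1)
  expect_gt(rs$icc$AI$icc, rl$icc$AI$icc)
  expect_lt(rl$icc$AI$icc, 0.6)
  expect_gt(rs$icc$AI$icc, 0.7)
  expect_error(reliability_study(shoulders, n_observers = 1), ">= 2")
  expect_error(reliability_study(shoulders[1]), ">= 2")
})
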
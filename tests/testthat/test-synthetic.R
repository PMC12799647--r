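test_that("generation is deterministic and parameter checking works", {
  g1 <- generate_shoulder()
  g2 <- generate_shoulder()
  expect_identical(g1$shoulder$humerus$vertices, g2$shoulder$humerus$vertices)
  expect_identical(g1$shoulder$scapula$vertices, g2$shoulder$scapula$vertices)
  expect_error(shoulder_params(canal_radius_mm = 12), "smaller")
  expect_error(shoulder_params(acromial_height_mm = 0.2), "intersects")
  expect_error(shoulder_params(head_radius_mm = -1), "positive")
})

test_that("the AI-overhang map is strictly monotone and invertible", {
  p <- shoulder_params()
  ov <- seq(20, 45, by = 1)
  ai <- ai_from_overhang(ov, p)
  expect_true(all(diff(ai) > 0))
  back <- overhang_from_ai(ai, p)
  expect_lt(max(abs(back - ov)), 1e-4)
})

test_that("cohort sampling respects the AI distribution and bounds", {
  co <- generate_cohort(cohort_spec(n_shoulders = 68, seed = 1))
  expect_lt(abs(mean(co$table$ai_target) - 0.668), 0.03)
  expect_true(all(co$table$ai_target >= 0.50 & co$table$ai_target <= 0.93))
  # reproducibility from (spec, seed)
  co2 <- generate_cohort(cohort_spec(n_shoulders = 68, seed = 1))
  expect_identical(co$table, co2$table)
  expect_identical(co$shoulders[[5]]$shoulder$humerus$vertices,
                   co2$shoulders[[5]]$shoulder$humerus$vertices)
  co3 <- generate_cohort(cohort_spec(n_shoulders = 68, seed = 2))
  expect_false(identical(co$table$ai_target, co3$table$ai_target))
})

test_that("measured AI tracks the sampled target across the cohort", {
  co <- generate_cohort(cohort_spec(n_shoulders = 12, seed = 5))
  ai_meas <- vapply(co$shoulders, function(s)
    measure_ai(s$shoulder)$AI, numeric(1))
  expect_lt(max(abs(ai_meas - co$table$ai_target)), 0.01)
})

test_that("extension only increases trajectory clearance (nested discordance)", {
  co <- generate_cohort(cohort_spec(n_shoulders = 20, seed = 11))
  cl0 <- vapply(co$shoulders, function(s) s$truth$clearance_0_mm, numeric(1))
  cl30 <- vapply(co$shoulders, function(s) s$truth$clearance_30_mm,
                 numeric(1))
  expect_true(all(cl30 > cl0))
})

test_that("a zero AI-collision link makes outcomes independent of AI", {
  spec0 <- cohort_spec(n_shoulders = 30, logistic_beta0 = -0.3,
                       logistic_beta1 = 0, seed = 19)
  co <- generate_cohort(spec0)
  expect_equal(sd(co$table$propensity_0deg), 0)
  expect_lt(abs(cor(co$table$ai_target, co$table$shelf_anterior_mm)), 0.5)
  y <- vapply(co$shoulders, function(s)
    run_condition(s$shoulder, extension_deg = 0)$collides, logical(1))
  f <- suppressWarnings(logistic_fit(y, data.frame(AI = co$table$ai_target),
                                     "AI"))
  row <- f$or[f$or$term == "AI", ]
  expect_true(row$ci_low < 1 && 1 < row$ci_high)
})

test_that("written cohorts can be read back and re-simulated identically", {
  co <- generate_cohort(cohort_spec(n_shoulders = 2, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort_dir(co, dir)
  expect_true(file.exists(file.path(dir, "S001_humerus.stl")))
  expect_true(file.exists(file.path(dir, "S001_humerus.ply")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- read_cohort_dir(dir)
  r0 <- run_condition(co$shoulders[[1]]$shoulder, extension_deg = 0)
  r1 <- run_condition(back$shoulders[[1]]$shoulder, extension_deg = 0)
  expect_identical(r0$collides, r1$collides)
  expect_lt(abs(r0$clearance_mm - r1$clearance_mm), 1e-4)
  m0 <- measure_ai(co$shoulders[[2]]$shoulder)
  m1 <- measure_ai(back$shoulders[[2]]$shoulder)
  expect_lt(abs(m0$AI - m1$AI), 1e-5)
})
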
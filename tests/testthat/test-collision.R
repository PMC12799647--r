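test_that("separated and overlapping unit cubes give analytic results", {
  c1 <- box_mesh(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5))
  c2 <- box_mesh(c(9.5, 10.5), c(-0.5, 0.5), c(-0.5, 0.5))
  r <- detect_collision(c1, c2)
  expect_false(r$collides)
  expect_equal(r$clearance_mm, 9.0, tolerance = 1e-9)
  expect_length(r$contact_faces_a, 0)
  c3 <- box_mesh(c(0, 1), c(-0.5, 0.5), c(-0.5, 0.5))
  r2 <- detect_collision(c1, c3)
  expect_true(r2$collides)
  expect_lte(r2$clearance_mm, 0)
  expect_gt(length(r2$contact_faces_a), 0)
  expect_gt(length(r2$contact_faces_b), 0)
})

test_that("cylinder-plate gap matches the exact point-to-cylinder distance", {
  for (d in c(-0.5, 0.5)) {
    cyl <- cylinder_mesh(c(0, 0, -15), c(0, 0, 1), 30, 4, n_facets = 64)
    plate <- box_mesh(c(4 + d, 10 + d), c(-20, 20), c(-10, 10))
    r <- detect_collision(cyl, plate)
    expect_equal(r$collides, d <= 0)
    expect_lt(abs(r$clearance_mm - max(d, r$clearance_mm * (d < 0))), 0.05)
    if (d > 0) expect_lt(abs(r$clearance_mm - d), 0.05)
  }
})

test_that("touching within tolerance counts as contact", {
  c1 <- box_mesh(c(0, 1), c(0, 1), c(0, 1))
  c2 <- box_mesh(c(1.2, 2), c(0, 1), c(0, 1))
  expect_false(detect_collision(c1, c2)$collides)
  rt <- detect_collision(c1, c2, tolerance_mm = 0.5)
  expect_true(rt$collides)
  expect_gt(length(rt$contact_faces_a), 0)
})

test_that("full containment is detected with negative clearance", {
  inner <- box_mesh(c(-1, 1), c(-1, 1), c(-1, 1))
  outer <- box_mesh(c(-5, 5), c(-5, 5), c(-5, 5))
  r <- detect_collision(inner, outer)
  expect_true(r$collides)
  expect_lt(r$clearance_mm, 0)
  expect_equal(r$clearance_mm, -4, tolerance = 1e-6)
})

test_that("collision is symmetric and rigid-invariant", {
  set.seed(31)
  for (k in 1:5) {
    pp <- random_primitive_pair(sample(1:3, 1))
    r1 <- detect_collision(pp$a, pp$b)
    r2 <- detect_collision(pp$b, pp$a)
    expect_identical(r1$collides, r2$collides)
    expect_lt(abs(r1$clearance_mm - r2$clearance_mm), 1e-9)
    R <- random_rotation(); t <- runif(3, -10, 10)
    r3 <- detect_collision(transform_mesh(pp$a, R, t),
                           transform_mesh(pp$b, R, t))
    expect_identical(r3$collides, r1$collides)
    expect_lt(abs(abs(r3$clearance_mm) - abs(r1$clearance_mm)), 1e-6)
  }
})

test_that("binary outcome matches the closed-form oracle on random primitives", {
  res <- primitive_oracle_check(200, seed = 7)
  expect_gt(res$checked, 150)
  expect_equal(res$agree, res$checked)
})

test_that("run_condition reproduces analytic clearance scenarios", {
  # shelf far posterior of the trajectory: clear in both conditions
  far <- generate_shoulder(shoulder_params(shelf_anterior_mm = -20))
  r0 <- run_condition(far$shoulder, extension_deg = 0)
  r30 <- run_condition(far$shoulder, extension_deg = 30)
  expect_false(r0$collides)
  expect_false(r30$collides)
  expect_lt(abs(r0$clearance_mm - far$truth$clearance_0_mm), 0.05)
  # extreme lateral overhang over the neutral corridor: hit at 0 degrees only
  big <- generate_shoulder(shoulder_params(acromial_overhang_mm = 40,
                                           shelf_anterior_mm = 8))
  b0 <- run_condition(big$shoulder, extension_deg = 0)
  b30 <- run_condition(big$shoulder, extension_deg = 30)
  expect_true(b0$collides)
  expect_true(big$truth$clearance_0_mm <= 0)
  expect_false(b30$collides)
  expect_lt(abs(b30$clearance_mm - big$truth$clearance_30_mm), 0.05)
})

test_that("neutral-pose collision is monotone in the acromial overhang", {
  outcomes <- vapply(c(18, 21, 24, 30), function(ov) {
    g <- generate_shoulder(shoulder_params(acromial_overhang_mm = ov,
                                           shelf_anterior_mm = -3))
    run_condition(g$shoulder, extension_deg = 0)$collides
  }, logical(1))
  expect_true(all(diff(as.integer(outcomes)) >= 0))
  expect_false(outcomes[1])
  expect_true(outcomes[4])
})

test_that("collision outcome is stable across nail tessellations", {
  set.seed(17)
  co <- generate_cohort(cohort_spec(n_shoulders = 8, seed = 23))
  # away from exact tangency, 16 and 256 facets must agree
  for (s in co$shoulders) {
    if (abs(s$truth$clearance_0_mm) < 0.2) next
    a <- run_condition(s$shoulder, extension_deg = 0, n_facets = 16L)
    b <- run_condition(s$shoulder, extension_deg = 0, n_facets = 256L)
    expect_identical(a$collides, b$collides)
  }
})

test_that("contact PLY export colours the contact faces", {
  c1 <- box_mesh(c(0, 1), c(0, 1), c(0, 1))
  c2 <- box_mesh(c(0.5, 1.5), c(0, 1), c(0, 1))
  r <- detect_collision(c1, c2)
  path <- file.path(withr::local_tempdir(), "contact.ply")
  export_contact_ply(r, c1, c2, path)
  lines <- readLines(path)
  expect_true(any(grepl("255 0 0$", lines)))
})
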
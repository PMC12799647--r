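test_that("medullary axis recovery is exact on the straight synthetic shaft", {
  g <- generate_shoulder()
  ax <- estimate_medullary_axis(g$shoulder)
  expect_lt(angle_deg(ax$direction, g$truth$canal_axis$direction), 0.1)
  # perpendicular offset of the fitted line from the true axis
  rel <- ax$point - g$truth$canal_axis$point
  perp <- rel - sum(rel * g$truth$canal_axis$direction) *
    g$truth$canal_axis$direction
  expect_lt(sqrt(sum(perp^2)), 0.1)
})

test_that("medullary axis follows a tilted shaft", {
  g <- generate_shoulder(shoulder_params(tilt_axis = c(1, 0, 0),
                                         tilt_deg = 10))
  ax <- estimate_medullary_axis(g$shoulder)
  expect_lt(angle_deg(ax$direction, g$truth$canal_axis$direction), 0.2)
})

test_that("two slices suffice on an exact cylinder", {
  g <- generate_shoulder()
  a2 <- estimate_medullary_axis(g$shoulder, n_slices = 2)
  a20 <- estimate_medullary_axis(g$shoulder, n_slices = 20)
  expect_lt(angle_deg(a2$direction, a20$direction), 0.01)
})

test_that("axis error does not grow as mesh noise shrinks", {
  g <- generate_shoulder()
  err_at <- function(sd) {
    errs <- vapply(1:3, function(s) {
      sh <- g$shoulder
      set.seed(100 + s)
      sh$humerus$vertices <- sh$humerus$vertices +
        matrix(rnorm(length(sh$humerus$vertices), 0, sd),
               ncol = 3)
      angle_deg(estimate_medullary_axis(sh)$direction,
                g$truth$canal_axis$direction)
    }, numeric(1))
    mean(errs)
  }
  e <- vapply(c(0.6, 0.2, 0.05, 0), err_at, numeric(1))
  expect_true(all(diff(e) <= 0.02))
})

test_that("entry point is the analytic head apex with the footprint distance", {
  g <- generate_shoulder()
  ax <- estimate_medullary_axis(g$shoulder)
  ep <- compute_entry_point(g$shoulder, ax)
  expect_lt(max(abs(ep$entry_point - g$truth$apex)), 1e-6)
  expect_lt(abs(ep$distance_to_footprint - 7), 0.2)
  expect_true(ep$satisfies_5mm_rule)
})

test_that("a 3-mm footprint offset violates the 5-mm rule and is reported", {
  g <- generate_shoulder(shoulder_params(footprint_offset_mm = 3))
  ax <- estimate_medullary_axis(g$shoulder)
  expect_warning(ep <- compute_entry_point(g$shoulder, ax), "5 mm")
  expect_false(ep$satisfies_5mm_rule)
  expect_lt(abs(ep$distance_to_footprint - 3), 0.2)
})

test_that("entry point misses when the axis does not reach the head patch", {
  g <- generate_shoulder()
  off_axis <- line3(c(80, 0, 0), c(0, 0, 1))
  expect_error(compute_entry_point(g$shoulder, off_axis), "trajectory miss")
})

test_that("entry report is invariant under joint rigid transforms", {
  g <- generate_shoulder()
  ax <- estimate_medullary_axis(g$shoulder)
  ep0 <- compute_entry_point(g$shoulder, ax)
  set.seed(5)
  R <- random_rotation(); t <- runif(3, -30, 30)
  sh <- g$shoulder
  fr <- lapply(sh$humerus$frame, function(v) drop(R %*% v))
  sh$humerus <- transform_mesh(sh$humerus, R, t); sh$humerus$frame <- fr
  sh$scapula <- transform_mesh(sh$scapula, R, t); sh$scapula$frame <- fr
  ax2 <- line3(drop(R %*% ax$point) + t, drop(R %*% ax$direction))
  ep1 <- compute_entry_point(sh, ax2)
  expect_lt(max(abs(ep1$entry_point - (drop(R %*% ep0$entry_point) + t))),
            1e-6)
  expect_lt(abs(ep1$distance_to_footprint - ep0$distance_to_footprint), 1e-6)
})

test_that("place_nail builds the analytic cylinder at the entry point", {
  ax <- line3(c(0, 0, 0), c(0, 0, 1))
  nl <- place_nail(ax, c(0, 0, 100))
  expect_equal(range(nl$mesh$vertices[, 3]), c(-50, 100))
  r2 <- rowSums(nl$mesh$vertices[, 1:2]^2)
  expect_true(all(r2 <= 16 + 1e-6))
  expect_error(place_nail(ax, c(0, 0, 100), diameter_mm = 0), "positive")
  expect_error(place_nail(ax, c(3, 0, 100)), "off the nail axis")
})

test_that("posing is exact: identity at 0, invertible, anterior at extension", {
  g <- generate_shoulder()
  ax <- estimate_medullary_axis(g$shoulder)
  ep <- compute_entry_point(g$shoulder, ax)
  nl <- place_nail(ax, ep)
  ps <- study_poses(g$shoulder)
  p0 <- apply_pose(g$shoulder, nl, ps$transdeltoid_0)
  expect_equal(p0$humerus$vertices, g$shoulder$humerus$vertices)
  expect_equal(p0$nail$mesh$vertices, nl$mesh$vertices)
  p30 <- apply_pose(g$shoulder, nl, ps$anterolateral_30)
  back <- rotate_rigid(p30$humerus, ps$anterolateral_30$rotation_axis, -30)
  expect_lt(max(abs(back$vertices - g$shoulder$humerus$vertices)), 1e-9)
  # extension moves the proximal trajectory anteriorly (+y)
  tip0 <- nl$entry_point
  tip30 <- p30$nail$entry_point
  expect_gt(tip30[2], tip0[2])
  # nail stays collinear with the posed canal axis
  ax30_dir <- rotate_points(ax$point + ax$direction,
                            ps$anterolateral_30$rotation_axis, 30) -
    rotate_points(ax$point, ps$anterolateral_30$rotation_axis, 30)
  expect_lt(angle_deg(p30$nail$axis$direction, ax30_dir), 1e-9)
  # relative humerus-nail geometry preserved
  d0 <- g$shoulder$humerus$vertices[1, ] - nl$entry_point
  d30 <- p30$humerus$vertices[1, ] - p30$nail$entry_point
  expect_lt(abs(sqrt(sum(d0^2)) - sqrt(sum(d30^2))), 1e-9)
})

test_that("head sphere fit locates the centre of rotation", {
  g <- generate_shoulder()
  ps <- study_poses(g$shoulder)
  expect_lt(max(abs(ps$head_sphere$center)), 1e-6)
  expect_lt(abs(ps$head_sphere$radius - 24), 1e-6)
  expect_equal(ps$transdeltoid_0$name, "transdeltoid_0")
  expect_equal(ps$anterolateral_30$name, "anterolateral_30")
  expect_false(arm_pose(15, ps$transdeltoid_0$rotation_axis)$study_condition)
})
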
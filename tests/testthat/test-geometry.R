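test_that("sphere fit is exact on noiseless samples and translation-equivariant", {
  P <- sphere_points(100)
  s <- fit_sphere(P)
  expect_lt(max(abs(s$center)), 1e-9)
  expect_lt(abs(s$radius - 1), 1e-9)
  expect_lt(attr(s, "rms"), 1e-9)
  s2 <- fit_sphere(sweep(P, 2, c(5, -3, 2), "+"))
  expect_lt(max(abs(s2$center - c(5, -3, 2))), 1e-9)
  expect_lt(abs(s2$radius - 1), 1e-9)
})

test_that("sphere fit matches a geometric least-squares oracle under noise", {
  set.seed(11)
  P <- sphere_points(500, radius = 24) + matrix(rnorm(1500, 0, 0.3), 500)
  s <- fit_sphere(P)
  expect_lt(sqrt(sum(s$center^2)), 0.2)
  expect_lt(abs(s$radius - 24), 0.2)
  # independent oracle: geometric nonlinear least squares from the truth
  obj <- function(p) sum((sqrt(rowSums(sweep(P, 2, p[1:3])^2)) - p[4])^2)
  o <- stats::optim(c(0, 0, 0, 24), obj, method = "BFGS",
                    control = list(reltol = 1e-14))
  expect_lt(sqrt(sum((s$center - o$par[1:3])^2)), 0.05)
  expect_lt(abs(s$radius - o$par[4]), 0.05)
  # Gauss-Newton refinement moves the algebraic fit toward the oracle
  sr <- fit_sphere(P, refine = TRUE)
  expect_lt(sqrt(sum((sr$center - o$par[1:3])^2)), 1e-6)
})

test_that("sphere fit rejects degenerate input", {
  g <- as.matrix(expand.grid(x = 0:5, y = 0:5))
  expect_error(fit_sphere(cbind(g, 0)), "degenerate")
  expect_error(fit_sphere(sphere_points(3)), "degenerate")
})

test_that("plane fit recovers analytic planes and orients the normal", {
  g <- as.matrix(expand.grid(x = -3:3, y = -3:3))
  p <- fit_plane(cbind(g, 0))
  expect_lt(angle_deg(p$normal, c(0, 0, 1)), 1e-9)
  expect_lt(abs(p$point[3]), 1e-9)
  expect_lt(attr(p, "rms"), 1e-9)
  # z = 2x + 1 has normal proportional to (2, 0, -1)
  p2 <- fit_plane(cbind(g[, 1], g[, 2], 2 * g[, 1] + 1))
  expect_lt(angle_deg(p2$normal, c(2, 0, -1) / sqrt(5)), 1e-9)
  # lateral orientation flips the sign
  p3 <- fit_plane(cbind(g, 0), lateral = c(0, 0, -1))
  expect_lt(sum(p3$normal * c(0, 0, -1)) - 1, 1e-12)
})

test_that("plane fit is within 1 degree of truth under 0.1 mm noise", {
  set.seed(3)
  g <- as.matrix(expand.grid(x = seq(-10, 10, 2), y = seq(-10, 10, 2)))
  P <- cbind(g, rnorm(nrow(g), 0, 0.1))
  p <- fit_plane(P)
  expect_lt(angle_deg(p$normal, c(0, 0, 1)), 1)
  expect_error(fit_plane(cbind(1:9, 2 * (1:9), 3 * (1:9))), "degenerate")
})

test_that("line fit recovers exact lines and rejects identical points", {
  P <- cbind(0, 0, seq(-10, 10, 1))
  l <- fit_line(P, proximal = c(0, 0, 1))
  expect_lt(angle_deg(l$direction, c(0, 0, 1)), 1e-9)
  expect_identical(sum(l$direction * c(0, 0, 1)) > 0, TRUE)
  expect_lt(attr(l, "rms"), 1e-9)
  l2 <- fit_line(rbind(c(1, 2, 3), c(4, 6, 3)))
  expect_lt(angle_deg(l2$direction, c(3, 4, 0)), 1e-9)
  expect_error(fit_line(rbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")
})

test_that("rigid rotation follows the right-hand rule and is an isometry", {
  m <- triangle_mesh(rbind(c(1, 0, 0), c(0, 0, 2), c(2, 1, 1)),
                     rbind(c(1L, 2L, 3L)))
  z <- line3(c(0, 0, 0), c(0, 0, 1))
  expect_equal(rotate_rigid(m, z, 0)$vertices, m$vertices)
  expect_lt(max(abs(rotate_rigid(m, z, 360)$vertices - m$vertices)), 1e-9)
  r <- rotate_rigid(m, z, 90)
  expect_lt(max(abs(r$vertices[1, ] - c(0, 1, 0))), 1e-12)
  # distances and areas preserved on a larger mesh
  box <- box_mesh(c(-3, 2), c(-1, 4), c(0, 5), res = 2)
  ax <- line3(c(1, -2, 0.5), c(1, 2, -1))
  rb <- rotate_rigid(box, ax, 37.3)
  d0 <- as.vector(dist(box$vertices[1:40, ]))
  d1 <- as.vector(dist(rb$vertices[1:40, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_lt(max(abs(face_areas(box) - face_areas(rb)) /
                  pmax(face_areas(box), 1)), 1e-9)
})

test_that("sphere and plane fits are equivariant under rigid transforms", {
  set.seed(21)
  P <- sphere_points(200, center = c(2, -1, 4), radius = 7) +
    matrix(rnorm(600, 0, 0.05), 200)
  g <- as.matrix(expand.grid(x = seq(-5, 5, 1), y = seq(-5, 5, 1)))
  Q <- cbind(g, rnorm(nrow(g), 0, 0.05))
  for (k in 1:5) {
    R <- random_rotation()
    t <- runif(3, -20, 20)
    s0 <- fit_sphere(P)
    s1 <- fit_sphere(P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE))
    expect_lt(max(abs(s1$center - (drop(R %*% s0$center) + t))), 1e-6)
    expect_lt(abs(s1$radius - s0$radius), 1e-6)
    p0 <- fit_plane(Q)
    p1 <- fit_plane(Q %*% t(R) + matrix(t, nrow(Q), 3, byrow = TRUE))
    expect_lt(angle_deg(p1$normal, drop(R %*% p0$normal)), 1e-4)
    # transformed fit point lies on the transformed plane
    expect_lt(abs(sum((drop(R %*% p0$point) + t - p1$point) * p1$normal)),
              1e-6)
  }
})
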
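# Shared fixtures: deterministic point samples, canonical triangle soups,
# random rigid transforms, and analytic primitive pairs with closed-form
# separation distances (the independent oracle for the collision kernel).

# golden-spiral sample of a sphere surface (deterministic, exactly on-sphere)
sphere_points <- function(n, center = c(0, 0, 0), radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(theta),
        center[2] + radius * sin(phi) * sin(theta),
        center[3] + radius * cos(phi))
}

# order-independent representation of a mesh as a sorted triangle soup
canonical_tris <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  tri <- cbind(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  tri <- t(apply(tri, 1, function(r) {
    pts <- matrix(r, 3, 3, byrow = TRUE)
    pts <- pts[order(pts[, 1], pts[, 2], pts[, 3]), ]
    as.vector(t(pts))
  }))
  tri[do.call(order, as.data.frame(tri)), , drop = FALSE]
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  nailsim::rotation_about_axis(ax / sqrt(sum(ax^2)),
                               stats::runif(1, -180, 180))
}

angle_deg <- function(u, v) {
  cu <- u / sqrt(sum(u^2)); cv <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(sum(cu * cv)))) * 180 / pi
}

# one random primitive pair with its closed-form signed separation:
# type 1 sphere-sphere, 2 cylinder-plate (lateral gap), 3 box-box
random_primitive_pair <- function(type) {
  if (type == 1L) {
    c1 <- stats::runif(3, -10, 10); r1 <- stats::runif(1, 3, 8)
    dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    gap <- stats::runif(1, -3, 6)
    r2 <- stats::runif(1, 3, 8)
    c2 <- c1 + dirn * (r1 + r2 + gap)
    m1 <- uv_sphere_mesh(c1, r1, n_az = 48, n_rings = 24)
    m2 <- uv_sphere_mesh(c2, r2, n_az = 48, n_rings = 24)
    list(a = m1, b = m2, dist = gap)
  } else if (type == 2L) {
    r <- stats::runif(1, 3, 6)
    cx <- stats::runif(1, -5, 5); cy <- stats::runif(1, -5, 5)
    cyl <- cylinder_mesh(c(cx, cy, -15), c(0, 0, 1), 30, r, n_facets = 64)
    gap <- stats::runif(1, -2, 5)
    x0 <- cx + r + gap
    plate <- box_mesh(c(x0, x0 + 6), cy + c(-20, 20), c(-10, 10))
    list(a = cyl, b = plate, dist = gap)
  } else {
    lo1 <- stats::runif(3, -10, 0); hi1 <- lo1 + stats::runif(3, 2, 8)
    lo2 <- stats::runif(3, -10, 0); hi2 <- lo2 + stats::runif(3, 2, 8)
    g <- pmax(lo1 - hi2, lo2 - hi1)
    d <- if (all(g < 0)) max(g) else sqrt(sum(pmax(g, 0)^2))
    list(a = box_mesh(c(lo1[1], hi1[1]), c(lo1[2], hi1[2]),
                      c(lo1[3], hi1[3])),
         b = box_mesh(c(lo2[1], hi2[1]), c(lo2[2], hi2[2]),
                      c(lo2[3], hi2[3])),
         dist = d)
  }
}

# tessellation guard band: curved primitives are compared to the closed form
# only when the analytic gap is clearly away from the chord error
primitive_oracle_check <- function(n_configs, seed, guard = 0.05) {
  set.seed(seed)
  checked <- 0L; agree <- 0L
  for (k in seq_len(n_configs)) {
    type <- sample(1:3, 1)
    pp <- random_primitive_pair(type)
    g <- if (type == 3L) 1e-9 else guard
    if (abs(pp$dist) < g) next
    res <- detect_collision(pp$a, pp$b)
    checked <- checked + 1L
    if (res$collides == (pp$dist <= 0)) agree <- agree + 1L
  }
  list(checked = checked, agree = agree)
}

# a small calibration study cached across test files
calibration_study <- local({
  cache <- NULL
  function(n = 68, seed = 1, B = 500) {
    if (is.null(cache))
      cache <<- run_study(run_config(cohort = cohort_spec(n_shoulders = n),
                                     seed = seed, bootstrap_B = B))
    cache
  }
})
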
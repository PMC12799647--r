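# Parametric synthetic shoulders with analytic ground truth, and seeded
# cohorts whose Acromion Index distribution and AI -> collision link emulate
# a clinical series. Geometry is deliberately idealized (spherical head,
# cylindrical hollow shaft, planar glenoid disc, box-shaped acromial shelf):
# every derived quantity (canal axis, entry apex, GA, GH, AI, trajectory
# clearance) then has a closed form against which the pipeline is tested.

# Calibration constants of the default cohort (frozen; changing them is a
# breaking change to downstream acceptance checks). The anterior edge of the
# acromial shelf is placed at
#   y_ant = y_crit + (sd_y / 1.7) * (beta0 + beta1 * AI) + eps,
#       eps ~ N(0, sd_y),
# so that P(0-deg collision | AI) ~ logistic(beta0 + beta1 * AI): the shelf
# reaches the insertion corridor (tangent at y_crit) with probit probability
# matched to the logistic via the canonical 1.7 scale factor. beta1 = 11.2
# per AI unit corresponds to an odds ratio of ~3 per +0.10 AI; beta0 places
# the 50% point at AI = 0.69.
.calib <- list(
  y_crit = -4,         # corridor tangent: nail radius, mm
  sd_y = 3,            # SD of the anteroposterior shelf-position noise, mm
  beta0 = -7.73,
  beta1 = 11.2,
  height_sd = 1.5      # SD of the acromial-height noise, mm
)

#' Parameters of one synthetic shoulder
#'
#' All lengths in mm. The humeral head is a sphere of `head_radius_mm`
#' centred at the origin; the hollow shaft (outer/canal radii) descends along
#' -z; the glenoid plane sits `glenoid_offset_mm` medial of the medial head
#' surface; the acromial shelf floats `acromial_height_mm` above the head
#' apex and reaches `acromial_overhang_mm` laterally beyond the glenoid
#' plane (this is the Acromion-Index-controlling parameter: AI =
#' overhang / GH with GH = 2 * head_radius + glenoid_offset).
#'
#' @param head_radius_mm humeral head radius (default 24).
#' @param shaft_length_mm diaphysis length (default 120).
#' @param shaft_outer_radius_mm outer cortex radius (default 11).
#' @param canal_radius_mm medullary canal radius (default 6).
#' @param neck_shaft_angle_deg orientation of the articular cap: the cap
#'   normal is tilted (180 - angle) degrees medially from the canal axis
#'   (default 135, i.e. a vertical canal with a supero-medially facing head).
#' @param glenoid_offset_mm gap between the glenoid plane and the medial
#'   head surface (default 1.5, giving GH = 49.5 at the default radius).
#' @param acromial_overhang_mm lateral reach of the shelf beyond the glenoid
#'   plane; default reproduces AI = 0.668.
#' @param acromial_height_mm clearance between head apex and shelf underside
#'   (default 8).
#' @param footprint_offset_mm distance from the head apex to the nearest
#'   supraspinatus-footprint vertex (default 7).
#' @param shelf_anterior_mm anterior edge (y) of the shelf; `NULL` (default)
#'   places it on the calibration line for the given overhang, with no noise.
#' @param shelf_depth_mm anteroposterior shelf depth (default 25).
#' @param shelf_thickness_mm shelf thickness (default 8).
#' @param mesh_resolution target edge length of the generated meshes
#'   (default 2.5).
#' @param tilt_axis,tilt_deg optional rigid tilt of the whole humerus (and
#'   its ground truth) about an axis through the head centre; used to test
#'   axis recovery on non-canonical orientations.
#' @param side "left" or "right" (metadata; geometry uses the common
#'   +x-lateral frame either way).
#' @param seed recorded for provenance (generation itself is deterministic).
#' @return a list of class `shoulder_params`.
#' @export
shoulder_params <- function(head_radius_mm = 24,
                            shaft_length_mm = 120,
                            shaft_outer_radius_mm = 11,
                            canal_radius_mm = 6,
                            neck_shaft_angle_deg = 135,
                            glenoid_offset_mm = 1.5,
                            acromial_overhang_mm = 0.668 * (2 * 24 + 1.5),
                            acromial_height_mm = 8,
                            footprint_offset_mm = 7,
                            shelf_anterior_mm = NULL,
                            shelf_depth_mm = 25,
                            shelf_thickness_mm = 8,
                            mesh_resolution = 2.5,
                            tilt_axis = NULL,
                            tilt_deg = 0,
                            side = "right",
                            seed = 0L) {
  p <- as.list(environment())
  lengths <- c(p$head_radius_mm, p$shaft_length_mm, p$shaft_outer_radius_mm,
               p$canal_radius_mm, p$acromial_overhang_mm,
               p$acromial_height_mm, p$shelf_depth_mm, p$shelf_thickness_mm,
               p$mesh_resolution)
  if (any(lengths <= 0)) stop("all lengths must be positive")
  if (p$canal_radius_mm >= p$shaft_outer_radius_mm)
    stop("canal_radius_mm must be smaller than shaft_outer_radius_mm")
  if (p$footprint_offset_mm < 0) stop("footprint_offset_mm must be >= 0")
  if (p$footprint_offset_mm >= 2 * p$head_radius_mm)
    stop("footprint_offset_mm exceeds the head diameter")
  if (p$acromial_height_mm <= 0.5)
    stop("generation error: acromial shelf intersects the humeral head ",
         "(acromial_height_mm too small)")
  if (!p$side %in% c("left", "right")) stop("side must be left or right")
  structure(p, class = "shoulder_params")
}

#' Acromion Index implied by an acromial overhang (analytic generator map)
#' @param overhang_mm lateral shelf reach beyond the glenoid plane (mm).
#' @param params a `shoulder_params` (for head radius and glenoid offset).
#' @return AI = overhang / GH.
#' @export
ai_from_overhang <- function(overhang_mm, params = shoulder_params()) {
  gh <- 2 * params$head_radius_mm + params$glenoid_offset_mm
  overhang_mm / gh
}

#' Invert the AI-overhang map (bisection on the monotone forward map)
#' @param ai target Acromion Index.
#' @param params a `shoulder_params`.
#' @param tol bisection tolerance on the overhang (mm).
#' @return overhang in mm.
#' @export
overhang_from_ai <- function(ai, params = shoulder_params(), tol = 1e-6) {
  gh <- 2 * params$head_radius_mm + params$glenoid_offset_mm
  vapply(ai, function(a) {
    stats::uniroot(function(o) ai_from_overhang(o, params) - a,
                   interval = c(1e-6, 3 * gh), tol = tol)$root
  }, numeric(1))
}

# default anterior shelf edge on the calibration line (no noise)
shelf_anterior_default <- function(overhang_mm, params) {
  ai <- ai_from_overhang(overhang_mm, params)
  .calib$y_crit + (.calib$sd_y / 1.7) * (.calib$beta0 + .calib$beta1 * ai)
}

#' Generate one synthetic shoulder with analytic ground truth
#'
#' Constructs the humerus (spherical head + hollow cylindrical shaft with a
#' straight medullary canal through the head centre, supraspinatus footprint
#' patch at a known chord distance lateral of the apex) and the scapula
#' (glenoid disc spanning the glenoid plane + box-shaped acromial shelf),
#' with all landmark patches labelled.
#'
#' @param params a [shoulder_params()].
#' @return list with elements `shoulder` (a `shoulder_model`) and `truth`:
#'   canal axis, entry apex, GA/GH/AI, and the analytic signed clearance of
#'   the 8-mm insertion corridor at 0 and 30 degrees of extension.
#' @export
generate_shoulder <- function(params = shoulder_params()) {
  if (!inherits(params, "shoulder_params")) params <- do.call(shoulder_params, params)
  R <- params$head_radius_mm
  res <- params$mesh_resolution
  f <- params$footprint_offset_mm
  gh_true <- 2 * R + params$glenoid_offset_mm
  x_plane <- -(R + params$glenoid_offset_mm)

  # --- humeral head: UV sphere, pole on the canal axis; exact rings at the
  #     footprint chord distance and at the equator (lateral cortex vertex)
  theta_fp <- 2 * asin(min(f / (2 * R), 1))
  n_az <- max(36L, ceiling(2 * pi * R / res))
  n_rings <- max(18L, ceiling(pi * R / res))
  head <- uv_sphere_mesh(c(0, 0, 0), R, pole_dir = c(0, 0, 1),
                         n_az = n_az, n_rings = n_rings,
                         extra_ring_angles = c(theta_fp, pi / 2,
                                               theta_fp + 4 / R))
  nh <- nrow(head$vertices)

  # --- hollow shaft along -z, canal collinear with the head-centre axis
  z_top <- -0.6 * R
  shaft <- tube_mesh(c(0, 0, z_top - params$shaft_length_mm), c(0, 0, 1),
                     params$shaft_length_mm, params$shaft_outer_radius_mm,
                     params$canal_radius_mm,
                     n_facets = max(32L, ceiling(
                       2 * pi * params$shaft_outer_radius_mm / res)),
                     n_len = max(6L, ceiling(params$shaft_length_mm / 5)))
  humerus <- merge_meshes(head, shaft)

  # landmark patches (vertex index sets)
  hv <- humerus$vertices
  apex <- c(0, 0, R)
  tiltcap <- (180 - params$neck_shaft_angle_deg) * pi / 180
  p_art <- c(-sin(tiltcap), 0, cos(tiltcap))   # articular cap normal
  relh <- hv[seq_len(nh), , drop = FALSE]
  cosang <- drop(relh %*% p_art) / R
  head_region <- which(cosang >= cos(75 * pi / 180))
  chord <- sqrt(rowSums((relh - matrix(apex, nh, 3, byrow = TRUE))^2))
  az <- atan2(relh[, 2], relh[, 1])
  footprint <- which(chord >= f - 1e-9 & chord <= f + 4 &
                       abs(az) <= 35 * pi / 180 & relh[, 3] > 0)
  shaft_idx <- nh + seq_len(nrow(shaft$vertices))
  shaft_region <- shaft_idx[hv[shaft_idx, 3] <= z_top - 5]

  # --- scapula: glenoid disc + acromial shelf
  disc <- cylinder_mesh(c(x_plane - 3, 0, 0), c(1, 0, 0), 3, 16,
                        n_facets = max(24L, ceiling(2 * pi * 16 / res)),
                        n_len = 1L)
  nd <- nrow(disc$vertices)
  glenoid_face <- which(abs(disc$vertices[, 1] - x_plane) < 1e-9)
  y_ant <- params$shelf_anterior_mm
  if (is.null(y_ant))
    y_ant <- shelf_anterior_default(params$acromial_overhang_mm, params)
  z_lo <- R + params$acromial_height_mm
  shelf <- box_mesh(c(x_plane, x_plane + params$acromial_overhang_mm),
                    c(y_ant - params$shelf_depth_mm, y_ant),
                    c(z_lo, z_lo + params$shelf_thickness_mm),
                    res = max(res, 4))
  scapula <- merge_meshes(disc, shelf)
  acromion <- nd + seq_len(nrow(shelf$vertices))

  axis <- line3(c(0, 0, 0), c(0, 0, 1))
  entry <- apex
  fp_near <- c(2 * R * sin(theta_fp / 2) * cos(theta_fp / 2), 0,
               R * cos(theta_fp))  # nearest footprint vertex (azimuth 0)

  # optional rigid tilt of the humeral anatomy about the head centre
  if (!is.null(params$tilt_axis) && params$tilt_deg != 0) {
    tax <- line3(c(0, 0, 0), params$tilt_axis)
    humerus <- rotate_rigid(humerus, tax, params$tilt_deg)
    axis <- line3(rotate_points(axis$point, tax, params$tilt_deg),
                  rotate_points(axis$point + axis$direction, tax,
                                params$tilt_deg) -
                    rotate_points(axis$point, tax, params$tilt_deg))
    entry <- rotate_points(entry, tax, params$tilt_deg)
    fp_near <- rotate_points(fp_near, tax, params$tilt_deg)
  }

  shoulder <- shoulder_model(humerus, scapula,
                             landmarks = list(
                               head_region = head_region,
                               shaft_region = shaft_region,
                               supraspinatus_footprint = footprint,
                               glenoid_face = glenoid_face,
                               acromion = acromion),
                             side = params$side)

  ga_true <- params$acromial_overhang_mm
  gh_mesh <- max(humerus$vertices[, 1]) - x_plane
  box <- list(x = c(x_plane, x_plane + ga_true),
              y = c(y_ant - params$shelf_depth_mm, y_ant),
              z = c(z_lo, z_lo + params$shelf_thickness_mm))
  cl0 <- corridor_box_clearance(entry, axis$direction, box, radius = 4,
                                extension_deg = 0, head_center = c(0, 0, 0))
  cl30 <- corridor_box_clearance(entry, axis$direction, box, radius = 4,
                                 extension_deg = 30, head_center = c(0, 0, 0))
  truth <- list(canal_axis = axis, entry = entry, apex = entry,
                footprint_nearest = fp_near,
                GA_mm = ga_true, GH_mm = gh_mesh,
                AI = ga_true / gh_mesh,
                GH_analytic = gh_true,
                shelf_anterior_mm = y_ant,
                clearance_0_mm = cl0, clearance_30_mm = cl30)
  list(shoulder = shoulder, truth = truth, params = params)
}

# analytic clearance between the posed 8-mm insertion corridor (a segment
# of half-length 150 mm about the entry point along the canal axis, swept
# radius `radius`) and an axis-aligned box; distance from a convex box to a
# point on the segment is convex in the segment parameter, so a 1-D golden
# search is exact.
corridor_box_clearance <- function(entry, dir, box, radius = 4,
                                   extension_deg = 0,
                                   head_center = c(0, 0, 0), half_len = 150) {
  p0 <- entry - half_len * dir
  p1 <- entry + half_len * dir
  if (extension_deg != 0) {
    ax <- line3(head_center, -c(1, 0, 0))  # mediolateral axis, medial dir
    p0 <- rotate_points(p0, ax, extension_deg)
    p1 <- rotate_points(p1, ax, extension_deg)
  }
  ptbox <- function(p) {
    d <- pmax(c(box$x[1] - p[1], box$y[1] - p[2], box$z[1] - p[3]),
              c(p[1] - box$x[2], p[2] - box$y[2], p[3] - box$z[2]), 0)
    sqrt(sum(d^2))
  }
  fopt <- stats::optimize(function(t) ptbox(p0 + t * (p1 - p0)),
                          interval = c(0, 1), tol = 1e-10)
  fopt$objective - radius
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the structure of a 68-shoulder clinical series: AI drawn
#' from a truncated normal (0.668 +- 0.082 on [0.50, 0.93]), 73.7% male,
#' age 48.3 +- 18.7 years, and a logistic AI -> collision link with an odds
#' ratio near 3 per +0.10 AI.
#'
#' @param n_shoulders cohort size (default 68).
#' @param ai_mean,ai_sd,ai_bounds truncated-normal AI distribution.
#' @param logistic_beta0,logistic_beta1 intercept and per-unit-AI slope of
#'   the intended log-odds of 0-degree collision; they drive the
#'   anteroposterior shelf placement (see package vignette). `beta1 = 0`
#'   makes collision independent of AI.
#' @param geom_noise_sd_mm SD of the anteroposterior shelf-position noise.
#' @param height_noise_sd_mm SD of the acromial-height noise.
#' @param head_radius_sd_mm SD of the humeral head radius across shoulders
#'   (default 1.3, giving a joint-width spread comparable to adult
#'   morphometry); the AI-overhang inversion uses each shoulder's own
#'   geometry.
#' @param sex_fraction_male,age_mean,age_sd demographic marginals.
#' @param left_fraction probability a shoulder is a left side.
#' @param base_params `shoulder_params` template for the fixed geometry.
#' @param seed RNG seed; the cohort is fully reproducible from (spec, seed).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_shoulders = 68L,
                        ai_mean = 0.668, ai_sd = 0.082,
                        ai_bounds = c(0.50, 0.93),
                        logistic_beta0 = .calib$beta0,
                        logistic_beta1 = .calib$beta1,
                        geom_noise_sd_mm = .calib$sd_y,
                        height_noise_sd_mm = .calib$height_sd,
                        head_radius_sd_mm = 1.3,
                        sex_fraction_male = 0.737,
                        age_mean = 48.3, age_sd = 18.7,
                        left_fraction = 0.574,
                        base_params = shoulder_params(),
                        seed = 1L) {
  if (n_shoulders < 2L) stop("n_shoulders must be >= 2")
  if (ai_sd <= 0) stop("ai_sd must be positive")
  if (sex_fraction_male < 0 || sex_fraction_male > 1)
    stop("sex_fraction_male must be in [0, 1]")
  structure(as.list(environment()), class = "cohort_spec")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(2L * n, 10L), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a seeded synthetic cohort
#'
#' Samples AI from the truncated normal, inverts the monotone AI-overhang
#' map to set each shoulder's geometry, perturbs the anteroposterior shelf
#' position and the acromial height (the per-shoulder geometric noise that
#' makes AI predictive but not deterministic of collision), and assigns
#' sex, age and side. The recorded `propensity_0deg` is the intended
#' logistic collision probability; actual outcomes come from running the
#' simulation on the meshes.
#'
#' @param spec a [cohort_spec()].
#' @return list with `shoulders` (list of [generate_shoulder()] outputs) and
#'   `table` (one row per shoulder: id, side, sex, age, AI target, geometry,
#'   propensity).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_shoulders
  ai <- rtruncnorm1(n, spec$ai_mean, spec$ai_sd,
                    spec$ai_bounds[1], spec$ai_bounds[2])
  radius <- rtruncnorm1(n, spec$base_params$head_radius_mm,
                        max(spec$head_radius_sd_mm, 1e-9),
                        spec$base_params$head_radius_mm - 5,
                        spec$base_params$head_radius_mm + 5)
  overhang <- vapply(seq_len(n), function(i) {
    p <- spec$base_params
    p$head_radius_mm <- radius[i]
    overhang_from_ai(ai[i], p)
  }, numeric(1))
  lin <- spec$logistic_beta0 + spec$logistic_beta1 * ai
  y_ant <- .calib$y_crit + (spec$geom_noise_sd_mm / 1.7) * lin +
    stats::rnorm(n, 0, spec$geom_noise_sd_mm)
  height <- pmax(2, stats::rnorm(n, spec$base_params$acromial_height_mm,
                                 spec$height_noise_sd_mm))
  sex <- ifelse(stats::runif(n) < spec$sex_fraction_male, "male", "female")
  age <- rtruncnorm1(n, spec$age_mean, spec$age_sd, 18, 91)
  side <- ifelse(stats::runif(n) < spec$left_fraction, "left", "right")
  shoulders <- vector("list", n)
  for (i in seq_len(n)) {
    p <- spec$base_params
    p$head_radius_mm <- radius[i]
    p$acromial_overhang_mm <- overhang[i]
    p$shelf_anterior_mm <- y_ant[i]
    p$acromial_height_mm <- height[i]
    p$side <- side[i]
    p$seed <- spec$seed + i
    shoulders[[i]] <- generate_shoulder(do.call(shoulder_params, p[
      setdiff(names(p), character(0))]))
  }
  table <- data.frame(
    shoulder_id = sprintf("S%03d", seq_len(n)),
    side = side, sex = sex, age_years = age,
    ai_target = ai, head_radius_mm = radius, overhang_mm = overhang,
    shelf_anterior_mm = y_ant, acromial_height_mm = height,
    propensity_0deg = stats::plogis(lin),
    stringsAsFactors = FALSE)
  list(shoulders = shoulders, table = table, spec = spec)
}
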
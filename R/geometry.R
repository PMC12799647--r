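# Least-squares geometric primitives shared by all pipeline stages:
# sphere fit (humeral head -> centre of rotation), plane fit (glenoid face),
# line fit (medullary canal axis), and rigid rotation about an axis.

#' Construct a plane (point + unit normal)
#' @param point 3-vector on the plane (mm).
#' @param normal 3-vector; normalized internally.
#' @return object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unit3(as.numeric(normal))),
            class = "plane3")
}

#' Construct a sphere
#' @param center 3-vector (mm).
#' @param radius positive radius (mm).
#' @return object of class `sphere3`.
#' @export
sphere3 <- function(center, radius) {
  if (radius <= 0) stop("sphere radius must be positive")
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "sphere3")
}

#' Construct a 3D line (point + unit direction)
#' @param point 3-vector on the line (mm).
#' @param direction 3-vector; normalized internally.
#' @return object of class `line3`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = unit3(as.numeric(direction))),
            class = "line3")
}

# condition-number guard for near-degenerate normal equations
.degenerate_kappa <- 1e8

#' Least-squares sphere fit
#'
#' Algebraic (Coope) linear least squares: minimizes
#' \eqn{\sum_i (|x_i|^2 - 2 c^T x_i - \rho)^2} with \eqn{\rho = r^2 - |c|^2},
#' which is linear in \eqn{(c, \rho)}. Optionally refined by geometric
#' Gauss-Newton on the orthogonal residuals. Used to locate the humeral-head
#' centre of rotation.
#'
#' @param points n x 3 matrix of surface samples (mm), n >= 4, non-coplanar.
#' @param refine run Gauss-Newton refinement of the geometric fit
#'   (default FALSE: the algebraic fit is deterministic and, on near-spherical
#'   heads, within ~0.1 mm of the geometric optimum).
#' @return a `sphere3` with attribute `rms` (root-mean-square orthogonal
#'   residual, mm).
#' @export
fit_sphere <- function(points, refine = FALSE) {
  P <- as.matrix(points)
  if (nrow(P) < 4L) stop("degenerate input: sphere fit needs >= 4 points")
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  AtA <- crossprod(A)
  sv <- svd(AtA, nu = 0, nv = 0)$d
  if (sv[4] <= sv[1] / .degenerate_kappa)
    stop("degenerate input: points are (near-)coplanar, sphere fit undefined")
  sol <- solve(AtA, crossprod(A, b))
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (r2 <= 0) stop("degenerate input: non-positive fitted radius")
  r <- sqrt(r2)
  if (refine) {
    for (it in 1:20) {
      d <- sqrt(rowSums((P - matrix(ctr, nrow(P), 3, byrow = TRUE))^2))
      res <- d - r
      J <- cbind(-(P - matrix(ctr, nrow(P), 3, byrow = TRUE)) / d, -1)
      step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                       error = function(e) rep(0, 4))
      ctr <- ctr - step[1:3]; r <- r - step[4]
      if (sqrt(sum(step^2)) < 1e-10) break
    }
  }
  d <- sqrt(rowSums((P - matrix(ctr, nrow(P), 3, byrow = TRUE))^2))
  out <- sphere3(ctr, r)
  attr(out, "rms") <- sqrt(mean((d - r)^2))
  out
}

#' Total-least-squares plane fit
#'
#' SVD of the centred points; the singular vector of the smallest singular
#' value is the normal. Houses the glenoid-face reference plane for the
#' Acromion Index.
#'
#' @param points n x 3 matrix, n >= 3, non-collinear.
#' @param lateral optional 3-vector; the normal sign is flipped, if needed,
#'   to have a positive dot product with this (anatomically lateral)
#'   direction.
#' @return a `plane3` with attribute `rms` (orthogonal residual, mm).
#' @export
fit_plane <- function(points, lateral = NULL) {
  P <- as.matrix(points)
  if (nrow(P) < 3L) stop("degenerate input: plane fit needs >= 3 points")
  ctr <- colMeans(P)
  X <- sweep(P, 2L, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1) ||
      (sv$d[2] > 0 && sv$d[1] / sv$d[2] > .degenerate_kappa))
    stop("degenerate input: points are (near-)collinear, plane fit undefined")
  n <- sv$v[, 3]
  if (!is.null(lateral) && sum(n * lateral) < 0) n <- -n
  out <- plane3(ctr, n)
  attr(out, "rms") <- sqrt(mean((X %*% n)^2))
  out
}

#' Total-least-squares line fit
#'
#' SVD of the centred points; the singular vector of the largest singular
#' value is the direction. Houses the medullary canal axis through the
#' slice centroids.
#'
#' @param points n x 3 matrix, n >= 2, not all identical.
#' @param proximal optional 3-vector; the direction sign is flipped, if
#'   needed, to have a positive dot product with this (anatomically
#'   superior/proximal) direction.
#' @return a `line3` with attribute `rms` (orthogonal residual, mm).
#' @export
fit_line <- function(points, proximal = NULL) {
  P <- as.matrix(points)
  if (nrow(P) < 2L) stop("degenerate input: line fit needs >= 2 points")
  ctr <- colMeans(P)
  X <- sweep(P, 2L, ctr)
  sv <- svd(X, nu = 0)
  if (sv$d[1] < 1e-12)
    stop("degenerate input: all points identical, line fit undefined")
  d <- sv$v[, 1]
  if (!is.null(proximal) && sum(d * proximal) < 0) d <- -d
  out <- line3(ctr, d)
  perp <- X - (X %*% d) %*% t(d)
  attr(out, "rms") <- sqrt(mean(rowSums(perp^2)))
  out
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues)
#' @param axis 3-vector (normalized internally).
#' @param angle_deg signed angle in degrees; positive is counter-clockwise
#'   about the axis direction (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- unit3(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid rotation of a mesh about a 3D axis
#'
#' Rodrigues rotation of all vertices about `axis`; the face table and all
#' pairwise distances are preserved. Positive angles follow the right-hand
#' rule about `axis$direction`.
#'
#' @param mesh a `triangle_mesh`.
#' @param axis a `line3` (rotation axis).
#' @param angle_deg signed degrees.
#' @return the rotated `triangle_mesh`.
#' @export
rotate_rigid <- function(mesh, axis, angle_deg) {
  R <- rotation_about_axis(axis$direction, angle_deg)
  p0 <- axis$point
  mesh$vertices <- sweep(sweep(mesh$vertices, 2L, p0) %*% t(R), 2L, p0, "+")
  mesh
}

#' Rotate a bare point set about an axis (same convention as [rotate_rigid])
#' @param points n x 3 matrix or 3-vector.
#' @inheritParams rotate_rigid
#' @return rotated points, same shape.
#' @export
rotate_points <- function(points, axis, angle_deg) {
  one <- is.null(dim(points))
  P <- if (one) matrix(points, 1, 3) else as.matrix(points)
  R <- rotation_about_axis(axis$direction, angle_deg)
  out <- sweep(sweep(P, 2L, axis$point) %*% t(R), 2L, axis$point, "+")
  if (one) drop(out) else out
}

#' Signed distances of points from a plane
#' @param points n x 3 matrix or 3-vector.
#' @param plane a `plane3`.
#' @return numeric vector of signed distances (positive on the normal side).
#' @export
plane_distance <- function(points, plane) {
  P <- if (is.null(dim(points))) matrix(points, 1, 3) else as.matrix(points)
  drop(sweep(P, 2L, plane$point) %*% plane$normal)
}
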
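# Parametric mesh primitives used by the synthetic generator and the nail
# model: UV sphere (with exact rings on demand), solid cylinder, hollow
# tube and axis-aligned box.

#' UV-sphere mesh with caller-chosen latitude rings
#'
#' Rings are placed at the polar angles in `ring_angles` (radians from the
#' pole direction); extra exact rings (e.g. the equator, or the ring at a
#' prescribed chord distance from the apex) can be forced so that landmark
#' vertices sit at analytically known positions.
#'
#' @param center 3-vector (mm).
#' @param radius mm.
#' @param pole_dir pole (apex) direction; azimuth 0 is aligned with the
#'   projection of +x (lateral) onto the equatorial plane.
#' @param n_az azimuthal segments.
#' @param n_rings number of evenly spaced latitude rings.
#' @param extra_ring_angles polar angles (radians) of rings that must exist
#'   exactly.
#' @return a `triangle_mesh`.
#' @export
uv_sphere_mesh <- function(center, radius, pole_dir = c(0, 0, 1),
                           n_az = 48L, n_rings = 24L,
                           extra_ring_angles = numeric()) {
  p <- unit3(pole_dir)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * p)) > 0.99) ref <- c(0, 1, 0)
  u <- unit3(ref - sum(ref * p) * p)
  v <- cross3(p, u)
  th <- sort(unique(c(seq(0, pi, length.out = n_rings + 2L)[-c(1L, n_rings + 2L)],
                      extra_ring_angles)))
  th <- th[th > 1e-9 & th < pi - 1e-9]
  phi <- 2 * pi * (seq_len(n_az) - 1L) / n_az
  ring <- function(t) {
    d <- outer(cos(phi), u) + outer(sin(phi), v)
    matrix(center, n_az, 3, byrow = TRUE) +
      radius * (cos(t) * matrix(p, n_az, 3, byrow = TRUE) + sin(t) * d)
  }
  verts <- rbind(center + radius * p,
                 do.call(rbind, lapply(th, ring)),
                 center - radius * p)
  nr <- length(th)
  idx <- function(r, a) 1L + (r - 1L) * n_az + ((a - 1L) %% n_az) + 1L
  faces <- list()
  a <- seq_len(n_az)
  # top fan
  faces[[1]] <- cbind(1L, idx(1L, a), idx(1L, a + 1L))
  # bands
  if (nr > 1L) {
    for (r in seq_len(nr - 1L)) {
      faces[[length(faces) + 1L]] <- cbind(idx(r, a), idx(r + 1L, a),
                                           idx(r + 1L, a + 1L))
      faces[[length(faces) + 1L]] <- cbind(idx(r, a), idx(r + 1L, a + 1L),
                                           idx(r, a + 1L))
    }
  }
  bot <- nrow(verts)
  faces[[length(faces) + 1L]] <- cbind(bot, idx(nr, a + 1L), idx(nr, a))
  triangle_mesh(verts, do.call(rbind, faces), drop_degenerate = FALSE)
}

#' Closed solid cylinder mesh
#'
#' @param base_center 3-vector, centre of the base cap (mm).
#' @param axis_dir direction from base to top (normalized internally).
#' @param length mm.
#' @param radius mm.
#' @param n_facets azimuthal facets.
#' @param n_len segments along the axis.
#' @return a `triangle_mesh` (watertight).
#' @export
cylinder_mesh <- function(base_center, axis_dir, length, radius,
                          n_facets = 64L, n_len = 2L) {
  d <- unit3(axis_dir)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * d)) > 0.99) ref <- c(0, 1, 0)
  u <- unit3(ref - sum(ref * d) * d)
  v <- cross3(d, u)
  phi <- 2 * pi * (seq_len(n_facets) - 1L) / n_facets
  circ <- outer(cos(phi), u) + outer(sin(phi), v)
  zs <- seq(0, length, length.out = n_len + 1L)
  verts <- do.call(rbind, lapply(zs, function(z)
    matrix(base_center + z * d, n_facets, 3, byrow = TRUE) + radius * circ))
  nrings <- n_len + 1L
  idx <- function(r, a) (r - 1L) * n_facets + ((a - 1L) %% n_facets) + 1L
  a <- seq_len(n_facets)
  faces <- list()
  for (r in seq_len(nrings - 1L)) {
    faces[[length(faces) + 1L]] <- cbind(idx(r, a), idx(r, a + 1L),
                                         idx(r + 1L, a + 1L))
    faces[[length(faces) + 1L]] <- cbind(idx(r, a), idx(r + 1L, a + 1L),
                                         idx(r + 1L, a))
  }
  cb <- nrow(verts) + 1L   # base centre
  ct <- nrow(verts) + 2L   # top centre
  verts <- rbind(verts, base_center, base_center + length * d)
  faces[[length(faces) + 1L]] <- cbind(cb, idx(1L, a + 1L), idx(1L, a))
  faces[[length(faces) + 1L]] <- cbind(ct, idx(nrings, a), idx(nrings, a + 1L))
  triangle_mesh(verts, do.call(rbind, faces), drop_degenerate = FALSE)
}

#' Hollow tube mesh (outer wall, inner canal wall, annulus end caps)
#' @param base_center base-cap centre (mm).
#' @param axis_dir base-to-top direction.
#' @param length mm.
#' @param outer_radius,inner_radius wall radii (mm), `inner < outer`.
#' @param n_facets azimuthal facets.
#' @param n_len axial segments.
#' @return a `triangle_mesh`.
#' @export
tube_mesh <- function(base_center, axis_dir, length, outer_radius,
                      inner_radius, n_facets = 48L, n_len = 12L) {
  if (inner_radius >= outer_radius)
    stop("inner_radius must be smaller than outer_radius")
  d <- unit3(axis_dir)
  ref <- c(1, 0, 0)
  if (abs(sum(ref * d)) > 0.99) ref <- c(0, 1, 0)
  u <- unit3(ref - sum(ref * d) * d)
  v <- cross3(d, u)
  phi <- 2 * pi * (seq_len(n_facets) - 1L) / n_facets
  circ <- outer(cos(phi), u) + outer(sin(phi), v)
  zs <- seq(0, length, length.out = n_len + 1L)
  wall <- function(r) do.call(rbind, lapply(zs, function(z)
    matrix(base_center + z * d, n_facets, 3, byrow = TRUE) + r * circ))
  verts <- rbind(wall(outer_radius), wall(inner_radius))
  nrings <- n_len + 1L
  off_in <- nrings * n_facets
  ixo <- function(r, a) (r - 1L) * n_facets + ((a - 1L) %% n_facets) + 1L
  ixi <- function(r, a) off_in + ixo(r, a)
  a <- seq_len(n_facets)
  faces <- list()
  for (r in seq_len(nrings - 1L)) {
    faces[[length(faces) + 1L]] <- cbind(ixo(r, a), ixo(r, a + 1L),
                                         ixo(r + 1L, a + 1L))
    faces[[length(faces) + 1L]] <- cbind(ixo(r, a), ixo(r + 1L, a + 1L),
                                         ixo(r + 1L, a))
    faces[[length(faces) + 1L]] <- cbind(ixi(r, a), ixi(r + 1L, a + 1L),
                                         ixi(r, a + 1L))
    faces[[length(faces) + 1L]] <- cbind(ixi(r, a), ixi(r + 1L, a),
                                         ixi(r + 1L, a + 1L))
  }
  # annulus caps
  faces[[length(faces) + 1L]] <- cbind(ixo(1L, a + 1L), ixo(1L, a), ixi(1L, a))
  faces[[length(faces) + 1L]] <- cbind(ixo(1L, a + 1L), ixi(1L, a),
                                       ixi(1L, a + 1L))
  faces[[length(faces) + 1L]] <- cbind(ixo(nrings, a), ixo(nrings, a + 1L),
                                       ixi(nrings, a + 1L))
  faces[[length(faces) + 1L]] <- cbind(ixo(nrings, a), ixi(nrings, a + 1L),
                                       ixi(nrings, a))
  triangle_mesh(verts, do.call(rbind, faces), drop_degenerate = FALSE)
}

#' Axis-aligned box mesh with optional face subdivision
#' @param xlim,ylim,zlim length-2 ranges (mm).
#' @param res target facet edge length (mm); faces are subdivided to it.
#' @return a `triangle_mesh` (watertight).
#' @export
box_mesh <- function(xlim, ylim, zlim, res = Inf) {
  nseg <- function(lim) max(1L, ceiling(diff(lim) / res))
  nx <- nseg(xlim); ny <- nseg(ylim); nz <- nseg(zlim)
  xs <- seq(xlim[1], xlim[2], length.out = nx + 1L)
  ys <- seq(ylim[1], ylim[2], length.out = ny + 1L)
  zs <- seq(zlim[1], zlim[2], length.out = nz + 1L)
  verts <- list(); faces <- list(); nv <- 0L
  grid_face <- function(A, B, const, plane, flip) {
    # plane: which coordinate is constant ("x","y","z")
    g <- expand.grid(a = A, b = B)
    P <- switch(plane,
                x = cbind(const, g$a, g$b),
                y = cbind(g$a, const, g$b),
                z = cbind(g$a, g$b, const))
    na <- length(A); nb <- length(B)
    id <- function(i, j) nv + (j - 1L) * na + i
    fs <- list()
    for (j in seq_len(nb - 1L)) {
      i <- seq_len(na - 1L)
      f1 <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
      f2 <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
      fs[[length(fs) + 1L]] <- rbind(f1, f2)
    }
    F <- do.call(rbind, fs)
    if (flip) F <- F[, c(1L, 3L, 2L)]
    verts[[length(verts) + 1L]] <<- P
    faces[[length(faces) + 1L]] <<- F
    nv <<- nv + nrow(P)
  }
  grid_face(ys, zs, xlim[1], "x", flip = FALSE)
  grid_face(ys, zs, xlim[2], "x", flip = TRUE)
  grid_face(xs, zs, ylim[1], "y", flip = TRUE)
  grid_face(xs, zs, ylim[2], "y", flip = FALSE)
  grid_face(xs, ys, zlim[1], "z", flip = FALSE)
  grid_face(xs, ys, zlim[2], "z", flip = TRUE)
  V <- do.call(rbind, verts)
  F <- do.call(rbind, faces)
  # weld the duplicated vertices along box edges so the mesh is watertight
  key <- paste(V[, 1], V[, 2], V[, 3])
  first <- match(key, key)
  remap <- match(first, sort(unique(first)))
  triangle_mesh(V[sort(unique(first)), , drop = FALSE],
                matrix(remap[F], ncol = 3L),
                drop_degenerate = FALSE)
}

#' Extract the submesh spanned by a vertex index set
#'
#' Keeps faces whose three vertices all belong to `vertex_idx`, re-indexing
#' vertices. The attribute `face_map` maps new face row numbers back to rows
#' of the parent mesh.
#'
#' @param mesh a `triangle_mesh`.
#' @param vertex_idx integer vertex indices in `mesh`.
#' @return a `triangle_mesh` with attributes `face_map` and `vertex_map`.
#' @export
submesh <- function(mesh, vertex_idx) {
  keepv <- logical(nrow(mesh$vertices))
  keepv[vertex_idx] <- TRUE
  fkeep <- keepv[mesh$faces[, 1]] & keepv[mesh$faces[, 2]] &
    keepv[mesh$faces[, 3]]
  vmap <- integer(nrow(mesh$vertices))
  used <- sort(unique(as.vector(mesh$faces[fkeep, , drop = FALSE])))
  vmap[used] <- seq_along(used)
  out <- triangle_mesh(mesh$vertices[used, , drop = FALSE],
                       matrix(vmap[mesh$faces[fkeep, ]], ncol = 3L),
                       frame = mesh$frame, drop_degenerate = FALSE)
  attr(out, "face_map") <- which(fkeep)
  attr(out, "vertex_map") <- used
  out
}
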
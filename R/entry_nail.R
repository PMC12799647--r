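# Medullary-axis estimation, optimal entry point with the 5-mm
# supraspinatus rule, virtual nail placement and approach-specific posing.

#' Bundle humerus and scapula meshes with labelled anatomy
#'
#' @param humerus,scapula `triangle_mesh` objects in a common patient frame.
#' @param landmarks named list of vertex index sets: `head_region`,
#'   `shaft_region`, `supraspinatus_footprint` (on the humerus) and
#'   `glenoid_face`, `acromion` (on the scapula).
#' @param side "left" or "right".
#' @return object of class `shoulder_model`.
#' @export
shoulder_model <- function(humerus, scapula, landmarks, side = "right") {
  need <- c("head_region", "shaft_region", "supraspinatus_footprint",
            "glenoid_face", "acromion")
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) stop("missing landmark sets: ", paste(miss, collapse = ", "))
  for (nm in need) {
    idx <- landmarks[[nm]]
    if (length(idx) == 0L) stop("landmark set is empty: ", nm)
    nmax <- if (nm %in% c("glenoid_face", "acromion"))
      nrow(scapula$vertices) else nrow(humerus$vertices)
    if (min(idx) < 1L || max(idx) > nmax)
      stop("landmark indices out of range for ", nm)
  }
  if (length(intersect(landmarks$head_region, landmarks$shaft_region)))
    stop("head_region and shaft_region must be disjoint")
  if (!side %in% c("left", "right")) stop("side must be left or right")
  structure(list(humerus = humerus, scapula = scapula,
                 landmarks = lapply(landmarks, as.integer), side = side),
            class = "shoulder_model")
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat(sprintf("shoulder_model (%s): humerus %d faces, scapula %d faces\n",
              x$side, nrow(x$humerus$faces), nrow(x$scapula$faces)))
  invisible(x)
}

# intersection contours of a face subset with a plane; returns a list of
# closed loops (matrices of ordered 3D points). Crossing edges are coded as
# integers and chained face-to-face via shared edges.
mesh_plane_contours <- function(mesh, face_rows, point, normal) {
  V <- mesh$vertices
  F <- mesh$faces[face_rows, , drop = FALSE]
  sd <- drop(sweep(V, 2L, point) %*% normal)
  sd[sd == 0] <- 1e-12
  cr <- cbind(sd[F[, 1]] * sd[F[, 2]] < 0,
              sd[F[, 2]] * sd[F[, 3]] < 0,
              sd[F[, 3]] * sd[F[, 1]] < 0)
  keep <- rowSums(cr) == 2L   # generic crossing triangles
  F <- F[keep, , drop = FALSE]
  cr <- cr[keep, , drop = FALSE]
  nf <- nrow(F)
  if (nf == 0L) return(list())
  ia <- cbind(F[, 1], F[, 2], F[, 3])
  ib <- cbind(F[, 2], F[, 3], F[, 1])
  sel <- which(cr)                       # 2 entries per face
  fidx <- ((sel - 1L) %% nf) + 1L
  i <- ia[sel]; j <- ib[sel]
  code <- pmin(i, j) * (nrow(V) + 1) + pmax(i, j)
  ukey <- unique(code)
  kid <- match(code, ukey)
  tt <- sd[i] / (sd[i] - sd[j])
  P <- V[i, , drop = FALSE] + tt * (V[j, , drop = FALSE] - V[i, , drop = FALSE])
  K <- length(ukey)
  KP <- matrix(NA_real_, K, 3L)
  KP[kid, ] <- P                          # one representative point per edge
  # per-face edge pair and per-edge face pair
  o <- order(fidx)
  k_sorted <- kid[o]
  fk <- matrix(k_sorted, ncol = 2L, byrow = TRUE)   # face -> its 2 edge keys
  kf <- matrix(NA_integer_, K, 2L)
  for (r in seq_len(nf)) {
    for (k in fk[r, ]) {
      if (is.na(kf[k, 1L])) kf[k, 1L] <- r else kf[k, 2L] <- r
    }
  }
  visited <- logical(nf)
  loops <- list()
  for (start in seq_len(nf)) {
    if (visited[start]) next
    cur <- start; key <- fk[start, 1L]
    ord_keys <- integer(0)
    repeat {
      visited[cur] <- TRUE
      ord_keys <- c(ord_keys, key)
      key <- if (fk[cur, 1L] == key) fk[cur, 2L] else fk[cur, 1L]
      nxt <- if (!is.na(kf[key, 1L]) && kf[key, 1L] != cur) kf[key, 1L]
             else kf[key, 2L]
      if (is.na(nxt)) { ord_keys <- c(ord_keys, key); break }  # open chain
      if (visited[nxt]) break                                   # closed loop
      cur <- nxt
    }
    if (length(ord_keys) >= 3L)
      loops[[length(loops) + 1L]] <- KP[ord_keys, , drop = FALSE]
  }
  loops
}

# signed area and centroid of a closed planar polygon given in 3D
polygon_area_centroid <- function(P, normal) {
  n <- unit3(normal)
  ref <- c(1, 0, 0); if (abs(sum(ref * n)) > 0.99) ref <- c(0, 1, 0)
  u <- unit3(ref - sum(ref * n) * n); v <- cross3(n, u)
  o <- P[1, ]
  x <- drop(sweep(P, 2L, o) %*% u); y <- drop(sweep(P, 2L, o) %*% v)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(list(area = 0, centroid = colMeans(P)))
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  list(area = A, centroid = o + cx * u + cy * v)
}

#' Estimate the medullary canal axis from shaft cross-sections
#'
#' Slices the labelled shaft region with planes perpendicular to its
#' principal axis at equally spaced stations over the middle 60% of its
#' extent (avoiding the metaphyseal flare), takes the area centroid of the
#' inner (canal) contour of each cross-section — or of the full section if
#' the mesh is not hollow — and fits a total-least-squares line through the
#' centroids.
#'
#' @param shoulder a `shoulder_model`.
#' @param n_slices number of cross-sections (default 20).
#' @return a `line3` pointing proximally, with attribute `centroids`.
#' @export
estimate_medullary_axis <- function(shoulder, n_slices = 20L) {
  idx <- shoulder$landmarks$shaft_region
  V <- shoulder$humerus$vertices[idx, , drop = FALSE]
  sup <- shoulder$humerus$frame$superior
  principal <- fit_line(V, proximal = sup)
  t <- drop(sweep(V, 2L, principal$point) %*% principal$direction)
  span <- diff(range(t))
  if (span < 40)
    stop("shaft_region spans only ", round(span, 1),
         " mm along its axis; >= 40 mm required")
  stations <- seq(min(t) + 0.2 * span, max(t) - 0.2 * span,
                  length.out = n_slices)
  inshaft <- logical(nrow(shoulder$humerus$vertices))
  inshaft[idx] <- TRUE
  frows <- which(inshaft[shoulder$humerus$faces[, 1]] &
                   inshaft[shoulder$humerus$faces[, 2]] &
                   inshaft[shoulder$humerus$faces[, 3]])
  centroids <- matrix(NA_real_, n_slices, 3L)
  for (s in seq_len(n_slices)) {
    pt <- principal$point + stations[s] * principal$direction
    loops <- mesh_plane_contours(shoulder$humerus, frows, pt,
                                 principal$direction)
    if (length(loops) == 0L)
      stop("empty shaft cross-section at slice ", s, " of ", n_slices)
    ac <- lapply(loops, polygon_area_centroid, normal = principal$direction)
    areas <- abs(vapply(ac, `[[`, numeric(1), "area"))
    pick <- if (length(loops) > 1L) which.min(areas) else 1L
    centroids[s, ] <- ac[[pick]]$centroid
  }
  out <- fit_line(centroids, proximal = sup)
  attr(out, "centroids") <- centroids
  out
}

#' Optimal nail entry point on the humeral head
#'
#' Intersects the (proximally extended) medullary axis with the humerus
#' surface restricted to the articular head region; the most proximal
#' intersection is the entry point. The distance to the supraspinatus
#' footprint is reported together with the >= 5 mm safety rule; a violation
#' is reported (with a warning), never silently relocated.
#'
#' @param shoulder a `shoulder_model`.
#' @param axis a `line3` canal axis (direction pointing proximally).
#' @return object of class `entry_report`: `entry_point`,
#'   `distance_to_footprint`, `satisfies_5mm_rule`.
#' @export
compute_entry_point <- function(shoulder, axis) {
  headm <- submesh(shoulder$humerus, shoulder$landmarks$head_region)
  hits <- ray_mesh_cpp(headm$vertices, headm$faces,
                       axis$point, axis$direction)
  if (length(hits$t) == 0L)
    stop("trajectory miss: the medullary axis does not intersect the ",
         "articular head region")
  tmax <- max(hits$t)
  entry <- axis$point + tmax * axis$direction
  fp <- shoulder$humerus$vertices[shoulder$landmarks$supraspinatus_footprint,
                                  , drop = FALSE]
  d <- min(sqrt(rowSums(sweep(fp, 2L, entry)^2)))
  ok <- d >= 5.0
  if (!ok)
    warning(sprintf(paste0("entry point is %.1f mm from the supraspinatus ",
                           "footprint (< 5 mm safety margin)"), d))
  structure(list(entry_point = entry, distance_to_footprint = d,
                 satisfies_5mm_rule = ok),
            class = "entry_report")
}

#' @export
print.entry_report <- function(x, ...) {
  cat(sprintf("entry point (%.2f, %.2f, %.2f) mm; %.1f mm to footprint (%s)\n",
              x$entry_point[1], x$entry_point[2], x$entry_point[3],
              x$distance_to_footprint,
              if (x$satisfies_5mm_rule) ">= 5 mm rule satisfied"
              else "5 mm rule VIOLATED"))
  invisible(x)
}

#' Place the virtual straight nail on the canal axis
#'
#' A closed cylinder of the given diameter and length, collinear with the
#' axis, with its proximal cap centre at the entry point, extending
#' distally.
#'
#' @param axis a `line3` (direction proximal).
#' @param entry an `entry_report` (or bare 3-vector entry point); must lie
#'   on the axis within `tol`.
#' @param diameter_mm nail diameter (default 8, the smallest clinically
#'   available size).
#' @param length_mm nail length (default 150).
#' @param n_facets cylinder tessellation (default 64).
#' @param tol off-axis tolerance for the entry point (mm).
#' @return object of class `nail_model` with fields `diameter`, `length`,
#'   `axis`, `entry_point`, `mesh`.
#' @export
place_nail <- function(axis, entry, diameter_mm = 8, length_mm = 150,
                       n_facets = 64L, tol = 1e-6) {
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  if (length_mm <= 0) stop("length_mm must be positive")
  ep <- if (inherits(entry, "entry_report")) entry$entry_point
        else as.numeric(entry)
  rel <- ep - axis$point
  off <- sqrt(sum((rel - sum(rel * axis$direction) * axis$direction)^2))
  if (off > tol)
    stop(sprintf("entry point is %.2g mm off the nail axis (tol %.2g)",
                 off, tol))
  mesh <- cylinder_mesh(ep - length_mm * axis$direction, axis$direction,
                        length_mm, diameter_mm / 2, n_facets = n_facets)
  structure(list(diameter = diameter_mm, length = length_mm,
                 axis = line3(ep, axis$direction), entry_point = ep,
                 mesh = mesh),
            class = "nail_model")
}

#' Approach-specific arm position
#'
#' The two study conditions are the transdeltoid approach in neutral
#' (0 degrees of glenohumeral extension) and the anterolateral approach in
#' 30 degrees of extension. Other angles are allowed for exploration and
#' flagged as non-study conditions.
#'
#' @param extension_deg glenohumeral extension angle.
#' @param rotation_axis a `line3`: the mediolateral axis through the fitted
#'   head-sphere centre, directed medially so that positive extension moves
#'   the proximal trajectory anteriorly.
#' @return object of class `arm_pose` with `name`, `extension_deg`,
#'   `rotation_axis`, `study_condition`.
#' @export
arm_pose <- function(extension_deg, rotation_axis) {
  study <- extension_deg %in% c(0, 30)
  name <- if (extension_deg == 0) "transdeltoid_0"
          else if (extension_deg == 30) "anterolateral_30"
          else sprintf("custom_%gdeg", extension_deg)
  structure(list(name = name, extension_deg = extension_deg,
                 rotation_axis = rotation_axis, study_condition = study),
            class = "arm_pose")
}

#' The two study arm poses for a shoulder
#'
#' Fits a sphere to the articular head surface to locate the centre of
#' rotation and builds the mediolateral rotation axis through it.
#'
#' @param shoulder a `shoulder_model`.
#' @return list with elements `transdeltoid_0` and `anterolateral_30`
#'   (each an [arm_pose()]), plus `head_sphere`.
#' @export
study_poses <- function(shoulder) {
  hs <- fit_sphere(shoulder$humerus$vertices[shoulder$landmarks$head_region,
                                             , drop = FALSE])
  ax <- line3(hs$center, -shoulder$humerus$frame$lateral)
  list(transdeltoid_0 = arm_pose(0, ax),
       anterolateral_30 = arm_pose(30, ax),
       head_sphere = hs)
}

#' Pose humerus and nail for an arm position
#'
#' Rotates the humerus mesh and the nail rigidly by the extension angle
#' about the pose's mediolateral axis; the scapula stays static, and the
#' relative humerus-nail geometry is preserved exactly.
#'
#' @param shoulder a `shoulder_model`.
#' @param nail a `nail_model`.
#' @param pose an `arm_pose`.
#' @return list with `humerus` (posed `triangle_mesh`) and `nail`
#'   (posed `nail_model`).
#' @export
apply_pose <- function(shoulder, nail, pose) {
  a <- pose$rotation_axis
  ang <- pose$extension_deg
  hum <- rotate_rigid(shoulder$humerus, a, ang)
  nm <- nail
  nm$mesh <- rotate_rigid(nail$mesh, a, ang)
  ep <- rotate_points(nail$entry_point, a, ang)
  dirp <- rotate_points(nail$entry_point + nail$axis$direction, a, ang) - ep
  nm$axis <- line3(ep, dirp)
  nm$entry_point <- ep
  list(humerus = hum, nail = nm)
}
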
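# Nail-acromion contact: exact triangle-mesh collision with signed
# clearance, and the per-condition pipeline stage that composes axis
# estimation, entry-point construction, nail placement and posing.

#' Detect contact between two triangle meshes
#'
#' Collision is declared when any triangle pair intersects, when one closed
#' mesh contains the other, or when the minimal surface-surface distance is
#' at or below `tolerance_mm`. The signed clearance is the minimal
#' separation (positive) or the maximal penetration depth of contained
#' vertices (negative).
#'
#' @param mesh_a,mesh_b `triangle_mesh` objects (e.g. nail and acromion
#'   patch).
#' @param tolerance_mm contact tolerance; 0 (default) means touching counts
#'   as collision.
#' @param condition optional condition label carried into the result.
#' @param closed treat the meshes as closed for the containment /
#'   penetration-depth tests (default TRUE).
#' @return object of class `collision_result`: `collides`,
#'   `contact_faces_a`, `contact_faces_b` (face row indices),
#'   `clearance_mm`, `condition`.
#' @export
detect_collision <- function(mesh_a, mesh_b, tolerance_mm = 0,
                             condition = NA_character_, closed = TRUE) {
  if (nrow(mesh_a$faces) == 0L || nrow(mesh_b$faces) == 0L)
    stop("configuration error: empty mesh passed to detect_collision")
  res <- mesh_contact_cpp(mesh_a$vertices, mesh_a$faces,
                          mesh_b$vertices, mesh_b$faces,
                          tolerance_mm, closed)
  structure(list(collides = res$collides,
                 contact_faces_a = sort(unique(res$faces_a)),
                 contact_faces_b = sort(unique(res$faces_b)),
                 clearance_mm = res$clearance,
                 tolerance_mm = tolerance_mm,
                 condition = condition),
            class = "collision_result")
}

#' @export
print.collision_result <- function(x, ...) {
  cat(sprintf("collision_result [%s]: %s, clearance %.2f mm (%d/%d contact faces)\n",
              if (is.na(x$condition)) "-" else x$condition,
              if (x$collides) "COLLISION" else "clear",
              x$clearance_mm,
              length(x$contact_faces_a), length(x$contact_faces_b)))
  invisible(x)
}

#' Simulate one approach condition for one shoulder
#'
#' Composes the full per-shoulder stage chain: medullary-axis estimation,
#' entry-point construction, nail placement, posing, and nail-acromion
#' collision detection. The collision object is the insertion corridor:
#' the volume swept by the straight nail advanced along its own axis from
#' first contact to seating, i.e. the nail cylinder extended one nail-length
#' proximal of the entry point (a seated nail lies beneath the acromion;
#' contact happens on the way in).
#'
#' @param shoulder a `shoulder_model`.
#' @param pose an [arm_pose()]; if missing, the requested `extension_deg` is
#'   built from the fitted head sphere.
#' @param extension_deg used when `pose` is missing (default 0).
#' @param nail_diameter_mm,nail_length_mm,n_facets nail geometry.
#' @param tolerance_mm collision tolerance (default 0).
#' @param n_slices slices for axis estimation (default 20).
#' @return a `collision_result` with attributes `entry_report`, `axis`,
#'   `nail` (posed) and `pose`.
#' @export
run_condition <- function(shoulder, pose = NULL, extension_deg = 0,
                          nail_diameter_mm = 8, nail_length_mm = 150,
                          n_facets = 64L, tolerance_mm = 0, n_slices = 20L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  axis <- stage("estimate_medullary_axis",
                estimate_medullary_axis(shoulder, n_slices = n_slices))
  entry <- stage("compute_entry_point", compute_entry_point(shoulder, axis))
  nail <- stage("place_nail",
                place_nail(axis, entry, diameter_mm = nail_diameter_mm,
                           length_mm = nail_length_mm, n_facets = n_facets))
  if (is.null(pose)) {
    ps <- stage("study_poses", study_poses(shoulder))
    pose <- if (extension_deg == 0) ps$transdeltoid_0
            else if (extension_deg == 30) ps$anterolateral_30
            else arm_pose(extension_deg, ps$transdeltoid_0$rotation_axis)
  }
  posed <- stage("apply_pose", apply_pose(shoulder, nail, pose))
  corridor <- stage("insertion_corridor", {
    d <- posed$nail$axis$direction
    cylinder_mesh(posed$nail$entry_point - nail_length_mm * d, d,
                  2 * nail_length_mm, nail_diameter_mm / 2,
                  n_facets = n_facets)
  })
  acromion <- stage("acromion_patch",
                    submesh(shoulder$scapula, shoulder$landmarks$acromion))
  if (nrow(acromion$faces) == 0L)
    stop("[acromion_patch] configuration error: acromion patch has no faces")
  res <- stage("detect_collision",
               detect_collision(corridor, acromion,
                                tolerance_mm = tolerance_mm,
                                condition = pose$name))
  attr(res, "entry_report") <- entry
  attr(res, "axis") <- axis
  attr(res, "nail") <- posed$nail
  attr(res, "pose") <- pose
  attr(res, "acromion_face_map") <- attr(acromion, "face_map")
  res
}

#' Export contact surfaces as a coloured ASCII PLY
#'
#' Writes both meshes into one PLY, contact faces coloured red, for visual
#' inspection of the collision output.
#'
#' @param result a `collision_result`.
#' @param mesh_a,mesh_b the meshes the result was computed from.
#' @param path output .ply path.
#' @return `path`, invisibly.
#' @export
export_contact_ply <- function(result, mesh_a, mesh_b, path) {
  m <- merge_meshes(mesh_a, mesh_b)
  red <- c(result$contact_faces_a,
           result$contact_faces_b + nrow(mesh_a$faces))
  col <- matrix(180L, nrow(m$faces), 3L)
  col[red, ] <- matrix(c(255L, 0L, 0L), length(red), 3L, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  v <- m$vertices; fc <- m$faces
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(fc)),
               "property list uchar int vertex_indices",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d %d %d %d",
                     fc[, 1] - 1L, fc[, 2] - 1L, fc[, 3] - 1L,
                     col[, 1], col[, 2], col[, 3]), con)
  invisible(path)
}
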
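#' Triangle surface mesh with an anatomical frame
#'
#' The basic geometric container of the package: an indexed triangle mesh in
#' millimetres, carrying a named anatomical frame (unit vectors pointing
#' lateral, anterior and superior). All downstream stages (axis estimation,
#' nail placement, collision, morphometry) consume and produce this type.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param frame named list with unit 3-vectors `lateral`, `anterior`,
#'   `superior` forming a right-handed orthonormal triad. Defaults to the
#'   package convention +x lateral, +y anterior, +z superior.
#' @param drop_degenerate drop zero-area faces on construction (default TRUE).
#'
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `frame`.
#' @export
triangle_mesh <- function(vertices, faces,
                          frame = default_frame(),
                          drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be an m x 3 index matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  check_frame(frame)
  m <- structure(list(vertices = vertices, faces = faces, frame = frame),
                 class = "triangle_mesh")
  if (drop_degenerate && nrow(faces) > 0L) {
    a <- face_areas(m)
    keep <- a > 1e-12
    if (!all(keep)) m$faces <- m$faces[keep, , drop = FALSE]
  }
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Default anatomical frame (+x lateral, +y anterior, +z superior)
#' @return named list of three unit vectors.
#' @export
default_frame <- function() {
  list(lateral = c(1, 0, 0), anterior = c(0, 1, 0), superior = c(0, 0, 1))
}

check_frame <- function(frame) {
  need <- c("lateral", "anterior", "superior")
  if (!is.list(frame) || !all(need %in% names(frame)))
    stop("frame must name lateral, anterior and superior unit vectors")
  M <- rbind(frame$lateral, frame$anterior, frame$superior)
  if (any(abs(M %*% t(M) - diag(3)) > 1e-6))
    stop("frame vectors must be orthonormal")
  if (det(M) < 0) stop("frame must be right-handed")
  invisible(TRUE)
}

#' Signed areas and centroids of mesh faces
#' @param mesh a `triangle_mesh`.
#' @return numeric vector of triangle areas (mm^2).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

#' Merge two meshes into one (concatenating vertex and face lists)
#' @param a,b `triangle_mesh` objects sharing the same frame.
#' @return a `triangle_mesh`.
#' @export
merge_meshes <- function(a, b) {
  off <- nrow(a$vertices)
  triangle_mesh(rbind(a$vertices, b$vertices),
                rbind(a$faces, b$faces + off),
                frame = a$frame, drop_degenerate = FALSE)
}

#' Apply an affine map to mesh vertices
#' @param mesh a `triangle_mesh`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return transformed `triangle_mesh` (frame metadata unchanged: the frame
#'   labels the patient axes, which do not move with a bone).
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$vertices <- mesh$vertices %*% t(R) +
    matrix(t, nrow(mesh$vertices), 3, byrow = TRUE)
  mesh
}

# ---- STL / PLY readers and writers --------------------------------------
# No installed R package reads surface STL/PLY, so the (simple) formats are
# parsed here directly. Binary STL: 80-byte header, uint32 count, 50-byte
# records. Vertices are de-duplicated on read (exact match).

#' Read a surface mesh from STL (ASCII or binary) or PLY (ASCII)
#'
#' Frame metadata is read from a JSON sidecar `<file>.frame.json` with keys
#' `lateral`, `anterior`, `superior` when present, else the default frame is
#' assumed.
#'
#' @param path file path ending in .stl or .ply (case-insensitive).
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              stl = read_stl(path),
              ply = read_ply_ascii(path),
              stop("unsupported mesh format: ", ext))
  sidecar <- paste0(path, ".frame.json")
  if (file.exists(sidecar)) {
    fr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    m$frame <- lapply(fr[c("lateral", "anterior", "superior")], as.numeric)
    check_frame(m$frame)
  }
  m
}

#' Write a surface mesh to STL (ASCII or binary) or PLY (ASCII)
#'
#' Also writes the anatomical frame to `<file>.frame.json`.
#'
#' @param mesh a `triangle_mesh`.
#' @param path destination (.stl or .ply).
#' @param binary write binary STL (ignored for PLY). Default TRUE.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (binary) write_stl_binary(mesh, path)
               else write_stl_ascii(mesh, path),
         ply = write_ply_ascii(mesh, path),
         stop("unsupported mesh format: ", ext))
  jsonlite::write_json(mesh$frame, paste0(path, ".frame.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 5L)
  close(con)
  if (identical(rawToChar(head), "solid")) {
    # could still be binary with a "solid" header; check triangle count
    sz <- file.size(path)
    con <- file(path, "rb")
    readBin(con, "raw", 80L)
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    close(con)
    if (!is.na(n) && sz == 84 + 50 * n) return(read_stl_binary(path))
    read_stl_ascii(path)
  } else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nums <- lapply(strsplit(trimws(vl), "\\s+"),
                 function(s) as.numeric(s[2:4]))
  tri <- do.call(rbind, nums)
  soup_to_mesh(tri)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", 50L * n)
  m <- matrix(rec, nrow = 50L)
  fl <- readBin(as.raw(m[1:48, ]), "numeric", size = 4L, n = 12L * n,
                endian = "little")
  fl <- matrix(fl, ncol = 12L, byrow = TRUE)   # normal + 3 vertices
  tri <- matrix(t(fl[, 4:12, drop = FALSE]), ncol = 3L, byrow = TRUE)
  soup_to_mesh(tri)
}

soup_to_mesh <- function(tri) {
  key <- apply(tri, 1L, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid nailsim", con)
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         p[, 1], p[, 2], p[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid nailsim", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeBin(as.numeric(c(n, t(p))), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("not a PLY file (no end_header)")
  hdr <- lines[seq_len(endh)]
  if (!grepl("^format ascii", trimws(hdr[2]))) stop("only ASCII PLY supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(endh + 1L):length(lines)]
  vt <- do.call(rbind, lapply(strsplit(trimws(body[1:nv]), "\\s+"),
                              function(s) as.numeric(s[1:3])))
  ft <- do.call(rbind, lapply(strsplit(trimws(body[nv + (1:nf)]), "\\s+"),
                              function(s) as.integer(s[2:4]) + 1L))
  triangle_mesh(vt, ft)
}

write_ply_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}
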
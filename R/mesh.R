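#' Triangle mesh of an articular facet patch
#'
#' A `facet_mesh` stores vertex coordinates (millimetres) and triangular
#' faces of one articular surface patch, the unit every downstream
#' measurement operates on.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates in mm.
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param name Label for the facet (used in reports).
#' @param clean If `TRUE` (default), degenerate faces and unreferenced
#'   vertices are removed before validation.
#'
#' @return An object of class `facet_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @export
facet_mesh <- function(vertices, faces, name = "facet", clean = TRUE) {
  vertices <- as_points_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3) fm_abort("'faces' must be an m x 3 index matrix", "fm_validation_error")
  storage.mode(faces) <- "integer"
  mesh <- structure(
    list(vertices = vertices, faces = faces, name = as.character(name)[1]),
    class = "facet_mesh"
  )
  if (clean) mesh <- clean_mesh(mesh)
  validate_mesh(mesh)
  mesh
}

is_facet_mesh <- function(x) inherits(x, "facet_mesh")

validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (any(!is.finite(v))) fm_abort("mesh has non-finite vertex coordinates", "fm_validation_error")
  if (nrow(f) < 1 || nrow(v) < 4) {
    fm_abort(
      sprintf(
        "mesh '%s' is degenerate after cleaning (%d vertices, %d faces); at least 4 vertices are needed to support a fit",
        mesh$name, nrow(v), nrow(f)
      ),
      "fm_degenerate_input"
    )
  }
  if (min(f) < 1 || max(f) > nrow(v)) fm_abort("face indices out of range", "fm_validation_error")
  invisible(mesh)
}

#' Clean a mesh: weld duplicate vertices, drop degenerate faces
#'
#' Welds vertices that coincide within `weld_tol` (needed to sew STL
#' triangle soup into a connected surface), removes faces with repeated
#' indices or area below `area_tol`, and drops unreferenced vertices.
#' Cleaning is idempotent.
#'
#' @param mesh A `facet_mesh` (or a bare list with `vertices`/`faces`).
#' @param weld_tol Vertex weld tolerance in mm (default 1e-9).
#' @param area_tol Minimum face area in mm^2 (default 1e-12).
#' @return The cleaned `facet_mesh`.
#' @export
clean_mesh <- function(mesh, weld_tol = 1e-9, area_tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  # weld: quantise coordinates and map duplicates to one representative
  key <- paste(round(v[, 1] / weld_tol), round(v[, 2] / weld_tol), round(v[, 3] / weld_tol))
  first <- match(key, key)
  keep_v <- which(first == seq_along(first))
  remap <- match(first, keep_v)
  v <- v[keep_v, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3)
  # drop faces with repeated vertices or negligible area
  distinct <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[distinct, , drop = FALSE]
  if (nrow(f) > 0) {
    a <- face_areas_vf(v, f)
    f <- f[a >= area_tol, , drop = FALSE]
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  v <- v[used, , drop = FALSE]
  f <- matrix(match(f, used), ncol = 3)
  structure(list(vertices = v, faces = f, name = mesh$name), class = "facet_mesh")
}

face_areas_vf <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3_rows(e1, e2)
  0.5 * sqrt(rowSums(cr^2))
}

face_areas <- function(mesh) face_areas_vf(mesh$vertices, mesh$faces)

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cross3_rows(e1, e2)
  n <- sqrt(rowSums(cr^2))
  cr / pmax(n, 1e-300)
}

face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
}

# Area-weighted vertex normals.
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  idx <- as.vector(mesh$faces)
  acc <- rowsum(rbind(fn, fn, fn), idx)
  out <- matrix(0, nrow(mesh$vertices), 3)
  out[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(out^2))
  out / pmax(len, 1e-300)
}

mean_vertex_normal <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  normalize(colSums(fn))
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas (half cross-product norms), in mm^2.
#'
#' @param mesh A `facet_mesh`.
#' @return Surface area in mm^2.
#' @export
surface_area <- function(mesh) {
  sum(face_areas(mesh))
}

# Area-weighted centroid of the surface.
area_centroid <- function(mesh) {
  a <- face_areas(mesh)
  fc <- face_centroids(mesh)
  colSums(fc * a) / sum(a)
}

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh A `facet_mesh`.
#' @param rotation 3 x 3 matrix applied to vertex coordinates.
#' @param translation 3-vector added after rotation.
#' @return The transformed `facet_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, as_point3(translation, "translation"), "+")
  structure(list(vertices = v, faces = mesh$faces, name = mesh$name), class = "facet_mesh")
}

# Reverse face winding (flips normals); geometry unchanged.
flip_mesh <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1, 3, 2), drop = FALSE]
  mesh
}

#' @export
print.facet_mesh <- function(x, ...) {
  cat(sprintf(
    "<facet_mesh '%s': %d vertices, %d faces, area %.2f mm^2>\n",
    x$name, nrow(x$vertices), nrow(x$faces), surface_area(x)
  ))
  invisible(x)
}
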
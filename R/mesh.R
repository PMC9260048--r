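#' Construct a triangulated cortical surface mesh
#'
#' A surface mesh is the geometric substrate for E-field thresholding and
#' area measurement: vertex coordinates in millimetres plus triangular faces.
#' Faces index vertices 1-based internally; file readers/writers convert
#' explicitly to the 0-based convention used on disk (GIFTI, TSV).
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param hemisphere Hemisphere label; only the stimulated ("L") hemisphere is
#'   modeled.
#' @return An object of class `efnet_mesh` with elements `vertices`, `faces`,
#'   `hemisphere`.
#' @export
surface_mesh <- function(vertices, faces, hemisphere = "L") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  n <- nrow(vertices)
  if (n < 4L) stop("a surface mesh needs at least 4 vertices")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(faces < 1L) || any(faces > n)) {
    stop("face indices must lie in [1, n_vertices]")
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3])) {
    stop("a face may not repeat a vertex")
  }
  if (!all(seq_len(n) %in% faces)) {
    stop("every vertex must be referenced by at least one face")
  }
  structure(list(vertices = vertices, faces = faces, hemisphere = hemisphere),
            class = "efnet_mesh")
}

#' @export
print.efnet_mesh <- function(x, ...) {
  cat(sprintf("<efnet_mesh> %d vertices, %d faces, hemisphere %s\n",
              n_vertices(x), nrow(x$faces), x$hemisphere))
  cat(sprintf("  total area %.2f mm^2\n", sum(face_areas(x))))
  invisible(x)
}

#' Number of vertices in a mesh
#' @param mesh An `efnet_mesh`.
#' @return Integer vertex count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-face triangle areas
#'
#' Areas are computed directly from the faces (triangles) of the surface mesh
#' as half the cross-product norm of two edge vectors. Degenerate (collinear)
#' faces contribute zero area and raise a warning rather than an error, since
#' real surface extracts can contain sliver triangles.
#'
#' @param mesh An `efnet_mesh`.
#' @return Numeric vector of face areas, mm^2, one per face.
#' @export
#' @examples
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'                   rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
#' face_areas(m)
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  areas <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(areas == 0)) {
    warning(sum(areas == 0), " degenerate (zero-area) face(s) in mesh")
  }
  areas
}

#' Validate a per-vertex scalar map against its mesh
#'
#' Scalar maps hold one value per mesh vertex, e.g. the induced E-field
#' magnitude |E| in V/m. Values must be finite and non-negative.
#'
#' @param values Numeric vector, one value per vertex.
#' @param mesh The `efnet_mesh` the map indexes.
#' @return `values`, invisibly, after validation.
#' @export
check_scalar_map <- function(values, mesh) {
  if (length(values) != n_vertices(mesh)) {
    stop("scalar map length (", length(values),
         ") does not match mesh vertex count (", n_vertices(mesh), ")")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("scalar map values must be finite and >= 0")
  }
  invisible(values)
}
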
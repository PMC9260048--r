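#' Build the template icosphere mesh
#'
#' Desk-scale stand-in for a ~32k-vertex cortical hemisphere surface: a unit
#' icosahedron subdivided `subdivision` times with vertices projected onto a
#' sphere of the requested radius. Subdivision level L yields
#' `20 * 4^L` faces and `10 * 4^L + 2` vertices (162 at level 2, 2562 at
#' level 4). The mesh is watertight and all faces have positive area.
#'
#' @param subdivision Subdivision level, integer in `[2, 6]`.
#' @param radius Sphere radius in mm.
#' @return An `efnet_mesh`.
#' @export
#' @examples
#' m <- build_template_mesh(2, radius = 100)
#' n_vertices(m)  # 162
build_template_mesh <- function(subdivision, radius = 12) {
  if (subdivision < 2) stop("subdivision level must be >= 2")
  if (subdivision > 6) stop("subdivision level > 6 rejected (mesh too large)")
  if (radius <= 0) stop("radius must be positive (mm)")

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  for (lev in seq_len(subdivision)) {
    nf <- nrow(f)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    # midpoint cache: one new vertex per unique edge
    keys <- c(edge_key(f[, 1], f[, 2]), edge_key(f[, 2], f[, 3]),
              edge_key(f[, 3], f[, 1]))
    uk <- unique(keys)
    mid_idx <- match(keys, uk) + nrow(v)
    pairs <- do.call(rbind, strsplit(uk, " "))
    mids <- (v[as.integer(pairs[, 1]), , drop = FALSE] +
               v[as.integer(pairs[, 2]), , drop = FALSE]) / 2
    v <- rbind(v, mids)
    m12 <- mid_idx[seq_len(nf)]
    m23 <- mid_idx[nf + seq_len(nf)]
    m31 <- mid_idx[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}
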
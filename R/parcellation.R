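#' Build a spatially contiguous parcellation with network assignments
#'
#' Emulates a canonical cortical network parcellation on the template mesh.
#' Parcel centers are chosen by farthest-point sampling (Euclidean distance);
#' every vertex joins its nearest center, giving contiguous Voronoi-like
#' parcels. Parcels are then mapped onto the eight canonical networks so that
#' every network receives at least one parcel. Optional `anchor_vertices`
#' force the first parcel centers to specific vertices (e.g. the stimulation
#' foci), so that each anchored parcel is centred on its focus and can be
#' pinned to a chosen network via `anchor_networks` — this is how a dominant
#' network is planted under a stimulation target.
#'
#' @param mesh An `efnet_mesh`.
#' @param n_parcels Number of parcels, `>= 8`.
#' @param seed Integer seed controlling the (single) random choice of the
#'   first non-anchored center; the construction is otherwise deterministic.
#' @param anchor_vertices Optional integer vector of vertex ids used as the
#'   first parcel centers.
#' @param anchor_networks Optional character vector, same length as
#'   `anchor_vertices`: network label for each anchored parcel.
#' @return An object of class `efnet_parcellation`: list with `vertex_parcel`
#'   (integer parcel id per vertex), `parcel_network` (named character,
#'   network per parcel), `centers` (center vertex ids).
#' @export
build_parcellation <- function(mesh, n_parcels = 8, seed = 1,
                               anchor_vertices = integer(0),
                               anchor_networks = character(0)) {
  if (n_parcels < 8) stop("n_parcels must be >= 8 (one per network)")
  nv <- n_vertices(mesh)
  if (n_parcels > nv) stop("more parcels than vertices")
  if (length(anchor_vertices) != length(anchor_networks)) {
    stop("anchor_vertices and anchor_networks must have equal length")
  }
  if (length(anchor_networks)) check_network(anchor_networks)
  if (anyDuplicated(anchor_vertices)) stop("anchor vertices must be distinct")

  centers <- as.integer(anchor_vertices)
  if (length(centers) == 0L) {
    centers <- with_seed(seed, sample.int(nv, 1L))
  }
  # farthest-point sampling: track min distance to chosen centers
  v <- mesh$vertices
  dmin <- rep(Inf, nv)
  for (c in centers) dmin <- pmin(dmin, vertex_dist(v, c))
  while (length(centers) < n_parcels) {
    nxt <- which.max(dmin)
    centers <- c(centers, nxt)
    dmin <- pmin(dmin, vertex_dist(v, nxt))
  }
  # nearest-center assignment
  d <- matrix(0, nv, n_parcels)
  for (k in seq_len(n_parcels)) d[, k] <- vertex_dist(v, centers[k])
  vertex_parcel <- max.col(-d, ties.method = "first")

  labs <- network_labels()
  parcel_network <- character(n_parcels)
  na <- length(anchor_networks)
  if (na) parcel_network[seq_len(na)] <- anchor_networks
  remaining <- setdiff(labs, anchor_networks)
  if (length(remaining) == 0L) remaining <- labs
  free <- setdiff(seq_len(n_parcels), seq_len(na))
  parcel_network[free] <- rep(remaining, length.out = length(free))
  if (!all(labs %in% parcel_network)) {
    stop("cannot place all eight networks: too few non-anchored parcels")
  }
  names(parcel_network) <- as.character(seq_len(n_parcels))
  structure(list(vertex_parcel = as.integer(vertex_parcel),
                 parcel_network = parcel_network,
                 centers = as.integer(centers)),
            class = "efnet_parcellation")
}

vertex_dist <- function(v, i) {
  sqrt(rowSums(sweep(v, 2, v[i, ])^2))
}

#' @export
print.efnet_parcellation <- function(x, ...) {
  cat(sprintf("<efnet_parcellation> %d vertices, %d parcels, networks: %s\n",
              length(x$vertex_parcel), length(x$parcel_network),
              paste(sort(unique(x$parcel_network)), collapse = " ")))
  invisible(x)
}

#' Network label per vertex
#'
#' @param parcellation An `efnet_parcellation`.
#' @return Character vector: the network each vertex belongs to, via its
#'   parcel.
#' @export
vertex_networks <- function(parcellation) {
  unname(parcellation$parcel_network[as.character(parcellation$vertex_parcel)])
}

#' @keywords internal
check_parcellation <- function(parcellation, mesh = NULL) {
  p <- parcellation
  if (!is.null(mesh) && length(p$vertex_parcel) != n_vertices(mesh)) {
    stop("parcellation does not match mesh vertex count")
  }
  if (anyNA(p$vertex_parcel)) stop("every vertex must have a parcel")
  if (!all(as.character(p$vertex_parcel) %in% names(p$parcel_network))) {
    stop("vertex assigned to a parcel with no network mapping")
  }
  if (!all(network_labels() %in% p$parcel_network)) {
    stop("all eight networks must be present in the parcellation")
  }
  invisible(parcellation)
}
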
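# Seed-averaged FC maps and the vertex-wise maximum-FC network-engagement
# statistic. Seed-averaged FC uses the plain arithmetic mean of r (no
# transform); Fisher z averaging is reserved for run/group averaging of whole
# connectomes, where it is the standard variance-stabilizing practice.

fisher_z <- function(r, cap = 1 - 1e-7) {
  atanh(pmin(pmax(r, -cap), cap))
}
fisher_z_inv <- function(z) tanh(z)

#' Validate a dense connectome
#'
#' @param m Square matrix of Pearson correlations.
#' @param tol Symmetry tolerance.
#' @return `m`, invisibly.
#' @export
check_connectome <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("connectome must be square")
  if (max(abs(m - t(m))) > tol) stop("connectome must be symmetric")
  if (any(abs(diag(m) - 1) > tol)) stop("connectome diagonal must be 1")
  if (min(m) < -1 - tol || max(m) > 1 + tol) {
    stop("connectome entries must lie in [-1, 1]")
  }
  invisible(m)
}

#' Average connectomes across runs (Fisher z)
#'
#' Each off-diagonal entry is Fisher-z transformed (clipping `|r|` at
#' `1 - 1e-7`), averaged across runs, and back-transformed; the diagonal is
#' forced to 1. This is how a subject's four resting-state runs are combined
#' into one connectome.
#'
#' @param runs List of >= 1 same-shaped connectome matrices.
#' @return One averaged connectome matrix.
#' @export
average_fc_runs <- function(runs) {
  if (length(runs) < 1) stop("at least one run is required")
  dims <- vapply(runs, dim, integer(2))
  if (any(dims != dims[, 1])) stop("run connectomes differ in shape")
  z <- Reduce(`+`, lapply(runs, fisher_z)) / length(runs)
  out <- fisher_z_inv(z)
  diag(out) <- 1
  out
}

#' Average connectomes across subjects (Fisher z)
#'
#' Same transform-average-backtransform scheme as [average_fc_runs()], across
#' subjects, producing the cohort's group connectome (the stand-in for an
#' external large-sample group-average dense connectome).
#'
#' @param subject_fc List of subject connectome matrices.
#' @return Group-average connectome matrix.
#' @export
group_average_fc <- function(subject_fc) average_fc_runs(subject_fc)

#' @keywords internal
check_seed_ids <- function(seed, n) {
  ids <- if (inherits(seed, "efnet_seed")) seed$vertex_ids else as.integer(seed)
  if (length(ids) == 0L) stop("empty seed")
  if (any(ids < 1L) || any(ids > n)) stop("seed vertex ids out of range")
  ids
}

#' Seed-averaged FC map
#'
#' The FC of an E-field seed is the average correlation, over all vertices
#' within the seed, to every node of the dense connectome. Seed vertices are
#' not excluded from the map's domain (their values include the r = 1
#' self-correlation term); use `mask_seed = TRUE` to set them `NA` for
#' display.
#'
#' @param connectome Dense connectome matrix.
#' @param seed An `efnet_seed` or integer vector of 1-based vertex ids.
#' @param mask_seed If `TRUE`, seed vertices are masked to `NA` in the output.
#' @return Numeric vector, one mean r per vertex.
#' @export
seed_fc_map <- function(connectome, seed, mask_seed = FALSE) {
  ids <- check_seed_ids(seed, nrow(connectome))
  out <- colMeans(connectome[ids, , drop = FALSE])
  if (mask_seed) out[ids] <- NA_real_
  out
}

#' Mean FC from one vertex to each canonical network
#'
#' For each of the eight networks, the arithmetic mean correlation from
#' `vertex` to all vertices of that network, excluding the vertex itself
#' (self-correlation would bias its own network upward). Signed r is used
#' throughout.
#'
#' @param connectome Dense connectome matrix.
#' @param vertex A single 1-based vertex id.
#' @param parcellation An `efnet_parcellation`.
#' @return Named numeric vector of eight mean r values, fixed network order.
#' @export
vertex_network_fc <- function(connectome, vertex, parcellation) {
  nv <- nrow(connectome)
  if (length(vertex) != 1L || vertex < 1L || vertex > nv) {
    stop("vertex id out of range")
  }
  net <- factor(vertex_networks(parcellation), levels = network_labels())
  row <- connectome[vertex, ]
  sums <- vapply(split(row, net), sum, numeric(1))
  counts <- as.numeric(table(net))
  own <- as.integer(net[vertex])
  sums[own] <- sums[own] - row[vertex]
  counts[own] <- counts[own] - 1
  if (any(counts == 0)) {
    stop("network with zero (non-self) vertices: ",
         paste(network_labels()[counts == 0], collapse = ", "))
  }
  sums / counts
}

#' Assign each seed vertex to its maximum-FC network
#'
#' Winner-take-all over the eight signed mean network correlations of
#' [vertex_network_fc()]; exact ties go to the network earlier in the fixed
#' order. This is the per-vertex statistic behind network engagement.
#'
#' @param connectome Dense connectome matrix.
#' @param seed An `efnet_seed` or integer vector of vertex ids.
#' @param parcellation An `efnet_parcellation`.
#' @return Character vector: one network label per seed vertex.
#' @export
assign_vertices <- function(connectome, seed, parcellation) {
  ids <- check_seed_ids(seed, nrow(connectome))
  labs <- network_labels()
  net <- factor(vertex_networks(parcellation), levels = labs)
  net_idx <- as.integer(net)
  counts <- as.numeric(table(net))
  if (any(counts - 1 <= 0)) {
    stop("network with zero (non-self) vertices: ",
         paste(labs[counts <= 1], collapse = ", "))
  }
  ind <- matrix(0, nrow(connectome), length(labs))
  ind[cbind(seq_len(nrow(connectome)), net_idx)] <- 1
  sums <- connectome[ids, , drop = FALSE] %*% ind           # seed x 8 sums
  cnt <- matrix(counts, length(ids), length(labs), byrow = TRUE)
  own <- net_idx[ids]
  sums[cbind(seq_along(ids), own)] <-
    sums[cbind(seq_along(ids), own)] - connectome[cbind(ids, ids)]
  cnt[cbind(seq_along(ids), own)] <- cnt[cbind(seq_along(ids), own)] - 1
  means <- sums / cnt
  labs[max.col(means, ties.method = "first")]
}

#' Network engagement profile of a seed
#'
#' The spider-plot statistic: the percentage of suprathreshold seed vertices
#' assigned (by maximum FC) to each of the eight canonical networks. All
#' eight networks are reported, zeros included; percentages sum to 100.
#'
#' @param assignments Character vector of network labels (one per seed
#'   vertex), as returned by [assign_vertices()].
#' @return Named numeric vector of eight percentages with attribute
#'   `n_seed_vertices`, class `efnet_profile`.
#' @export
engagement_profile <- function(assignments) {
  if (length(assignments) == 0L) stop("no vertex assignments given")
  check_network(assignments)
  counts <- table(factor(assignments, levels = network_labels()))
  pct <- 100 * as.numeric(counts) / length(assignments)
  names(pct) <- network_labels()
  structure(pct, n_seed_vertices = length(assignments),
            class = "efnet_profile")
}

#' @export
print.efnet_profile <- function(x, ...) {
  cat(sprintf("<efnet_profile> %d seed vertices\n",
              attr(x, "n_seed_vertices")))
  print(round(unclass(x), 1))
  invisible(x)
}

#' Most engaged network of a profile
#'
#' @param profile An `efnet_profile` (or named vector of eight percentages in
#'   fixed network order).
#' @return Single network label: argmax percentage, fixed-order tie-break.
#' @export
most_engaged <- function(profile) {
  names(profile)[which.max(profile)]
}
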
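# Shared fixtures and independent brute-force oracles. All fixtures are
# generated in code under fixed seeds; oracles are deliberately naive
# double-loop implementations, kept independent of the package's vectorized
# paths.

tetra_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

# random correlation matrix with unit diagonal (n vertices)
random_connectome <- function(n, seed) {
  with_seed(seed, {
    x <- matrix(rnorm((n + 10) * n), n + 10, n)
    r <- cor(x)
    diag(r) <- 1
    r
  })
}

# random parcellation covering all eight networks, each with >= 2 vertices
# (non-spatial; used only by the connectivity oracles, which need labels,
# not geometry); requires n >= 16
random_parcellation <- function(n, seed) {
  stopifnot(n >= 16)
  labs <- network_labels()
  vp <- with_seed(seed, {
    sample(c(rep(seq_along(labs), 2),
             sample(seq_along(labs), n - 16, replace = TRUE)))
  })
  structure(list(vertex_parcel = as.integer(vp),
                 parcel_network = setNames(labs, as.character(1:8)),
                 centers = NULL),
            class = "efnet_parcellation")
}

oracle_seed_fc <- function(conn, ids) {
  n <- nrow(conn)
  out <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (i in ids) acc <- acc + conn[i, j]
    out[j] <- acc / length(ids)
  }
  out
}

oracle_vertex_network_fc <- function(conn, v, parc) {
  labs <- network_labels()
  net <- vertex_networks(parc)
  out <- setNames(numeric(8), labs)
  for (k in seq_along(labs)) {
    acc <- 0
    cnt <- 0
    for (j in seq_len(nrow(conn))) {
      if (net[j] == labs[k] && j != v) {
        acc <- acc + conn[v, j]
        cnt <- cnt + 1
      }
    }
    if (cnt == 0) stop("oracle: empty network")
    out[k] <- acc / cnt
  }
  out
}

oracle_assign <- function(conn, ids, parc) {
  labs <- network_labels()
  vapply(ids, function(v) {
    vals <- oracle_vertex_network_fc(conn, v, parc)
    labs[which.max(vals)]   # which.max takes the first maximum
  }, character(1))
}

oracle_profile <- function(assignments) {
  labs <- network_labels()
  out <- setNames(numeric(8), labs)
  for (a in assignments) out[a] <- out[a] + 1
  100 * out / length(assignments)
}

# small cohort used across variant/statistics tests
small_cohort <- function(master_seed = 7, n_subjects = 6, ...) {
  generate_cohort(cohort_spec(n_subjects = n_subjects, mesh_subdivision = 3,
                              n_timepoints = 60, master_seed = master_seed,
                              ...))
}
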
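# Latent-factor connectome generator. Each canonical network has one latent
# time series; vertices load on their network's factor plus a shared global
# signal plus iid noise. Pearson correlation of the vertex series gives a
# dense connectome that is symmetric, unit-diagonal and positive semidefinite
# by construction, and multi-run averaging is meaningful.

# per-vertex factor loadings: base within-network loading scaled by the
# network's multiplier, plus an optional per-subject perturbation delta
vertex_loadings <- function(parcellation, within_network_loading,
                            loading_multipliers = NULL, delta = NULL) {
  labs <- network_labels()
  mult <- rep(1, length(labs))
  names(mult) <- labs
  if (!is.null(loading_multipliers)) {
    check_network(names(loading_multipliers))
    mult[names(loading_multipliers)] <- loading_multipliers
  }
  net <- vertex_networks(parcellation)
  w <- within_network_loading * unname(mult[net])
  if (!is.null(delta)) w <- w + delta
  w
}

#' Simulate one resting-state run's dense connectome
#'
#' Generates latent network time series `f_n(t)` (iid standard normal, one per
#' canonical network) and a shared global signal `g(t)`; each vertex's series
#' is `x_i(t) = w_i * f_net(i)(t) + w_shared * g(t) + eps_i(t)` with
#' `eps ~ N(0, noise_sd^2)`. Returns the vertex-by-vertex Pearson matrix.
#' The expected within-network correlation (unit multipliers, no
#' perturbation, large T) is `w^2 / (w^2 + w_shared^2 + noise_sd^2)`.
#'
#' @param parcellation An `efnet_parcellation` (defines vertex networks).
#' @param n_timepoints Number of time points T (> 3).
#' @param within_network_loading Loading `w` of each vertex on its network
#'   factor.
#' @param shared_loading Loading `w_shared` on the global signal.
#' @param noise_sd SD of the iid vertex noise.
#' @param loading_multipliers Optional named vector of per-network multipliers
#'   on the within-network loading (how a dominant network is planted).
#' @param delta Optional per-vertex loading perturbations (a subject's FC
#'   fingerprint).
#' @return Dense connectome: symmetric matrix with unit diagonal.
#' @export
simulate_fc_run <- function(parcellation, n_timepoints,
                            within_network_loading = 0.6,
                            shared_loading = 0.3, noise_sd = 0.8,
                            loading_multipliers = NULL, delta = NULL) {
  if (n_timepoints <= 3) stop("n_timepoints must exceed 3")
  net_idx <- match(vertex_networks(parcellation), network_labels())
  nv <- length(net_idx)
  w <- vertex_loadings(parcellation, within_network_loading,
                       loading_multipliers, delta)
  f <- matrix(stats::rnorm(n_timepoints * length(network_labels())),
              n_timepoints)
  g <- stats::rnorm(n_timepoints)
  x <- f[, net_idx, drop = FALSE] * rep(w, each = n_timepoints) +
    shared_loading * g +
    matrix(stats::rnorm(n_timepoints * nv, sd = noise_sd), n_timepoints)
  pearson_matrix(x)
}

# column-wise Pearson correlation via BLAS crossprod (exactly symmetric)
pearson_matrix <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  s <- sqrt(colSums(x^2))
  r <- crossprod(x) / outer(s, s)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Simulate a subject's dense connectome (one run)
#'
#' Draws the subject's per-vertex loading perturbations
#' `delta_i ~ N(0, fc_perturbation_scale^2)` and one run of latent series
#' under a seeded stream, then returns the Pearson connectome. Used by
#' [generate_cohort()], which averages several runs per subject.
#'
#' @param parcellation An `efnet_parcellation`.
#' @param spec An `efnet_cohort_spec` (supplies T, loadings, noise).
#' @param params An `efnet_subject_params` (supplies the perturbation scale).
#' @param seed Integer stream seed.
#' @return Dense connectome matrix.
#' @export
simulate_subject_fc <- function(parcellation, spec, params, seed) {
  with_seed(seed, {
    delta <- stats::rnorm(length(parcellation$vertex_parcel),
                          sd = params$fc_perturbation_scale)
    simulate_fc_run(parcellation, spec$n_timepoints,
                    spec$within_network_loading, spec$shared_loading,
                    spec$noise_sd, spec$loading_multipliers, delta)
  })
}

#' Population (noise-free) connectome of the factor model
#'
#' The exact correlation matrix implied by the latent-factor model with no
#' per-subject perturbation and infinite scan length:
#' `r(i,j) = (w_i w_j [net(i)=net(j)] + w_shared^2) / sqrt((w_i^2 + s^2)(w_j^2 + s^2))`
#' with `s^2 = w_shared^2 + noise_sd^2`. Serves as the analytic expectation
#' against which empirical cohort engagement is compared.
#'
#' @param parcellation An `efnet_parcellation`.
#' @param spec An `efnet_cohort_spec`.
#' @return Dense connectome matrix (exact, deterministic).
#' @export
population_connectome <- function(parcellation, spec) {
  net_idx <- match(vertex_networks(parcellation), network_labels())
  w <- vertex_loadings(parcellation, spec$within_network_loading,
                       spec$loading_multipliers)
  s2 <- spec$shared_loading^2 + spec$noise_sd^2
  sd_i <- sqrt(w^2 + s2)
  same <- outer(net_idx, net_idx, "==")
  r <- (outer(w, w) * same + spec$shared_loading^2) / outer(sd_i, sd_i)
  diag(r) <- 1
  r
}
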
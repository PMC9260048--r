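#' Specify a synthetic cohort
#'
#' Collects every knob of the synthetic study in one validated object. The
#' defaults define the packaged study conditions: 40 subjects on a level-4
#' icosphere (2562 vertices, 12 mm radius), an eight-parcel/eight-network
#' parcellation anchored at the two stimulation foci, four resting-state runs
#' of 200 time points per subject, and moderate geometry and FC variability.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param mesh_subdivision Icosphere subdivision level (2-6).
#' @param mesh_radius Template sphere radius, mm.
#' @param n_parcels Number of parcels (>= 8).
#' @param n_timepoints Time points per run (> n_parcels).
#' @param n_runs Resting-state runs per subject (averaged downstream).
#' @param within_network_loading,shared_loading,noise_sd Factor-model
#'   parameters of [simulate_fc_run()].
#' @param loading_multipliers Optional named per-network multipliers on the
#'   within-network loading (e.g. `c(VAN = 3)` plants a dominant VAN).
#' @param fc_perturbation_scale SD of each subject's per-vertex loading
#'   perturbations (FC variability knob).
#' @param amplitude_spread,sigma_spread Log-normal sdlog of the per-subject
#'   amplitude/width factors (geometry variability knobs).
#' @param focus_jitter_sd SD (mm, per axis) of the per-subject focus jitter.
#' @param shared_fc_stream If `TRUE`, all subjects draw their FC from one
#'   stream, making subject connectomes bitwise identical — the "zero FC
#'   variability" degenerate cohort.
#' @param average_order `"fc"` (default): average run-wise connectomes with
#'   Fisher z; `"timeseries"`: average run time series, then correlate once.
#' @param master_seed Mandatory integer master seed; all randomness derives
#'   from it via [stream_seed()].
#' @return An object of class `efnet_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40, mesh_subdivision = 4,
                        mesh_radius = 12, n_parcels = 8, n_timepoints = 200,
                        n_runs = 4, within_network_loading = 0.6,
                        shared_loading = 0.3, noise_sd = 0.8,
                        loading_multipliers = NULL,
                        fc_perturbation_scale = 0.1,
                        amplitude_spread = 0.08, sigma_spread = 0.14,
                        focus_jitter_sd = 1.5, shared_fc_stream = FALSE,
                        average_order = c("fc", "timeseries"),
                        master_seed) {
  if (missing(master_seed)) stop("master_seed is mandatory")
  average_order <- match.arg(average_order)
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (n_parcels < 8) stop("n_parcels must be >= 8")
  if (n_timepoints <= n_parcels) stop("n_timepoints must exceed n_parcels")
  if (n_runs < 1) stop("n_runs must be >= 1")
  stopifnot(within_network_loading >= 0, shared_loading >= 0, noise_sd >= 0,
            fc_perturbation_scale >= 0, amplitude_spread >= 0,
            sigma_spread >= 0, focus_jitter_sd >= 0)
  if (!is.null(loading_multipliers)) {
    check_network(names(loading_multipliers))
    stopifnot(all(loading_multipliers > 0))
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    mesh_subdivision = as.integer(mesh_subdivision),
    mesh_radius = mesh_radius, n_parcels = as.integer(n_parcels),
    n_timepoints = as.integer(n_timepoints), n_runs = as.integer(n_runs),
    within_network_loading = within_network_loading,
    shared_loading = shared_loading, noise_sd = noise_sd,
    loading_multipliers = loading_multipliers,
    fc_perturbation_scale = fc_perturbation_scale,
    amplitude_spread = amplitude_spread, sigma_spread = sigma_spread,
    focus_jitter_sd = focus_jitter_sd,
    shared_fc_stream = isTRUE(shared_fc_stream),
    average_order = average_order,
    master_seed = as.integer(master_seed)), class = "efnet_cohort_spec")
}

draw_subject_params <- function(spec, s) {
  with_seed(stream_seed(spec$master_seed, s, "params"), {
    subject_params(
      amplitude_factor = exp(stats::rnorm(1, sd = spec$amplitude_spread)),
      sigma_factor = exp(stats::rnorm(1, sd = spec$sigma_spread)),
      focus_jitter = stats::rnorm(3, sd = spec$focus_jitter_sd),
      fc_perturbation_scale = spec$fc_perturbation_scale)
  })
}

subject_fc_average <- function(parcellation, spec, params, seed) {
  with_seed(seed, {
    nv <- length(parcellation$vertex_parcel)
    delta <- stats::rnorm(nv, sd = params$fc_perturbation_scale)
    if (spec$average_order == "timeseries") {
      # average the run time series pointwise, then correlate once
      acc <- NULL
      for (run in seq_len(spec$n_runs)) {
        net_idx <- match(vertex_networks(parcellation), network_labels())
        w <- vertex_loadings(parcellation, spec$within_network_loading,
                             spec$loading_multipliers, delta)
        f <- matrix(stats::rnorm(spec$n_timepoints * length(network_labels())),
                    spec$n_timepoints)
        g <- stats::rnorm(spec$n_timepoints)
        x <- f[, net_idx, drop = FALSE] * rep(w, each = spec$n_timepoints) +
          spec$shared_loading * g +
          matrix(stats::rnorm(spec$n_timepoints * nv, sd = spec$noise_sd),
                 spec$n_timepoints)
        acc <- if (is.null(acc)) x else acc + x
      }
      pearson_matrix(acc / spec$n_runs)
    } else {
      runs <- lapply(seq_len(spec$n_runs), function(run) {
        simulate_fc_run(parcellation, spec$n_timepoints,
                        spec$within_network_loading, spec$shared_loading,
                        spec$noise_sd, spec$loading_multipliers, delta)
      })
      average_fc_runs(runs)
    }
  })
}

#' Generate the full synthetic cohort
#'
#' Builds the template mesh and anchored parcellation, simulates the template
#' (identity-parameter) E-field for each placement, then for every subject
#' draws geometry parameters and an individual E-field per placement and a
#' run-averaged dense connectome, and finally Fisher-z-averages subject
#' connectomes into the cohort's group connectome. Fully reproducible from
#' `spec$master_seed`; distinct subjects never share an RNG stream.
#'
#' @param spec An `efnet_cohort_spec`.
#' @param placements Named list of `efnet_placement`s; defaults to
#'   [default_placements()] at the spec's mesh radius.
#' @param anchor_networks Networks pinned to the parcels containing each
#'   placement focus (recycled); defaults to VAN at the dlPFC-like and DMN at
#'   the OFC-like focus.
#' @param keep_runs If `TRUE`, retain each subject's individual run
#'   connectomes (memory-heavy); by default only the run average is stored.
#' @return An object of class `efnet_cohort`: list with `spec`, `mesh`,
#'   `parcellation`, `placements`, `template_efield` (named list of maps),
#'   `subjects` (per subject: `subject_id`, `params`, `efield`, `fc`) and
#'   `group_fc`.
#' @export
generate_cohort <- function(spec, placements = NULL,
                            anchor_networks = c("VAN", "DMN"),
                            keep_runs = FALSE) {
  stopifnot(inherits(spec, "efnet_cohort_spec"))
  if (is.null(placements)) placements <- default_placements(spec$mesh_radius)
  if (length(placements) < 1) stop("at least one placement is required")
  if (is.null(names(placements)) || any(names(placements) == "")) {
    stop("placements must be a named list")
  }
  anchor_networks <- rep(anchor_networks, length.out = length(placements))
  check_network(anchor_networks)

  mesh <- build_template_mesh(spec$mesh_subdivision, spec$mesh_radius)
  anchor_vertices <- vapply(placements, function(p) {
    which.min(rowSums(sweep(mesh$vertices, 2, p$focus_point)^2))
  }, integer(1))
  parcellation <- build_parcellation(
    mesh, spec$n_parcels, seed = stream_seed(spec$master_seed, 0, "parcel"),
    anchor_vertices = unname(anchor_vertices),
    anchor_networks = anchor_networks)

  template_efield <- lapply(placements, function(p) {
    simulate_efield(mesh, p, subject_params())
  })

  z_acc <- NULL
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    params <- draw_subject_params(spec, s)
    efield <- lapply(placements, function(p) simulate_efield(mesh, p, params))
    fc_seed <- stream_seed(spec$master_seed,
                           if (spec$shared_fc_stream) 0L else s, "fc")
    rec <- tryCatch({
      fc <- subject_fc_average(parcellation, spec, params, fc_seed)
      runs <- NULL
      if (keep_runs) {
        runs <- with_seed(fc_seed, {
          delta <- stats::rnorm(n_vertices(mesh),
                                sd = params$fc_perturbation_scale)
          lapply(seq_len(spec$n_runs), function(run) {
            simulate_fc_run(parcellation, spec$n_timepoints,
                            spec$within_network_loading, spec$shared_loading,
                            spec$noise_sd, spec$loading_multipliers, delta)
          })
        })
      }
      list(subject_id = sprintf("sub-%03d", s), params = params,
           efield = efield, fc = fc, fc_runs = runs)
    }, error = function(e) {
      stop(sprintf("subject sub-%03d: %s", s, conditionMessage(e)))
    })
    z_acc <- if (is.null(z_acc)) fisher_z(rec$fc) else z_acc + fisher_z(rec$fc)
    subjects[[s]] <- rec
  }
  group_fc <- fisher_z_inv(z_acc / spec$n_subjects)
  diag(group_fc) <- 1

  structure(list(spec = spec, mesh = mesh, parcellation = parcellation,
                 placements = placements, anchor_vertices = anchor_vertices,
                 template_efield = template_efield, subjects = subjects,
                 group_fc = group_fc),
            class = "efnet_cohort")
}

#' @export
print.efnet_cohort <- function(x, ...) {
  cat(sprintf(
    "<efnet_cohort> %d subjects, %d-vertex mesh, %d parcels, targets: %s\n",
    length(x$subjects), n_vertices(x$mesh), length(x$parcellation$parcel_network),
    paste(names(x$placements), collapse = ", ")))
  invisible(x)
}
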
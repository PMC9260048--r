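#' Read a cohort specification from a YAML config file
#'
#' Every field of [cohort_spec()] may appear as a top-level key;
#' `master_seed` is mandatory. `loading_multipliers` is given as a mapping
#' of network label to multiplier. Unknown keys are an error, so typos do
#' not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An `efnet_cohort_spec`.
#' @export
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("n_subjects: 4", "mesh_subdivision: 2",
#'              "n_timepoints: 30", "master_seed: 7",
#'              "loading_multipliers:", "  VAN: 3"), cfg)
#' cohort_spec_from_yaml(cfg)$n_subjects
cohort_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$master_seed)) stop("master_seed is mandatory in the config")
  known <- names(formals(cohort_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$loading_multipliers)) {
    cfg$loading_multipliers <- unlist(cfg$loading_multipliers)
  }
  do.call(cohort_spec, cfg)
}
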
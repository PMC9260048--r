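#' Factor-model expectation of cohort engagement
#'
#' Runs the engagement pipeline with each subject's own E-field seed against
#' the exact population connectome of the factor model
#' ([population_connectome()]) instead of the subject's noisy empirical
#' connectome. The cohort mean of these noise-free profiles is the analytic
#' expectation of engagement under the planted network structure, against
#' which the empirical cohort mean can be compared (parameter recovery).
#'
#' @param cohort An `efnet_cohort`.
#' @param target Placement name.
#' @param threshold E-field threshold, V/m.
#' @return List with `profiles` (subject x network matrix), `mean_profile`
#'   (named vector) and `most_engaged` (per-subject labels).
#' @export
expected_engagement <- function(cohort, target, threshold = 0.9) {
  stopifnot(inherits(cohort, "efnet_cohort"))
  pop <- population_connectome(cohort$parcellation, cohort$spec)
  labs <- network_labels()
  ns <- length(cohort$subjects)
  profiles <- matrix(NA_real_, ns, length(labs),
                     dimnames = list(NULL, labs))
  engaged <- rep(NA_character_, ns)
  for (s in seq_len(ns)) {
    sub <- cohort$subjects[[s]]
    seed <- tryCatch(extract_seed(sub$efield[[target]], cohort$mesh,
                                  threshold),
                     error = function(e) NULL)
    if (is.null(seed)) next
    prof <- engagement_profile(
      assign_vertices(pop, seed, cohort$parcellation))
    profiles[s, ] <- as.numeric(prof)
    engaged[s] <- most_engaged(prof)
  }
  keep <- !is.na(profiles[, 1])
  list(profiles = profiles,
       mean_profile = colMeans(profiles[keep, , drop = FALSE]),
       most_engaged = engaged)
}
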
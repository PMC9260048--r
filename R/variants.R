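#' The three E-field/FC pairing variants
#'
#' * `GEOM` — subject-specific E-field seed x group-average FC: isolates the
#'   influence of individual cortical geometry (FC held constant).
#' * `FCONLY` — template E-field seed x subject FC: isolates the influence of
#'   each subject's unique connectivity profile (geometry held constant).
#' * `COMBINED` — subject E-field x subject FC: the real-world scenario where
#'   both sources act jointly.
#'
#' @return Character vector of the three variant kinds.
#' @export
variant_kinds <- function() c("GEOM", "FCONLY", "COMBINED")

#' Run the engagement pipeline under one variant
#'
#' For every subject: extract the E-field seed (subject-specific or template,
#' depending on the variant), compute the seed-averaged FC map, assign each
#' seed vertex to its maximum-FC network, and summarize as an engagement
#' profile. Subjects whose field never reaches the threshold are recorded as
#' excluded with a warning and dropped from downstream statistics.
#'
#' @param cohort An `efnet_cohort`.
#' @param target Placement name (e.g. `"dlpfc"`, `"ofc"`).
#' @param variant One of `"GEOM"`, `"FCONLY"`, `"COMBINED"`.
#' @param threshold E-field threshold, V/m (default 0.9).
#' @return An object of class `efnet_variant`: list with `variant`, `target`,
#'   `threshold`, `subject_ids`, `included` (logical), `seeds`, `profiles`
#'   (subject x network matrix, `NA` rows for excluded subjects),
#'   `most_engaged`, `seed_fc` (subject x vertex matrix), `n_excluded`.
#' @export
run_variant <- function(cohort, target, variant, threshold = 0.9) {
  stopifnot(inherits(cohort, "efnet_cohort"))
  variant <- match.arg(variant, variant_kinds())
  if (!target %in% names(cohort$placements)) {
    stop("cohort has no placement named '", target, "'")
  }
  mesh <- cohort$mesh
  parc <- cohort$parcellation
  ns <- length(cohort$subjects)
  nv <- n_vertices(mesh)
  labs <- network_labels()

  template_seed <- extract_seed(cohort$template_efield[[target]], mesh,
                                threshold)
  profiles <- matrix(NA_real_, ns, length(labs),
                     dimnames = list(NULL, labs))
  seed_fc <- matrix(NA_real_, ns, nv)
  seeds <- vector("list", ns)
  engaged <- rep(NA_character_, ns)
  included <- logical(ns)

  for (s in seq_len(ns)) {
    sub <- cohort$subjects[[s]]
    seed <- if (variant == "FCONLY") {
      template_seed
    } else {
      tryCatch(extract_seed(sub$efield[[target]], mesh, threshold),
               error = function(e) {
                 warning(sprintf("%s (%s): subject %s excluded: %s",
                                 variant, target, sub$subject_id,
                                 conditionMessage(e)))
                 NULL
               })
    }
    if (is.null(seed)) next
    conn <- if (variant == "GEOM") cohort$group_fc else sub$fc
    seeds[[s]] <- seed
    seed_fc[s, ] <- seed_fc_map(conn, seed)
    prof <- engagement_profile(assign_vertices(conn, seed, parc))
    profiles[s, ] <- as.numeric(prof)
    engaged[s] <- most_engaged(prof)
    included[s] <- TRUE
  }
  structure(list(
    variant = variant, target = target, threshold = threshold,
    subject_ids = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    included = included, seeds = seeds, profiles = profiles,
    most_engaged = engaged, seed_fc = seed_fc,
    n_excluded = sum(!included)), class = "efnet_variant")
}

#' @export
print.efnet_variant <- function(x, ...) {
  cat(sprintf("<efnet_variant> %s / %s, threshold %g V/m: %d subjects (%d excluded)\n",
              x$variant, x$target, x$threshold, length(x$subject_ids),
              x$n_excluded))
  invisible(x)
}

#' Engagement matrix of a variant result
#'
#' @param res An `efnet_variant`.
#' @return Numeric matrix, included subjects x eight networks; every row sums
#'   to 100.
#' @export
engagement_matrix <- function(res) {
  m <- res$profiles[res$included, , drop = FALSE]
  if (nrow(m) < 1) stop("no included subjects in variant result")
  m
}

#' Cross-variant engagement correlation
#'
#' Pearson correlation, across subjects, of one network's engagement
#' percentage between two variants of the same cohort and target — the
#' statistic quantifying how well one information source (e.g. group FC)
#' predicts individual network loading. Subjects excluded in either variant
#' are dropped pairwise.
#'
#' @param res_a,res_b Two `efnet_variant`s with the same target and subjects.
#' @param network One network label.
#' @return Pearson r.
#' @export
cross_variant_engagement_correlation <- function(res_a, res_b, network) {
  check_network(network)
  if (!identical(res_a$subject_ids, res_b$subject_ids)) {
    stop("variant results come from different cohorts")
  }
  if (!identical(res_a$target, res_b$target)) {
    stop("variant results target different placements")
  }
  keep <- res_a$included & res_b$included
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " subject(s) dropped pairwise (empty seed)")
  }
  a <- res_a$profiles[keep, network]
  b <- res_b$profiles[keep, network]
  pearson_r(a, b, label = network)
}

#' Most-engaged-network counts over a cohort
#'
#' How many included subjects have each network as their most engaged; counts
#' sum to the number of included subjects.
#'
#' @param res An `efnet_variant`.
#' @return Named integer vector over the eight networks.
#' @export
most_engaged_counts <- function(res) {
  eng <- res$most_engaged[res$included]
  if (length(eng) < 1) stop("no included subjects in variant result")
  out <- table(factor(eng, levels = network_labels()))
  stats::setNames(as.integer(out), network_labels())
}
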
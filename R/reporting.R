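#' Per-network summary of a variant result
#'
#' Mean and SD of engagement percentage per network over included subjects,
#' plus most-engaged counts — the table behind the spider-plot summaries.
#' Sample SD is the default; `population_sd = TRUE` uses the n-denominator
#' variant (the choice is recorded in the `sd_type` attribute).
#'
#' @param res An `efnet_variant`.
#' @param population_sd Use population (n-denominator) SD instead of sample
#'   SD.
#' @return `data.frame` with eight rows: `target`, `variant`, `network`,
#'   `mean_percent`, `sd_percent`, `most_engaged_count`.
#' @export
summarize_variant <- function(res, population_sd = FALSE) {
  m <- engagement_matrix(res)
  n <- nrow(m)
  if (n == 1) {
    warning("single included subject: SD reported as 0")
    sds <- rep(0, ncol(m))
  } else {
    sds <- apply(m, 2, stats::sd)
    if (population_sd) sds <- sds * sqrt((n - 1) / n)
  }
  out <- data.frame(
    target = res$target, variant = res$variant, network = colnames(m),
    mean_percent = unname(colMeans(m)), sd_percent = unname(sds),
    most_engaged_count = unname(most_engaged_counts(res)),
    row.names = NULL)
  attr(out, "sd_type") <- if (population_sd) "population" else "sample"
  attr(out, "n_subjects") <- n
  out
}

#' Summed mean engagement of a set of networks
#'
#' The coverage statistic quoted alongside spider plots: the sum of the mean
#' engagement percentages of the chosen networks (e.g. the three headline
#' networks of a target). Returns full precision with an integer-rounded
#' `display` value for reporting; files keep full precision.
#'
#' @param rows A summary `data.frame` from [summarize_variant()] (or any
#'   data frame with `network` and `mean_percent` columns).
#' @param networks Nonempty subset of network labels.
#' @return List with `value` (full precision percent) and `display` (rounded
#'   to the nearest integer).
#' @export
#' @examples
#' s <- data.frame(network = c("VAN", "FPN", "DMN"),
#'                 mean_percent = c(38.2, 27.9, 20.3))
#' topk_coverage(s, c("VAN", "FPN", "DMN"))$display  # 86
topk_coverage <- function(rows, networks) {
  if (length(networks) == 0) stop("networks subset must be nonempty")
  check_network(networks)
  missing <- setdiff(networks, rows$network)
  if (length(missing)) {
    stop("networks absent from summary: ", paste(missing, collapse = ", "))
  }
  value <- sum(rows$mean_percent[match(networks, rows$network)])
  list(value = value, display = round(value))
}

#' Spider-plot polygon area fraction
#'
#' Engagement profiles are drawn as polygons on a regular eight-direction
#' fan with radius `percent / 100` per network. The area of that polygon,
#' normalized by the unit regular octagon, is
#' `sum_i r_i * r_(i+1) / 8` (indices cyclic in the fixed network order).
#' A single nonzero spoke has zero area (two adjacent radii are needed).
#'
#' @param profile An `efnet_profile` or numeric vector of eight percentages
#'   in fixed network order.
#' @return Area fraction in `[0, 1]`.
#' @export
spider_polygon_area <- function(profile) {
  r <- as.numeric(profile) / 100
  if (length(r) != 8) stop("profile must have eight network percentages")
  if (any(r < 0) || any(r > 1 + 1e-9)) stop("percentages must be in [0, 100]")
  sum(r * r[c(2:8, 1)]) / 8
}

#' Spider-plot data for a profile
#'
#' @param profile An `efnet_profile`.
#' @return `data.frame` with `network` (fixed order), `percent`, plus the
#'   normalized polygon `area_fraction` as an attribute.
#' @export
spider_data <- function(profile) {
  out <- data.frame(network = network_labels(),
                    percent = as.numeric(profile))
  attr(out, "area_fraction") <- spider_polygon_area(profile)
  out
}

#' Write engagement profiles as a long-format TSV
#'
#' One row per (subject, network): `subject_id`, `target`, `variant`,
#' `network`, `percent`. Excluded subjects are omitted.
#'
#' @param res An `efnet_variant`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_engagement_tsv <- function(res, path) {
  m <- engagement_matrix(res)
  ids <- res$subject_ids[res$included]
  long <- data.frame(
    subject_id = rep(ids, each = ncol(m)),
    target = res$target, variant = res$variant,
    network = rep(colnames(m), times = nrow(m)),
    percent = as.vector(t(m)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read engagement profiles from a long-format TSV
#'
#' @param path TSV written by [write_engagement_tsv()].
#' @return `data.frame` in the same long format.
#' @export
read_engagement_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
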
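# Repeated-measures one-way ANOVA over the eight-network within-subject
# factor, Tukey-corrected pairwise post hocs on the same error term, paired
# target contrasts and Pearson utilities.

#' Repeated-measures one-way ANOVA (within-subject factor NETWORK)
#'
#' Classical within-subject decomposition of a subjects x levels matrix:
#' `SS_total = SS_subjects + SS_levels + SS_error`, with
#' `F = MS_levels / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. Effect size is partial eta squared,
#' `SS_levels / (SS_levels + SS_error)`. No sphericity correction is applied
#' by default; `gg_correction = TRUE` applies Greenhouse-Geisser adjusted
#' degrees of freedom to the p-value.
#'
#' @param m Numeric matrix: rows = subjects (>= 2), columns = within-subject
#'   levels (>= 2), e.g. an engagement matrix.
#' @param gg_correction Apply Greenhouse-Geisser df correction (default
#'   `FALSE`).
#' @return List of class `efnet_anova`: `F`, `df_effect`, `df_error`, `p`,
#'   `eta_sq`, `ms_error`, plus the sums of squares.
#' @export
#' @examples
#' rm_anova_network(rbind(c(1, 2), c(2, 4), c(3, 6)))  # F = 12 on (1, 2) df
rm_anova_network <- function(m, gg_correction = FALSE) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 levels")
  grand <- mean(m)
  ss_subjects <- k * sum((rowMeans(m) - grand)^2)
  ss_levels <- n * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_subjects - ss_levels
  df_effect <- k - 1
  df_error <- (k - 1) * (n - 1)
  ms_error <- ss_error / df_error
  if (ms_error <= .Machine$double.eps * max(1, ss_total)) {
    warning("zero within-subject error variance; F reported as +Inf")
    f <- if (ss_levels > 0) Inf else 0
    p <- if (ss_levels > 0) 0 else 1
    eps <- 1
  } else {
    f <- (ss_levels / df_effect) / ms_error
    eps <- if (gg_correction) gg_epsilon(m) else 1
    p <- stats::pf(f, eps * df_effect, eps * df_error, lower.tail = FALSE)
  }
  eta_sq <- if (ss_levels + ss_error > 0) ss_levels / (ss_levels + ss_error)
            else 0
  structure(list(F = f, df_effect = df_effect, df_error = df_error, p = p,
                 eta_sq = eta_sq, ms_error = ms_error,
                 ss_levels = ss_levels, ss_subjects = ss_subjects,
                 ss_error = ss_error, gg_epsilon = eps),
            class = "efnet_anova")
}

# Greenhouse-Geisser epsilon from the double-centred covariance of levels
gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  C <- S - outer(rowMeans(S), colMeans(S), function(a, b) a + b) + mean(S)
  num <- (sum(diag(C)))^2
  den <- (k - 1) * sum(C^2)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.efnet_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%g, %g) = %.4g, p = %.3g, partial eta^2 = %.3f\n",
              x$df_effect, x$df_error, x$F, x$p, x$eta_sq))
  invisible(x)
}

#' Tukey-corrected pairwise post hocs for the within-subject factor
#'
#' All pairwise level differences tested against the studentized-range
#' distribution, using the pooled `MS_error` and `df_error` from the
#' repeated-measures decomposition. Raw (uncorrected) p-values use the
#' pooled-error t statistic. For two levels the Tukey-adjusted p equals the
#' unadjusted one (`q = t * sqrt(2)`); for more levels it is never smaller.
#'
#' @param m Numeric matrix, subjects x levels (named columns label the
#'   pairs).
#' @return `data.frame` of class `efnet_posthoc`, one row per level pair:
#'   `level_a`, `level_b`, `mean_diff`, `t`, `p_raw`, `p_tukey`,
#'   `sig_tukey` (adjusted p < 0.05), `sig_raw` (raw p < 0.05).
#' @export
tukey_posthoc <- function(m) {
  m <- as.matrix(m)
  a <- suppressWarnings(rm_anova_network(m))  # degeneracy re-reported below
  n <- nrow(m)
  k <- ncol(m)
  labs <- colnames(m)
  if (is.null(labs)) labs <- paste0("L", seq_len(k))
  se <- sqrt(2 * a$ms_error / n)
  pairs <- utils::combn(k, 2)
  cm <- colMeans(m)
  out <- data.frame(
    level_a = labs[pairs[1, ]], level_b = labs[pairs[2, ]],
    mean_diff = cm[pairs[1, ]] - cm[pairs[2, ]], row.names = NULL)
  if (a$ms_error <= 0 || !is.finite(a$ms_error)) {
    warning("zero error variance; degenerate post hocs")
    out$t <- ifelse(out$mean_diff == 0, 0, Inf * sign(out$mean_diff))
    out$p_raw <- ifelse(out$mean_diff == 0, 1, 0)
    out$p_tukey <- out$p_raw
  } else {
    out$t <- out$mean_diff / se
    out$p_raw <- 2 * stats::pt(-abs(out$t), a$df_error)
    if (k == 2) {
      # q = t * sqrt(2): the range distribution reduces to the paired
      # comparison exactly; bypass ptukey's numerical approximation
      out$p_tukey <- out$p_raw
    } else {
      q <- abs(out$t) * sqrt(2)
      out$p_tukey <- stats::ptukey(q, k, a$df_error, lower.tail = FALSE)
    }
  }
  out$sig_tukey <- out$p_tukey < 0.05
  out$sig_raw <- out$p_raw < 0.05
  class(out) <- c("efnet_posthoc", "data.frame")
  out
}

#' Paired contrast of one network's engagement between two targets
#'
#' Two-sided paired t-test of per-subject engagement percentages between two
#' stimulation targets (e.g. dlPFC vs OFC loading on the DMN).
#'
#' @param a,b Equal-length (>= 3) numeric vectors of per-subject percentages
#'   for the two targets.
#' @param network Optional label used in messages.
#' @return List with `T` (paired t statistic), `df`, `p`.
#' @export
paired_target_contrast <- function(a, b, network = NULL) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 paired observations")
  d <- a - b
  if (all(d == 0)) return(list(T = 0, df = length(d) - 1, p = 1))
  if (stats::var(d) == 0) {
    stop("zero variance of paired differences",
         if (!is.null(network)) paste0(" for ", network) else "")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(T = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with explicit degenerate-input errors (the bare-metal
#' utility behind cross-variant engagement correlations).
#'
#' @param x,y Equal-length (>= 3) numeric vectors.
#' @param label Optional label used in error messages.
#' @return Pearson r.
#' @export
pearson_r <- function(x, y, label = NULL) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  tag <- if (!is.null(label)) paste0(" for ", label) else ""
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined (zero variance)", tag)
  }
  stats::cor(x, y)
}
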
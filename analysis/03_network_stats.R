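#!/usr/bin/env Rscript
# Stage 3 — statistics over the engagement profiles.
#
# Per target x variant: repeated-measures one-way ANOVA with the
# within-subject factor NETWORK (eight levels), Tukey-corrected pairwise
# post hocs on the same error term; between targets: paired t contrasts of
# the headline networks; between variants: Pearson correlations of each
# network's engagement across subjects.
#
# Outputs: results/anova.tsv, results/posthoc.tsv, results/contrasts.tsv,
#          results/correlations.tsv

suppressPackageStartupMessages(library(efnet))

variants <- readRDS("scratch/variants.rds")
dir.create("results", showWarnings = FALSE)

## RM-ANOVA + post hocs -------------------------------------------------------
anova_rows <- list()
posthoc_rows <- list()
for (key in names(variants)) {
  res <- variants[[key]]
  m <- engagement_matrix(res)
  a <- rm_anova_network(m)
  anova_rows[[key]] <- data.frame(
    target = res$target, variant = res$variant, F = a$F,
    df_effect = a$df_effect, df_error = a$df_error, p = a$p,
    partial_eta_sq = a$eta_sq)
  ph <- tryCatch(tukey_posthoc(m), warning = function(w) {
    message(key, ": ", conditionMessage(w)); suppressWarnings(tukey_posthoc(m))
  })
  posthoc_rows[[key]] <- cbind(target = res$target, variant = res$variant, ph)
  cat(sprintf("%-18s F(%d, %d) = %.2f, p = %.3g, eta^2 = %.2f\n", key,
              a$df_effect, a$df_error, a$F, a$p, a$eta_sq))
}
write.table(do.call(rbind, anova_rows), "results/anova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, posthoc_rows), "results/posthoc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## paired target contrasts (dlPFC vs OFC per network, COMBINED variant) -------
rc_d <- variants$dlpfc_combined
rc_o <- variants$ofc_combined
keep <- rc_d$included & rc_o$included
contrast_rows <- list()
for (nw in network_labels()) {
  ct <- tryCatch(paired_target_contrast(rc_d$profiles[keep, nw],
                                        rc_o$profiles[keep, nw], nw),
                 error = function(e) NULL)
  if (is.null(ct)) next
  contrast_rows[[nw]] <- data.frame(network = nw, T = ct$T, df = ct$df,
                                    p = ct$p)
  cat(sprintf("dlPFC vs OFC, %-7s T = %6.1f, p = %.3g\n", nw, ct$T, ct$p))
}
write.table(do.call(rbind, contrast_rows), "results/contrasts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## cross-variant engagement correlations --------------------------------------
pairs <- list(c("geom", "combined"), c("fconly", "combined"),
              c("geom", "fconly"))
corr_rows <- list()
for (tg in c("dlpfc", "ofc")) {
  for (pr in pairs) {
    ra <- variants[[paste(tg, pr[1], sep = "_")]]
    rb <- variants[[paste(tg, pr[2], sep = "_")]]
    for (nw in network_labels()) {
      r <- tryCatch(
        suppressMessages(cross_variant_engagement_correlation(ra, rb, nw)),
        error = function(e) NA_real_)
      corr_rows[[length(corr_rows) + 1]] <- data.frame(
        target = tg, variant_a = toupper(pr[1]), variant_b = toupper(pr[2]),
        network = nw, pearson_r = r)
    }
  }
}
corr <- do.call(rbind, corr_rows)
write.table(corr, "results/correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
hl <- corr[corr$network %in% c("VAN", "FPN", "DMN") & !is.na(corr$pearson_r), ]
if (nrow(hl)) {
  cat("headline-network cross-variant correlations:\n")
  print(hl, row.names = FALSE)
}
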
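#!/usr/bin/env Rscript
# Stage 4 — reporting layer: spider-plot data, coverage sums, counts.
#
# For every target x variant: the fixed-order spider data with normalized
# polygon area per subject, the summed mean engagement of the top three
# networks (coverage), and most-engaged-network counts.
#
# Outputs: results/spider_data.tsv, results/coverage.tsv,
#          results/most_engaged_counts.tsv

suppressPackageStartupMessages(library(efnet))

variants <- readRDS("scratch/variants.rds")
dir.create("results", showWarnings = FALSE)

spider_rows <- list()
coverage_rows <- list()
count_rows <- list()
for (key in names(variants)) {
  res <- variants[[key]]
  m <- engagement_matrix(res)
  ids <- res$subject_ids[res$included]
  for (i in seq_len(nrow(m))) {
    spider_rows[[length(spider_rows) + 1]] <- data.frame(
      subject_id = ids[i], target = res$target, variant = res$variant,
      t(m[i, ]), polygon_area_fraction = spider_polygon_area(m[i, ]))
  }
  s <- summarize_variant(res)
  top3 <- s$network[order(-s$mean_percent)][1:3]
  cov <- topk_coverage(s, top3)
  coverage_rows[[key]] <- data.frame(
    target = res$target, variant = res$variant,
    networks = paste(top3, collapse = "+"),
    coverage_percent = cov$value, coverage_display = cov$display)
  cnt <- most_engaged_counts(res)
  count_rows[[key]] <- data.frame(
    target = res$target, variant = res$variant,
    network = names(cnt), n_subjects = unname(cnt))
  cat(sprintf("%-8s %-8s top-3 %s cover %d%% of seed vertices; counts: %s\n",
              res$target, res$variant, paste(top3, collapse = "+"),
              cov$display,
              paste(sprintf("%s:%d", names(cnt)[cnt > 0], cnt[cnt > 0]),
                    collapse = " ")))
}
write.table(do.call(rbind, spider_rows), "results/spider_data.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, coverage_rows), "results/coverage.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, count_rows), "results/most_engaged_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("report tables written under results/\n")
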
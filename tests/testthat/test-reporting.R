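test_that("variant summaries report mean, SD and top-network counts", {
  profiles <- matrix(0, 2, 8, dimnames = list(NULL, network_labels()))
  profiles[, "VAN"] <- c(10, 30)
  profiles[, "FPN"] <- c(90, 70)
  res <- structure(list(variant = "GEOM", target = "dlpfc", threshold = 0.9,
                        subject_ids = c("sub-001", "sub-002"),
                        included = c(TRUE, TRUE), profiles = profiles,
                        most_engaged = c("FPN", "FPN")),
                   class = "efnet_variant")
  s <- summarize_variant(res)
  expect_equal(nrow(s), 8L)
  expect_equal(s$mean_percent[s$network == "VAN"], 20)
  expect_equal(s$sd_percent[s$network == "VAN"], 14.142135623731,
               tolerance = 1e-9)
  expect_equal(s$most_engaged_count[s$network == "FPN"], 2L)
  expect_equal(sum(s$mean_percent), 100)           # rows sum to 100
  expect_equal(attr(s, "sd_type"), "sample")
  sp <- summarize_variant(res, population_sd = TRUE)
  expect_equal(sp$sd_percent[sp$network == "VAN"], 10)
})

test_that("single-subject summaries warn and report zero SD", {
  profiles <- matrix(0, 1, 8, dimnames = list(NULL, network_labels()))
  profiles[, "DMN"] <- 100
  res <- structure(list(variant = "GEOM", target = "ofc", threshold = 0.9,
                        subject_ids = "sub-001", included = TRUE,
                        profiles = profiles, most_engaged = "DMN"),
                   class = "efnet_variant")
  expect_warning(s <- summarize_variant(res), "single")
  expect_true(all(s$sd_percent == 0))
})

test_that("coverage sums reproduce the printed headline percentages", {
  printed <- list(
    list(means = c(VAN = 38.2, FPN = 27.9, DMN = 20.3), display = 86),
    list(means = c(FPN = 46.5, DMN = 51.4), display = 98),
    list(means = c(VAN = 30.6, FPN = 29.0, DMN = 21.5), display = 81),
    list(means = c(FPN = 23.4, DMN = 42.0), display = 65),
    list(means = c(VAN = 22.2, FPN = 34.6, DMN = 18.4), display = 75),
    list(means = c(FPN = 38.1, DMN = 37.8), display = 76))
  for (case in printed) {
    rows <- data.frame(network = names(case$means),
                       mean_percent = unname(case$means))
    cov <- topk_coverage(rows, names(case$means))
    expect_equal(cov$display, case$display)
    expect_equal(cov$value, sum(case$means))       # full precision retained
  }
})

test_that("coverage handles completeness, identity and bad names", {
  rows <- data.frame(network = network_labels(),
                     mean_percent = c(5, 5, 10, 40, 5, 20, 5, 10))
  expect_equal(topk_coverage(rows, network_labels())$value, 100)
  expect_equal(topk_coverage(rows, "VAN")$value, 40)
  expect_error(topk_coverage(rows, "Bogus"), "unknown network")
  expect_error(topk_coverage(rows, character(0)), "nonempty")
  expect_error(topk_coverage(rows[1:3, ], "VAN"), "absent")
})

test_that("spider polygon area follows the unit-octagon normalization", {
  full <- engagement_profile(rep(network_labels(), 2))   # 12.5% each
  expect_equal(spider_polygon_area(rep(100, 8)), 1)
  expect_equal(spider_polygon_area(rep(0, 8)), 0)
  expect_equal(spider_polygon_area(c(100, rep(0, 7))), 0)  # single spike
  expect_equal(spider_polygon_area(full), 8 * 0.125^2 / 8)
  # two adjacent spokes at 100: one product term
  expect_equal(spider_polygon_area(c(100, 100, rep(0, 6))), 1 / 8)
  expect_error(spider_polygon_area(rep(50, 7)), "eight")
  sd <- spider_data(full)
  expect_equal(sd$network, network_labels())
  expect_equal(attr(sd, "area_fraction"), 0.015625)
})

test_that("engagement TSV round-trips at full precision", {
  profiles <- matrix(runif(24, 0, 50), 3, 8,
                     dimnames = list(NULL, network_labels()))
  profiles <- profiles / rowSums(profiles) * 100
  res <- structure(list(variant = "COMBINED", target = "dlpfc",
                        threshold = 0.9,
                        subject_ids = sprintf("sub-%03d", 1:3),
                        included = rep(TRUE, 3), profiles = profiles,
                        most_engaged = rep("VAN", 3)),
                   class = "efnet_variant")
  path <- file.path(withr::local_tempdir(), "engagement.tsv")
  write_engagement_tsv(res, path)
  long <- read_engagement_tsv(path)
  expect_equal(nrow(long), 24L)
  expect_equal(long$percent, as.vector(t(profiles)), tolerance = 1e-12)
  expect_true(all(long$variant == "COMBINED"))
})
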
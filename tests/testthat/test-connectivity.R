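test_that("run averaging uses the Fisher z transform entrywise", {
  a <- matrix(c(1, 0.3, 0.3, 1), 2)
  b <- matrix(c(1, 0.5, 0.5, 1), 2)
  avg <- average_fc_runs(list(a, b))
  # hand Fisher-z arithmetic: tanh((atanh .3 + atanh .5) / 2)
  expect_equal(avg[1, 2], 0.404830522383856, tolerance = 1e-12)
  expect_equal(diag(avg), c(1, 1))
  # single run returned unchanged (up to clipping)
  expect_equal(average_fc_runs(list(a)), a, tolerance = 1e-9)
  # odd-function symmetry: r and -r average to 0
  neg <- a; neg[1, 2] <- neg[2, 1] <- -0.3
  expect_equal(average_fc_runs(list(a, neg))[1, 2], 0)
  expect_error(average_fc_runs(list()), "at least one")
  expect_error(average_fc_runs(list(a, matrix(1, 3, 3))), "shape")
})

test_that("group averaging is idempotent, order-invariant, and Fisher-exact", {
  m1 <- matrix(c(1, 0.1, 0.1, 1), 2)
  m2 <- matrix(c(1, 0.2, 0.2, 1), 2)
  m3 <- matrix(c(1, 0.3, 0.3, 1), 2)
  g <- group_average_fc(list(m1, m2, m3))
  expect_equal(g[1, 2], 0.201404338033699, tolerance = 1e-12)
  expect_equal(g, group_average_fc(list(m3, m1, m2)))
  expect_equal(group_average_fc(list(m2, m2, m2)), m2, tolerance = 1e-9)
})

test_that("seed FC map is the plain mean of seed rows", {
  conn <- matrix(c(1, .5, .2,
                   .5, 1, .4,
                   .2, .4, 1), 3, byrow = TRUE)
  v <- seed_fc_map(conn, c(1L, 2L))
  expect_equal(v[3], 0.3)                       # mean of .2, .4
  expect_equal(v[1], 0.75)                      # self-correlation included
  # singleton seed returns the matrix row
  expect_equal(seed_fc_map(conn, 2L), conn[2, ])
  # masking seed vertices for display
  vm <- seed_fc_map(conn, c(1L, 2L), mask_seed = TRUE)
  expect_true(all(is.na(vm[1:2])))
  expect_equal(vm[3], 0.3)
  expect_error(seed_fc_map(conn, integer(0)), "empty seed")
})

test_that("vertex-to-network FC averages signed r with self-exclusion", {
  # two vertices per network; vertex 1's row set by hand so that its own
  # network (excluding itself) has mean .6 and the next network mean .3
  parc <- structure(list(vertex_parcel = rep(1:8, each = 2),
                         parcel_network = setNames(network_labels(),
                                                   as.character(1:8)),
                         centers = NULL), class = "efnet_parcellation")
  conn <- diag(16)
  conn[1, 2:4] <- c(.6, .2, .4)
  conn[2:4, 1] <- c(.6, .2, .4)
  vals <- vertex_network_fc(conn, 1L, parc)
  expect_equal(unname(vals["Vis"]), 0.6)         # own network, self excluded
  expect_equal(unname(vals["SomMot"]), 0.3)      # mean of .2 and .4
  expect_equal(unname(vals[3:8]), rep(0, 6))     # zero rows stay zero
  # constant off-diagonal row: all networks see the same constant
  connc <- matrix(0.25, 16, 16); diag(connc) <- 1
  expect_equal(unname(vertex_network_fc(connc, 5L, parc)), rep(0.25, 8))
})

test_that("winner-take-all assignment breaks ties by fixed network order", {
  parc <- structure(list(vertex_parcel = rep(1:8, each = 2),
                         parcel_network = setNames(network_labels(),
                                                   as.character(1:8)),
                         centers = NULL), class = "efnet_parcellation")
  # vertex 16 (DMN): equal FC to VAN and FPN vertices, zero elsewhere
  conn <- diag(16)
  conn[16, 7:8] <- conn[7:8, 16] <- 0.5          # VAN parcel vertices
  conn[16, 11:12] <- conn[11:12, 16] <- 0.5      # FPN parcel vertices
  expect_equal(assign_vertices(conn, 16L, parc), "VAN")  # earlier in order
  # all-negative values: least negative (signed argmax) wins
  connn <- -0.2 * (matrix(1, 16, 16) - diag(16)) + diag(16)
  connn[3, 5:6] <- connn[5:6, 3] <- -0.05        # DAN least negative
  expect_equal(assign_vertices(connn, 3L, parc), "DAN")
})

test_that("engagement profiles count assignments as percentages", {
  p <- engagement_profile(c("VAN", "VAN", "FPN", "VAN"))
  expect_equal(unname(p["VAN"]), 75)
  expect_equal(unname(p["FPN"]), 25)
  expect_equal(sum(p), 100)
  expect_equal(attr(p, "n_seed_vertices"), 4L)
  expect_equal(names(p), network_labels())
  u <- engagement_profile(network_labels())
  expect_equal(as.numeric(u), rep(12.5, 8))
  expect_error(engagement_profile(character(0)), "no vertex assignments")
  expect_error(engagement_profile(c("VAN", "Nope")), "unknown")
})

test_that("most_engaged takes the argmax with fixed-order tie-break", {
  p <- engagement_profile(c("VAN", "VAN", "FPN", "VAN"))
  expect_equal(most_engaged(p), "VAN")
  tie <- engagement_profile(c("VAN", "FPN", "VAN", "FPN"))
  expect_equal(most_engaged(tie), "VAN")
})

test_that("vectorized connectivity matches brute-force oracles", {
  for (seed in 1:10) {
    n <- with_seed(seed, sample(20:50, 1))
    conn <- random_connectome(n, seed)
    parc <- random_parcellation(n, seed + 50)
    ids <- sort(with_seed(seed + 99, sample.int(n, sample(2:8, 1))))
    expect_equal(seed_fc_map(conn, ids), oracle_seed_fc(conn, ids),
                 tolerance = 1e-12)
    v <- ids[1]
    expect_equal(vertex_network_fc(conn, v, parc),
                 oracle_vertex_network_fc(conn, v, parc),
                 tolerance = 1e-12)
    asg <- assign_vertices(conn, ids, parc)
    expect_identical(asg, oracle_assign(conn, ids, parc))
    expect_equal(unclass(engagement_profile(asg)), oracle_profile(asg),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("engagement is invariant to parcel relabeling within networks", {
  n <- 40
  conn <- random_connectome(n, 77)
  parc <- random_parcellation(n, 78)
  # split every parcel in two (odd/even vertices), keeping networks
  vp2 <- parc$vertex_parcel * 2L - (seq_len(n) %% 2L)
  pn2 <- setNames(rep(parc$parcel_network, each = 2),
                  as.character(rep(1:8, each = 2) * 2 - rep(c(1, 0), 8)))
  parc2 <- structure(list(vertex_parcel = vp2, parcel_network = pn2,
                          centers = NULL), class = "efnet_parcellation")
  ids <- 1:10
  expect_identical(assign_vertices(conn, ids, parc),
                   assign_vertices(conn, ids, parc2))
})
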
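# ROI-pair strength aggregation, dominance, graph construction and
# current-flow centralities.

toy_desc <- data.frame(
  measure = "identity",
  roi = c(1L, 1L, 2L, 2L, 3L, NA),
  band = c(1L, 2L, 1L, 3L, 2L, NA),
  task = c(1L, 1L, 2L, 1L, 2L, NA))

test_that("pair strengths sum chi-square mass over all contributing records", {
  rec <- data.frame(f1 = c(1, 2, 1, 1, 1),
                    f2 = c(3, 3, 4, 5, NA),
                    log = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                    chi2 = c(10, 20, 5, 7, 99))
  sm <- accumulate_strengths(rec, toy_desc, n_roi = 3, n_task = 5)
  expect_equal(sm$strength[1, 2], 35)    # 10 + 20 + 5 for pair (1, 2)
  expect_equal(sm$strength[2, 1], 35)    # symmetric
  expect_equal(sm$strength[1, 3], 7)
  expect_equal(diag(sm$strength), rep(0, 3))
  expect_equal(sm$n_skipped, 1)          # the singleton record
  # vertex strength and the handshake identity
  expect_equal(vertex_strength(sm, 1), 42)
  expect_equal(vertex_strength(sm, 3), 7)
  expect_equal(sum(vertex_strength(sm)),
               2 * sum(sm$strength[upper.tri(sm$strength)]))
  # chunked accumulation equals one-shot
  sm2 <- accumulate_strengths(rec[1:2, ], toy_desc, 3, 5)
  sm2 <- accumulate_strengths(rec[3:5, ], toy_desc, 3, 5, into = sm2)
  expect_equal(sm2$strength, sm$strength)
  expect_equal(sm2$band_acc, sm$band_acc)
})

test_that("aggregation matches a brute-force group-by on a full toy universe", {
  out <- generate_cohort(synthetic_config(n_subjects = 12, n_roi = 4,
                                          n_task = 2, seed = 15))
  s1 <- stage1_features(out$cohort)
  y <- unname(out$cohort$labels[, "anxiety"])
  sm <- roi_pair_strengths(out$cohort, "anxiety")

  full <- oracle_score_universe(s1, y)
  d <- describe_features(full$id, s1$descriptors)
  roi1 <- s1$descriptors$roi[d$f1]
  roi2 <- ifelse(is.na(d$f2), NA, s1$descriptors$roi[d$f2])
  ok <- !is.na(roi1) & !is.na(roi2) & roi1 != roi2
  want <- matrix(0, 4, 4)
  band_want <- array(0, c(4, 4, 4))
  lo <- pmin(roi1[ok], roi2[ok]); hi <- pmax(roi1[ok], roi2[ok])
  w <- full$chi2[ok]
  b1 <- s1$descriptors$band[d$f1[ok]]; b1[is.na(b1)] <- 4L
  b2 <- s1$descriptors$band[d$f2[ok]]; b2[is.na(b2)] <- 4L
  for (m in seq_along(lo)) {
    want[lo[m], hi[m]] <- want[lo[m], hi[m]] + w[m]
    want[hi[m], lo[m]] <- want[hi[m], lo[m]] + w[m]
    for (lev in unique(c(b1[m], b2[m]))) {
      band_want[lo[m], hi[m], lev] <- band_want[lo[m], hi[m], lev] + w[m]
      band_want[hi[m], lo[m], lev] <- band_want[hi[m], lo[m], lev] + w[m]
    }
  }
  expect_equal(sm$strength, want, tolerance = 1e-8)
  expect_equal(sm$band_acc, band_want, tolerance = 1e-8)
  # skipped records: singletons, aggregated-ROI constituents, same-ROI pairs
  expect_equal(sm$n_records, nrow(full))
  expect_equal(sm$n_skipped, sum(!ok))
})

test_that("dominant factors take the concrete-level argmax with fixed ties", {
  sm <- neurosym:::new_strength_matrix(3, 5)
  sm$band_acc[1, 2, ] <- c(12, 30, 3, 500)   # aggregated never competes
  sm$band_acc[2, 1, ] <- sm$band_acc[1, 2, ]
  expect_equal(dominant_factor(sm, pair = c(1, 2), factor = "band"), "alpha")
  sm$task_acc[1, 2, ] <- c(4, 4, 1, 0, 0, 9)  # tie between tasks 1 and 2
  expect_equal(dominant_factor(sm, pair = c(1, 2), factor = "task"), "1")
  expect_equal(dominant_factor(sm, pair = c(1, 3), factor = "band"),
               "undetermined")
  # vertex-level dominance pools the vertex's pairs
  sm$band_acc[1, 3, ] <- c(100, 0, 0, 0)
  sm$band_acc[3, 1, ] <- sm$band_acc[1, 3, ]
  expect_equal(dominant_factor(sm, vertex = 1, factor = "band"), "theta")
  # a single contributing record determines its pair outright
  rec <- data.frame(f1 = 1, f2 = 3, log = FALSE, chi2 = 2)
  one <- accumulate_strengths(rec, toy_desc, 3, 5)
  expect_equal(dominant_factor(one, pair = c(1, 2), factor = "band"),
               "theta")  # constituents have bands theta (f1) and theta (f3)
  expect_equal(dominant_factor(one, pair = c(1, 2), factor = "task"), "1")
})

test_that("graph edges follow the strength threshold monotonically", {
  sm <- toy_strength(4, list(list(1, 2, 150), list(2, 3, 90),
                             list(3, 4, 310)))
  g <- build_graph(sm, threshold = 100)
  expect_equal(igraph::ecount(g$graph), 2)
  expect_equal(igraph::vcount(g$graph), 4)
  expect_equal(sort(igraph::E(g$graph)$weight), c(150, 310))
  expect_equal(igraph::ecount(build_graph(sm, threshold = Inf)$graph), 0)
  expect_equal(igraph::ecount(build_graph(sm, threshold = 0)$graph), 3)
  counts <- vapply(c(0, 50, 100, 200, 400),
                   function(th) igraph::ecount(build_graph(sm, th)$graph),
                   0)
  expect_true(all(diff(counts) <= 0))
  # vertex-sum mode keys edges on endpoint strengths
  gv <- build_graph(sm, threshold = 395, mode = "vertex_sum")
  # vertex strengths: 150, 240, 400, 310; pairs with mass: sums 390/640/710
  expect_equal(igraph::ecount(gv$graph), 2)
})

test_that("current-flow centralities match the electrical oracle", {
  # path a - b - c with unit conductances
  sm <- toy_strength(3, list(list(1, 2, 1), list(2, 3, 1)))
  cent <- current_flow_centralities(build_graph(sm, threshold = 0))
  expect_equal(cent$betweenness, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(cent$closeness, c(2 / 3, 1, 2 / 3), tolerance = 1e-12)

  # triangle symmetry
  sm3 <- toy_strength(3, list(list(1, 2, 1), list(2, 3, 1), list(1, 3, 1)))
  cent3 <- current_flow_centralities(build_graph(sm3, threshold = 0))
  expect_equal(diff(range(cent3$closeness)), 0, tolerance = 1e-12)
  expect_equal(diff(range(cent3$betweenness)), 0, tolerance = 1e-12)

  # random weighted graphs against the dense per-pair solve
  set.seed(12)
  for (rep in 1:40) {
    nv <- sample(2:8, 1)
    W <- random_weighted_graph(nv)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    got <- current_flow_centralities(g)
    want <- oracle_current_flow(W)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-8)
    if (nv > 2)
      expect_equal(got$betweenness, want$betweenness, tolerance = 1e-8)
    expect_true(all(got$betweenness >= -1e-12 & got$betweenness <= 1 + 1e-12))
  }

  # disconnected graph: per-component values, singletons undefined
  smd <- toy_strength(5, list(list(1, 2, 1), list(3, 4, 2)))
  centd <- current_flow_centralities(build_graph(smd, threshold = 0))
  expect_true(is.na(centd$closeness[5]) && is.na(centd$betweenness[5]))
  expect_equal(centd$betweenness[1:4], rep(0, 4))  # 2-vertex components
  expect_equal(length(unique(centd$component)), 3)
})

test_that("hub tables and graph exports have the published shape", {
  sm <- toy_strength(6, list(list(1, 2, 120), list(2, 3, 180),
                             list(3, 4, 150), list(4, 5, 130),
                             list(5, 6, 170), list(1, 6, 110)))
  g <- build_graph(sm, threshold = 100)
  cent <- current_flow_centralities(g)
  hubs <- top_hubs(cent, n_top = 5)
  expect_equal(nrow(hubs), 10)
  expect_true(all(c("metric", "roi", "region", "closeness", "betweenness")
                  %in% names(hubs)))
  expect_true(all(diff(hubs$closeness[hubs$metric == "closeness"]) <= 0))
  ep <- tempfile(); gp <- tempfile()
  write_graph_files(g, ep, gp)
  el <- read.delim(ep)
  expect_equal(nrow(el), igraph::ecount(g$graph))
  expect_true(file.exists(gp))
})
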
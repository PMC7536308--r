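test_that("pairwise distances match the metric definitions", {
  X <- rbind(c(1, 1), c(1, 0), c(0, 1))
  D <- pairwise_distance(X, "cosine")
  expect_equal(diag(D), rep(0, 3))
  expect_equal(D, t(D))
  expect_equal(D[2, 3], 1)                     # orthogonal vectors
  expect_equal(D[1, 2], 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_error(pairwise_distance(rbind(c(0, 0), c(1, 0)), "cosine"), "zero-norm")

  E <- pairwise_distance(cbind(c(0, 3)), "euclidean")
  expect_equal(E[1, 2], 3)
})

test_that("lens functions follow their definitions", {
  # L-infinity centrality on 1-D points {0, 1, 3}
  D <- pairwise_distance(cbind(c(0, 1, 3)), "euclidean")
  expect_equal(lens_linf_centrality(D), c(3, 2, 3))
  expect_equal(lens_linf_centrality(matrix(0, 1, 1)), 0)
  D2 <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(lens_linf_centrality(D2), c(2, 2))

  # first-singular-vector projection of a rank-1 matrix (uncentred)
  sv <- lens_svd(rbind(c(1, 0), c(2, 0)), center = FALSE)
  expect_equal(abs(sv), c(1, 2))
  # identical rows share their lens value; row order permutes the lens
  X <- rbind(c(1, 2), c(3, 1), c(1, 2))
  lv <- lens_svd(X)
  expect_equal(lv[1], lv[3])
  perm <- c(2, 3, 1)
  expect_equal(lens_svd(X[perm, ]), lv[perm])
  expect_warning(lens_svd(rbind(c(1, 1), c(1, 1))), "identical")
})

test_that("the cover places overlapping closed intervals over the range", {
  lens <- cbind(c(0, 10), c(0, 10))
  bins <- build_cover(lens, num_intervals = 2, gain = 0.5)
  expect_length(bins, 4)
  # interval length R/(n - (n-1) g) = 10 / 1.5
  expect_equal(bins[[1]]$x_range, c(0, 20 / 3), tolerance = 1e-12)
  expect_equal(bins[[4]]$x_range, c(10 / 3, 10), tolerance = 1e-12)

  # n = 1: single interval = full range for any gain
  b1 <- build_cover(lens, 1, 0.3)
  expect_length(b1, 1)
  expect_equal(b1[[1]]$x_range, c(0, 10))
  expect_equal(b1[[1]]$members, 1:2)

  # 7 intervals at 60 % overlap in both dimensions: 49 bins
  expect_length(build_cover(lens, 7, 0.6), 49)

  expect_error(build_cover(lens, 0, 0.5), "num_intervals")
  expect_error(build_cover(lens, 2, 1.2), "gain")

  # cover property: every row lands in at least one bin
  set.seed(4)
  L <- cbind(rnorm(200), rnorm(200))
  bb <- build_cover(L, 5, 0.4)
  expect_setequal(sort(unique(unlist(lapply(bb, `[[`, "members")))), 1:200)
})

test_that("fixed-k bin clustering cuts exactly min(k, size) clusters", {
  X <- cbind(c(0, 0.1, 10, 10.1), 0)
  cl <- cluster_bin(1:4, k = 2, X = X, metric = "euclidean")
  expect_equal(sort(vapply(cl, paste, "", collapse = ",")),
               c("1,2", "3,4"))
  # more clusters requested than points: singletons
  cl2 <- cluster_bin(c(7, 9), k = 10, X = rbind(1, 1, 1, 1, 1, 1, 1, 5, 1, 9),
                     metric = "euclidean")
  expect_equal(cl2, list(7, 9))
  expect_equal(cluster_bin(integer(0), k = 3, X = X), list())
  # clusters partition the bin
  expect_setequal(unlist(cl), 1:4)
})

test_that("histogram-mode clustering cuts at the first linkage gap", {
  X <- cbind(c(0, 0.1, 10, 10.1), 0)
  cl <- cluster_bin(1:4, k = 5, X = X, metric = "euclidean",
                    mode = "histogram")
  expect_equal(sort(vapply(cl, paste, "", collapse = ",")),
               c("1,2", "3,4"))
  # no gap in the merge spectrum: one cluster survives
  X2 <- cbind(c(0, 1, 2, 3, 4), 0)
  cl2 <- cluster_bin(1:5, k = 3, X = X2, metric = "euclidean",
                     mode = "histogram")
  expect_length(cl2, 1)
  # a two-point bin is a single cluster (height equals diameter)
  expect_length(cluster_bin(1:2, k = 6, X = cbind(c(0, 1), 0),
                            metric = "euclidean", mode = "histogram"), 1)
})

test_that("graph assembly links exactly the intersecting clusters", {
  bin_clusters <- list(list(c(1, 2, 3)), list(c(3, 4), c(5, 6)),
                       list(c(6, 7)), list())
  g <- build_mapper_graph(bin_clusters, n_rows = 7)
  expect_equal(n_nodes(g), 4)
  expect_equal(g$node_bin, c(1, 2, 2, 3))
  expect_equal(g$edges$u, c(1, 3))
  expect_equal(g$edges$v, c(2, 4))
  expect_equal(g$edges$shared, list(3L, 6L))
  # conservation: node members cover exactly the clustered rows
  expect_setequal(unlist(g$nodes), 1:7)

  # disjoint clusters: no edge
  g2 <- build_mapper_graph(list(list(1:2), list(3:4)), n_rows = 4)
  expect_equal(nrow(g2$edges), 0)
})

test_that("edge shared sets equal member intersections on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    # random overlapping member sets over 40 rows, one bin per cluster
    nodes <- lapply(1:12, function(i) sort(sample(1:40, sample(2:8, 1))))
    g <- build_mapper_graph(lapply(nodes, list), n_rows = 40)
    expect_lte(n_nodes(g), 50)
    # brute force over all node pairs
    for (i in seq_len(n_nodes(g) - 1)) {
      for (j in (i + 1):n_nodes(g)) {
        inter <- intersect(g$nodes[[i]], g$nodes[[j]])
        row <- which(g$edges$u == i & g$edges$v == j)
        if (length(inter) == 0) {
          expect_length(row, 0)
        } else {
          expect_length(row, 1)
          expect_equal(g$edges$shared[[row]], sort(inter))
        }
      }
    }
    # no self edges
    expect_true(all(g$edges$u != g$edges$v))
  }
})

test_that("node enrichment averages and takes the tie-broken mode", {
  g <- build_mapper_graph(list(list(c(1, 2)), list(c(3, 4, 5)),
                               list(c(5, 6))), n_rows = 6)
  g <- enrich_nodes(g, c(0, 4000, 2, 2, 5, 5), "mean", name = "mean_time")
  expect_equal(g$attrs$mean_time[1], 2000)
  g <- enrich_nodes(g, c(9, 9, 2, 2, 5, 4), "majority", name = "maj")
  expect_equal(g$attrs$maj[2], 2)   # mode of {2, 2, 5}
  g2 <- enrich_nodes(g, c(1, 4, 1, 4, 1, 4), "majority", name = "tie")
  expect_equal(g2$attrs$tie[1], 1)  # tie {1, 4} resolves downward
})

test_that("full construction covers rows and degenerates gracefully", {
  set.seed(7)
  X <- cbind(rnorm(120), rnorm(120))
  g <- suppressMessages(build_mapper(X, mapper_config(
    metric = "euclidean", lens_pair = "raw2d", num_intervals = 4,
    gain = 0.5, clusters_per_bin = 4)))
  expect_setequal(sort(unique(unlist(g$nodes))), 1:120)

  # one interval, fixed single cluster: everything in one node
  g1 <- suppressMessages(build_mapper(X, mapper_config(
    metric = "euclidean", lens_pair = "raw2d", num_intervals = 1,
    gain = 0.5, clusters_per_bin = 1, cluster_mode = "fixed_k")))
  expect_equal(n_nodes(g1), 1)
  expect_equal(g1$nodes[[1]], 1:120)

  # raising the gain never loses edges
  cfg_lo <- mapper_config(metric = "euclidean", lens_pair = "raw2d",
                          num_intervals = 4, gain = 0.3, clusters_per_bin = 4)
  cfg_hi <- mapper_config(metric = "euclidean", lens_pair = "raw2d",
                          num_intervals = 4, gain = 0.6, clusters_per_bin = 4)
  e_lo <- nrow(suppressMessages(build_mapper(X, cfg_lo))$edges)
  e_hi <- nrow(suppressMessages(build_mapper(X, cfg_hi))$edges)
  expect_gte(e_hi, e_lo)
})

test_that("graph exports round-trip structure", {
  g <- build_mapper_graph(list(list(c(1, 2, 3)), list(c(3, 4))), n_rows = 4)
  g <- enrich_nodes(g, c(1, 2, 3, 4), "mean", name = "mean_time")
  jp <- file.path(tempdir(), "graph.json")
  write_mapper_json(g, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(nrow(back$nodes), 2)
  expect_equal(back$edges$u, 1)
  expect_equal(unlist(back$edges$shared), 3)

  gm <- file.path(tempdir(), "graph.graphml")
  write_mapper_graphml(g, gm, weights = 1.5)
  ig <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::vcount(ig), 2)
  expect_equal(igraph::ecount(ig), 1)
  expect_equal(igraph::E(ig)$weight, 1.5)
})
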
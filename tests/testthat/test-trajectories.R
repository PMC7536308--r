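test_that("edge weights follow their definitions", {
  g <- build_mapper_graph(list(list(c(1, 2, 3)), list(c(2, 3, 4)),
                               list(c(4, 5))), n_rows = 5)
  tw <- edge_time_weights(g, c(50, 100, 300, 0, 10))
  expect_equal(tw[1], 200)   # shared rows {2, 3}: mean(100, 300)
  expect_equal(tw[2], 0)     # shared row {4}
  # permuting extra rows' times leaves shared means unchanged
  tw2 <- edge_time_weights(g, c(999, 100, 300, 0, 999))
  expect_equal(tw, tw2)

  iw <- index_weights(g)
  expect_equal(iw, c(1, 1))
  g2 <- graph_from_edges(8, u = c(4, 2), v = c(7, 8))
  expect_equal(index_weights(g2), c(3, 6))
})

test_that("the spanning tree is minimal and deterministic", {
  # a path graph is its own tree
  gp <- graph_from_edges(4, 1:3, 2:4)
  tp <- minimum_spanning_tree(gp, c(1, 2, 3))
  expect_equal(nrow(tp$edges), 3)
  expect_equal(tp$total_weight, 6)

  # 4-cycle with one heavy edge drops exactly that edge
  gc <- graph_from_edges(4, c(1, 2, 3, 4), c(2, 3, 4, 1))
  tc <- minimum_spanning_tree(gc, c(1, 1, 1, 5))
  expect_equal(nrow(tc$edges), 3)
  expect_false(any(tc$edges$u == 4 | tc$edges$v == 4 & tc$edges$weight == 5))
  expect_equal(tc$total_weight, 3)

  # oracle equivalence on random graphs up to 8 nodes
  for (seed in 1:20) {
    g <- random_test_graph(sample(5:8, 1), 0.45, seed + 10)
    if (nrow(g$edges) == 0) next
    set.seed(seed)
    w <- sample(1:6, nrow(g$edges), replace = TRUE)
    tree <- minimum_spanning_tree(g, w)
    expect_equal(tree$total_weight,
                 enumerate_mst_weight(8, g$edges$u, g$edges$v, w))
    # spanning forest: n - (number of components) edges in total
    comp <- phenotraj:::edge_components(8, g$edges$u, g$edges$v)
    expect_equal(nrow(tree$edges), 8 - length(unique(comp)))
  }

  # deterministic tie-break: equal weights pick lexicographically first edges
  gt <- graph_from_edges(3, c(1, 1, 2), c(2, 3, 3))
  tt <- minimum_spanning_tree(gt, c(1, 1, 1))
  expect_equal(tt$edges$u, c(1, 1))
  expect_equal(tt$edges$v, c(2, 3))
})

test_that("root-to-leaf extraction yields one trajectory per leaf", {
  # star with early centre: one length-2 trajectory per leaf
  gs <- graph_from_edges(4, c(1, 1, 1), c(2, 3, 4))
  ts <- minimum_spanning_tree(gs, rep(1, 3))
  trs <- extract_trajectories(ts, mean_time = c(0, 5, 6, 7))
  expect_length(trs, 3)
  expect_true(all(vapply(trs, function(t) length(t$node_ids), 1L) == 2))
  expect_true(all(vapply(trs, function(t) t$node_ids[1], 1L) == 1))

  # path with earliest endpoint: single trajectory along the path
  gp <- graph_from_edges(3, c(1, 2), c(2, 3))
  tp <- minimum_spanning_tree(gp, c(1, 1))
  trp <- extract_trajectories(tp, mean_time = c(0, 1, 2))
  expect_length(trp, 1)
  expect_equal(trp[[1]]$node_ids, 1:3)

  # single node
  g1 <- graph_from_edges(1, integer(0), integer(0))
  t1 <- minimum_spanning_tree(g1, numeric(0))
  expect_length(extract_trajectories(t1, 0), 1)

  # trajectory count equals leaf count (root excluded) on random trees
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    parent <- c(0, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
    g <- graph_from_edges(n, parent[-1], 2:n)
    tr <- minimum_spanning_tree(g, rep(1, n - 1))
    mt <- runif(n)
    trajs <- extract_trajectories(tr, mt)
    deg <- tabulate(c(parent[-1], 2:n), nbins = n)
    root <- which(mt == min(mt))[1]
    leaves <- setdiff(which(deg == 1), root)
    expect_length(trajs, length(leaves))
  }
})

test_that("Jaccard similarity is the set overlap and assignment takes the argmax", {
  ti <- trajectory(c(41, 42, 43, 39, 40, 33, 34, 26, 27, 19), "individual",
                   subject = "i")
  td <- list(
    trajectory(c(41, 37, 30, 22, 15, 8, 1), "mined"),
    trajectory(c(41, 42, 43, 39, 32, 24, 17, 10, 3), "mined"),
    trajectory(c(41, 42, 43, 39, 40, 33, 34, 26, 19, 12, 5), "mined")
  )
  sims <- vapply(td, jaccard_similarity, numeric(1), B = ti)
  expect_equal(sims, c(0.0625, 4 / 15, 0.75), tolerance = 1e-12)
  asg <- assign_subjects(list(ti), td)
  expect_equal(asg$trajectory_id, 3)
  expect_equal(asg$jaccard, 0.75)

  # identity, disjointness, symmetry, multiplicity-blindness
  expect_equal(jaccard_similarity(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 2), c(3, 4)), 0)
  for (seed in 1:10) {
    set.seed(seed)
    a <- sample(1:12, 6); b <- sample(1:12, 4)
    expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
    expect_gte(jaccard_similarity(a, b), 0)
    expect_lte(jaccard_similarity(a, b), 1)
    expect_equal(jaccard_similarity(rep(a, 2), b), jaccard_similarity(a, b))
  }

  # forced and tied assignments
  one <- assign_subjects(list(ti), td[1])
  expect_equal(one$trajectory_id, 1)
  tie <- assign_subjects(list(trajectory(c(1, 2), "individual", subject = "s")),
                         list(trajectory(c(1, 3), "mined"),
                              trajectory(c(2, 3), "mined")))
  expect_equal(tie$trajectory_id, 1)
})

test_that("encounters resolve to the closest containing node", {
  # rows 1..4; node 1 = {1,2}, node 2 = {2,3}, node 3 = {4}
  g <- build_mapper_graph(list(list(c(1, 2)), list(c(2, 3)), list(4)),
                          n_rows = 4)
  X <- cbind(c(0, 0.1, 5, 9))
  D <- pairwise_distance(X, "euclidean")
  tab <- observation_table(
    subject_id = c("a", "a", "a", "b"),
    time_days = c(0, 10, 20, 0), label = c(0, 0, 1, 0),
    features = data.frame(x = X[, 1])
  )
  ind <- map_observations_to_nodes(g, tab, D)
  # row 2 sits in nodes 1 and 2; its only co-member in node 1 (row 1) is
  # nearer than the one in node 2 (row 3)
  expect_equal(ind[["a"]]$node_ids, c(1, 2))  # rows 1,2 -> node 1; row 3 -> node 2
  expect_equal(ind[["b"]]$node_ids, 3)

  # every subject with covered encounters gets exactly one assignment
  mined <- list(trajectory(c(1, 2), "mined"), trajectory(3, "mined"))
  asg <- assign_subjects(ind, mined)
  expect_equal(sort(asg$subject), c("a", "b"))
  expect_equal(asg$jaccard[asg$subject == "a"], 1)

  # an uncovered row is dropped with a warning
  g2 <- build_mapper_graph(list(list(c(1, 2)), list(c(2, 3))), n_rows = 4)
  expect_warning(map_observations_to_nodes(g2, tab, D), "covered by no node")
})

test_that("progression mining roots at the first observations and ends late", {
  # path 1-2-3-4-5 with a small early spur 6 hanging off node 2
  g <- graph_from_edges(6, c(1, 2, 3, 4, 2), c(2, 3, 4, 5, 6))
  g$nodes <- list(1:20, 21:30, 31:40, 41:50, 51:60, 61:62)
  g$n_rows <- 62
  time <- c(rep(0, 20), rep(10, 10), rep(20, 10), rep(30, 10), rep(40, 10),
            rep(1, 2))
  first <- seq_len(62) <= 20
  trajs <- suppressMessages(
    mine_trajectories(g, time = time, first = first, weights = "index"))
  # the early, tiny spur node 6 is not a progression endpoint
  expect_length(trajs, 1)
  expect_equal(trajs[[1]]$node_ids, 1:5)
  expect_equal(attr(trajs, "root"), 1)
})
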
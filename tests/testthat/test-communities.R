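test_that("modularity matches hand values and the definitional double sum", {
  gs <- oracle_graph_set()
  # two disjoint triangles split into the triangles: Q = 1/2
  expect_equal(modularity_q(gs$two_triangles, c(1, 1, 1, 2, 2, 2)), 0.5)
  # a single community always scores zero
  expect_equal(modularity_q(gs$two_triangles, rep(1, 6)), 0)
  expect_equal(modularity_q(gs$k5, rep(1, 5)), 0)
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 2, 3)), "edgeless")
  set.seed(61)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.6)
    A <- A + t(A)
    if (sum(A) == 0) next
    lb <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(A, lb), brute_modularity(A, lb),
                 tolerance = 1e-12)
  }
})

test_that("greedy detection recovers the exhaustive optimum on benchmarks", {
  for (nm in names(oracle_graph_set())) {
    A <- oracle_graph_set()[[nm]]
    part <- detect_communities(A)
    expect_equal(part$Q, brute_best_modularity(A), tolerance = 1e-12,
                 label = paste("optimum on", nm))
    expect_equal(part$Q, modularity_q(A, part$labels), tolerance = 1e-12)
  }
  # the two-clique benchmark splits exactly into its cliques
  p8 <- detect_communities(oracle_graph_set()$two_k4)
  expect_equal(p8$n_communities, 2L)
  expect_length(unique(p8$labels[1:4]), 1)
  expect_length(unique(p8$labels[5:8]), 1)
  expect_false(p8$labels[1] == p8$labels[5])
})

test_that("edge cases: edgeless graphs and a single edge", {
  p0 <- detect_communities(matrix(0, 5, 5))
  expect_equal(p0$labels, 1:5)
  expect_true(is.na(p0$Q))
  # one edge on two nodes: compare against the two candidate partitions
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  p2 <- detect_communities(A)
  qs <- c(modularity_q(A, c(1, 1)), modularity_q(A, c(1, 2)))
  expect_equal(p2$Q, max(qs))
})

test_that("detection never scores below the all-singletons partition", {
  set.seed(62)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
    A <- A + t(A)
    if (sum(A) == 0) next
    p <- detect_communities(A)
    expect_gte(p$Q, modularity_q(A, seq_len(n)))
  }
})

test_that("co-membership probabilities count shared labels", {
  # identical partitions: probabilities are 0/1 and groups reproduce them
  parts <- replicate(4, structure(list(labels = c(1, 1, 2, 2, 3)),
                                  class = "partition"), simplify = FALSE)
  cm <- co_membership(parts)
  expect_true(all(cm$P %in% c(0, 1)))
  expect_equal(cm$stable_groups, list(c(1, 2), c(3, 4), 5))
  # 7 of 10 windows together: exactly 0.7, inclusive at the threshold
  parts2 <- lapply(1:10, function(w) {
    lb <- if (w <= 7) c(1, 1) else c(1, 2)
    structure(list(labels = lb), class = "partition")
  })
  cm2 <- co_membership(parts2, threshold = 0.70)
  expect_equal(cm2$P[1, 2], 0.7)
  expect_equal(cm2$stable_groups, list(c(1, 2)))
  # random label streams against a direct pair count
  set.seed(63)
  parts3 <- lapply(1:12, function(w)
    structure(list(labels = sample(1:3, 6, replace = TRUE)),
              class = "partition"))
  cm3 <- co_membership(parts3)
  for (i in 1:5) for (j in (i + 1):6) {
    cnt <- mean(vapply(parts3, function(p)
      p$labels[i] == p$labels[j], logical(1)))
    expect_equal(cm3$P[i, j], cnt)
  }
  expect_equal(cm3$P, t(cm3$P))
  expect_true(all(diag(cm3$P) == 1))
})

test_that("thresholding at 1 yields groups consistent across all windows", {
  set.seed(64)
  parts <- lapply(1:8, function(w) {
    lb <- sample(1:2, 5, replace = TRUE)
    lb[2] <- lb[1]              # pin a pair that always shares a label
    structure(list(labels = lb), class = "partition")
  })
  cm <- co_membership(parts, threshold = 1)
  expect_true(any(vapply(cm$stable_groups, length, integer(1)) >= 2))
  for (g in cm$stable_groups) {
    if (length(g) < 2) next
    for (p in parts) expect_length(unique(p$labels[g]), 1)
  }
})

test_that("clique mode enforces the threshold on every internal pair", {
  parts <- lapply(1:10, function(w) {
    # 2-3 always together, 1-2 and 1-3 together only 5/10
    lb <- if (w <= 5) c(1, 1, 1) else c(2, 1, 1)
    structure(list(labels = lb), class = "partition")
  })
  cm <- co_membership(parts, threshold = 0.7, mode = "clique")
  for (g in cm$stable_groups) {
    if (length(g) < 2) next
    for (a in g) for (b in g) if (a != b)
      expect_gte(cm$P[a, b], 0.7 - 1e-12)
  }
})

test_that("window community series account for every neuron", {
  tr <- cached_trace("lattice16")
  parts <- window_partitions(tr, include_isolated = TRUE)
  cc <- community_count_series(parts)
  expect_equal(nrow(cc), length(tr$snapshots) + 1L)
  # pre-coupling pseudo-window: all singletons
  expect_equal(cc$n_communities[1], tr$config$N)
  expect_true(all(vapply(cc$sizes, sum, numeric(1)) == tr$config$N))
})

test_that("community detection depends only on the snapshots", {
  tr <- cached_trace("lattice16")
  ref <- window_partitions(tr)
  shuffled <- tr
  set.seed(65)
  shuffled$V <- tr$V[, sample(ncol(tr$V))]
  alt <- window_partitions(shuffled)
  expect_equal(lapply(ref, `[[`, "labels"), lapply(alt, `[[`, "labels"))
})

test_that("greedy optimizer agrees with an independent backend on benchmarks", {
  skip_if_not_installed("igraph")
  for (nm in c("two_triangles", "two_k4", "barbell")) {
    A <- oracle_graph_set()[[nm]]
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    ref <- igraph::cluster_fast_greedy(g)
    p <- detect_communities(A)
    expect_equal(p$Q, igraph::modularity(g, igraph::membership(ref)),
                 tolerance = 1e-9, label = nm)
  }
})

test_that("per-group synchronization delegates to the subset series", {
  tr <- cached_trace("lattice16")
  all_idx <- seq_len(tr$config$N)
  rep1 <- community_sync_report(tr, list(all_idx))
  expect_equal(rep1$group1, sync_series(tr))
  expect_warning(community_sync_report(tr, list(integer(0), c(1, 2))),
                 "empty")
  expect_error(community_sync_report(tr, list()), "non-empty")
})
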
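test_that("periodic distance uses the minimum image", {
  expect_equal(periodic_distance(c(3, 4), c(3, 4), 100), 0)
  expect_equal(periodic_distance(c(5, 0), c(95, 0), 100), 10)
  set.seed(31)
  for (rep in 1:25) {
    p <- runif(2, -30, 130)
    q <- runif(2, -30, 130)
    d <- periodic_distance(p, q, 100)
    expect_equal(d, periodic_distance(q, p, 100))
    expect_equal(d, brute_periodic_distance(p, q, 100), tolerance = 1e-10)
    expect_lte(d, 100 * sqrt(2) / 2 + 1e-9)
  }
})

test_that("neighborhoods are inclusive at the radius and exclude self", {
  pos <- rbind(c(0, 0), c(25, 0))    # exactly at R
  nb <- neighborhood(pos, R = 25, global_L = 100)
  expect_equal(nb$sets[[1]], 2L)
  expect_equal(nb$sets[[2]], 1L)
  expect_equal(nb$counts, c(1L, 1L))
  nb1 <- neighborhood(rbind(c(10, 10)), R = 25, global_L = 100)
  expect_equal(nb1$counts, 0L)
  expect_length(nb1$sets[[1]], 0)
})

test_that("neighborhoods match an all-pairs brute-force scan", {
  set.seed(32)
  for (rep in 1:10) {
    n <- 12
    pos <- matrix(runif(2 * n, 0, 100), n, 2)
    nb <- neighborhood(pos, R = 30, global_L = 100)
    for (i in seq_len(n)) {
      manual <- which(vapply(seq_len(n), function(j) {
        j != i && brute_periodic_distance(pos[i, ], pos[j, ], 100) <= 30
      }, logical(1)))
      expect_equal(nb$sets[[i]], manual)
    }
  }
})

test_that("position update follows the hand-evaluated attraction rule", {
  net <- structural_network(list(
    list(lower = c(0, 0), upper = c(100, 100)),
    list(lower = c(0, 0), upper = c(100, 100))), global_L = 100)
  pos <- rbind(c(0, 0), c(10, 0))
  pp <- plasticity_params(gamma = 1e-3, R = 25)
  out <- update_positions(pos, c(20, 20), pp, net)
  # displacement = gamma * V_i * V_j = 0.4, towards the partner
  expect_equal(out[1, ], c(0.4, 0), tolerance = 1e-12)
  expect_equal(out[2, ], c(9.6, 0), tolerance = 1e-12)
  # opposite-sign potentials repel
  out2 <- update_positions(pos, c(20, -20), pp, net)
  expect_equal(out2[1, ], c(100 - 0.4, 0), tolerance = 1e-12)  # wrapped
  expect_equal(out2[2, ], c(10.4, 0), tolerance = 1e-12)
})

test_that("degenerate updates leave positions unchanged", {
  net <- structural_network(rep(list(
    list(lower = c(0, 0), upper = c(100, 100))), 3), global_L = 100)
  pos <- rbind(c(1, 1), c(5, 5), c(5, 5))
  pp0 <- plasticity_params(gamma = 0, R = 25)
  expect_equal(update_positions(pos, c(10, 20, 30), pp0, net), pos)
  pp <- plasticity_params(gamma = 1e-3, R = 25)
  expect_equal(update_positions(pos, c(0, 0, 0), pp, net), pos)
  # coincident neighbours contribute no direction (and no NaN)
  out <- update_positions(rbind(c(5, 5), c(5, 5)), c(10, 10), pp, net)
  expect_true(all(is.finite(out)))
  expect_equal(out, rbind(c(5, 5), c(5, 5)))
})

test_that("update is equivariant under a global torus translation", {
  L <- 100
  net <- structural_network(rep(list(
    list(lower = c(0, 0), upper = c(L, L))), 4), global_L = L)
  set.seed(33)
  pos <- matrix(runif(8, 0, L), 4, 2)
  V <- runif(4, -70, 30)
  pp <- plasticity_params(gamma = 1e-4, R = 40)
  shift <- c(23.7, 71.2)
  a <- update_positions(pos, V, pp, net)
  b <- update_positions(wrap_position(sweep(pos, 2, shift, `+`),
                                      net$domains[[1]]), V, pp, net)
  # compare displaced results on the torus
  delta <- (b - sweep(a, 2, shift, `+`)) %% L
  delta <- pmin(delta, L - delta)
  expect_lt(max(abs(delta)), 1e-9)
})

test_that("equal positive potentials contract mutually neighbouring pairs", {
  L <- 100
  net <- structural_network(rep(list(
    list(lower = c(0, 0), upper = c(L, L))), 5), global_L = L)
  set.seed(34)
  for (rep in 1:5) {
    pos <- matrix(runif(10, 40, 60), 5, 2)   # one tight cluster
    pp <- plasticity_params(gamma = 1e-5, R = 40)
    out <- update_positions(pos, rep(30, 5), pp, net)
    for (i in 1:4) for (j in (i + 1):5) {
      expect_lte(periodic_distance(out[i, ], out[j, ], L),
                 periodic_distance(pos[i, ], pos[j, ], L) + 1e-12)
    }
  }
})

test_that("topology snapshots have Laplacian structure and coupling strengths", {
  pp <- plasticity_params(R = 25, epsilon = 18.82)
  # far apart: empty graph, zero strengths
  s0 <- adjacency_from_positions(rbind(c(0, 0), c(50, 50)), pp, 100)
  expect_equal(nrow(s0$edges), 0)
  expect_equal(s0$c, c(0, 0))
  expect_equal(snapshot_laplacian(s0), matrix(0, 2, 2))
  # two within range: textbook two-node Laplacian, c = epsilon
  s1 <- adjacency_from_positions(rbind(c(0, 0), c(10, 0)), pp, 100)
  expect_equal(snapshot_laplacian(s1),
               matrix(c(-1, 1, 1, -1), 2, 2))
  expect_equal(s1$c, c(18.82, 18.82))
  expect_equal(s1$degree, c(1L, 1L))
})

test_that("snapshot Laplacians of random configurations are valid", {
  set.seed(35)
  pp <- plasticity_params(R = 30)
  for (rep in 1:10) {
    pos <- matrix(runif(24, 0, 100), 12, 2)
    s <- adjacency_from_positions(pos, pp, 100)
    A <- snapshot_adjacency(s)
    Lap <- snapshot_laplacian(s)
    expect_equal(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_equal(max(abs(rowSums(Lap))), 0)
    expect_lte(max(eigen(Lap, symmetric = TRUE,
                         only.values = TRUE)$values), 1e-10)
  }
})

test_that("the structural mask vetoes edges without touching the strengths", {
  pp <- plasticity_params(R = 25, epsilon = 18.82)
  pos <- rbind(c(0, 0), c(10, 0))
  mask <- matrix(0, 2, 2)
  s <- adjacency_from_positions(pos, pp, 100, mask = mask)
  expect_equal(nrow(s$edges), 0)        # functional edge vetoed
  expect_equal(s$c, c(18.82, 18.82))    # neighborhood count is unmasked
  expect_equal(s$degree, c(0L, 0L))
})
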
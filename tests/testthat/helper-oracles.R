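# Independent brute-force oracles used across the suite.  These deliberately
# take the slow, obviously-correct route (image enumeration, double sums,
# exhaustive partition search) and never call the code paths they check.

# Box overlap on the torus by enumerating periodic images of the second box.
brute_overlap_pair <- function(d1, d2, L) {
  d <- length(d1$lower)
  shifts <- as.matrix(expand.grid(rep(list((-2:2) * L), d)))
  for (r in seq_len(nrow(shifts))) {
    hit <- TRUE
    for (ax in seq_len(d)) {
      lo2 <- d2$lower[ax] + shifts[r, ax]
      up2 <- d2$upper[ax] + shifts[r, ax]
      if (up2 < d1$lower[ax] - 1e-9 || lo2 > d1$upper[ax] + 1e-9) {
        hit <- FALSE
        break
      }
    }
    if (hit) return(1L)
  }
  0L
}

brute_overlap_matrix <- function(domains, L) {
  n <- length(domains)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ov[i, j] <- brute_overlap_pair(domains[[i]], domains[[j]], L)
  }
  ov
}

# Minimum-image distance by scanning all 5^d periodic images.
brute_periodic_distance <- function(p, q, L) {
  d <- length(p)
  shifts <- as.matrix(expand.grid(rep(list((-2:2) * L), d)))
  min(apply(shifts, 1, function(s) sqrt(sum((q + s - p)^2))))
}

# Modularity straight from the definitional double sum.
brute_modularity <- function(A, labels) {
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  }
  q / m2
}

# All set partitions of 1..n via restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(s, kmax) {
    i <- length(s) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- s
      return()
    }
    for (v in seq_len(kmax + 1L)) rec(c(s, v), max(kmax, v))
  }
  rec(integer(0), 0L)
  out
}

# Best achievable modularity by exhaustive search (n <= 8).
brute_best_modularity <- function(A) {
  best <- -Inf
  for (lb in all_partitions(nrow(A))) {
    q <- brute_modularity(A, lb)
    if (q > best) best <- q
  }
  best
}

# Graph connectivity by breadth-first search on a 0/1 adjacency matrix.
is_connected_graph <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(TRUE)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nbrs <- which(colSums(A[frontier, , drop = FALSE] != 0) > 0)
    frontier <- nbrs[!seen[nbrs]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

# A small named collection of <= 8-node benchmark graphs.
oracle_graph_set <- function() {
  two_triangles <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    two_triangles[e[1], e[2]] <- two_triangles[e[2], e[1]] <- 1
  two_k4 <- matrix(0, 8, 8)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    two_k4[i, j] <- 1
    two_k4[i + 4, j + 4] <- 1
  }
  path4 <- matrix(0, 4, 4)
  for (i in 1:3) path4[i, i + 1] <- path4[i + 1, i] <- 1
  cycle5 <- matrix(0, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    cycle5[i, j] <- cycle5[j, i] <- 1
  }
  star6 <- matrix(0, 6, 6)
  for (i in 2:6) star6[1, i] <- star6[i, 1] <- 1
  barbell <- two_triangles
  barbell[3, 4] <- barbell[4, 3] <- 1
  k5 <- matrix(1, 5, 5) - diag(5)
  list(two_triangles = two_triangles, two_k4 = two_k4, path4 = path4,
       cycle5 = cycle5, star6 = star6, barbell = barbell, k5 = k5)
}
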
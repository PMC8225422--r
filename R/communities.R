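# Community structure of the functional network: Newman modularity, a
# deterministic greedy agglomerative optimizer, per-window community
# series, co-membership probabilities and the stable (>= 70%) groups.

#' Newman modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` over communities `c`, with `e_c`
#' the number of within-community edges, `d_c` the total degree of the
#' community and `m` the edge count of the (undirected, unweighted) graph.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal; must contain at
#'   least one edge.
#' @param labels Community label per node (any atomic type).
#' @return The modularity `Q`, in `[-1, 1]`.
#' @export
modularity_q <- function(adjacency, labels) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  if (length(labels) != n) stop("'labels' must have one entry per node")
  m2 <- sum(A)
  if (m2 == 0) stop("modularity is undefined for an edgeless graph")
  deg <- rowSums(A)
  q <- 0
  for (lb in unique(labels)) {
    idx <- which(labels == lb)
    q <- q + sum(A[idx, idx]) / m2 - (sum(deg[idx]) / m2)^2
  }
  q
}

#' Greedy modularity-optimizing community detection
#'
#' Deterministic agglomerative optimizer: starting from singletons, the pair
#' of communities whose merge gives the largest modularity increase is
#' merged (ties broken towards the lexicographically lowest pair of
#' community roots, a community's root being its smallest member), until no
#' merge increases modularity.  Disconnected communities are never merged
#' (their merge gain is always negative).  An edgeless graph yields all
#' singletons.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param seed Unused; accepted so callers can treat all detection backends
#'   uniformly (this optimizer is fully deterministic).
#' @return An object of class `partition`: a list with `labels` (integer
#'   community ids, numbered by order of each community's smallest member),
#'   `Q` (the achieved modularity, `NA` for an edgeless graph) and
#'   `n_communities`.
#' @export
detect_communities <- function(adjacency, seed = NULL) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  deg <- rowSums(A)
  m2 <- sum(A)
  if (m2 == 0) {
    return(structure(list(labels = seq_len(n), Q = NA_real_,
                          n_communities = n),
                     class = "partition"))
  }
  e <- A / m2            # fraction of edge ends between community pairs
  a <- deg / m2
  active <- rep(TRUE, n)
  parent <- seq_len(n)
  repeat {
    best <- -Inf; bi <- 0L; bj <- 0L
    act <- which(active)
    for (ii in seq_along(act)) {
      i <- act[ii]
      for (jj in seq_along(act)) {
        if (jj <= ii) next
        j <- act[jj]
        if (e[i, j] <= 0) next
        dq <- 2 * (e[i, j] - a[i] * a[j])
        # strict improvement, lowest-(i, j) tie-break at equal gain
        if (dq > best + 1e-12) { best <- dq; bi <- i; bj <- j }
      }
    }
    if (best <= 1e-12) break
    i <- bi; j <- bj
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    e[i, i] <- e[i, i]     # diagonal already accumulated both halves
    a[i] <- a[i] + a[j]
    active[j] <- FALSE
    parent[parent == j] <- i
  }
  roots <- sort(unique(parent))
  labels <- match(parent, roots)
  Q <- modularity_q(A, labels)
  structure(list(labels = labels, Q = Q,
                 n_communities = length(roots)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d communities, Q = %s\n", x$n_communities,
              format(x$Q, digits = 4)))
  invisible(x)
}

#' Community partitions of every fixed-topology window
#'
#' Runs [detect_communities()] on the coupling matrix of each snapshot of a
#' trace.  Optionally prepends the isolated pre-coupling phase as a
#' pseudo-window in which every neuron is its own community.
#'
#' @param trace A [run_simulation()] trace.
#' @param include_isolated Prepend the `[0, t_couple)` all-singletons
#'   pseudo-window (default `FALSE`).
#' @return A list of `partition` objects, each carrying `t_start`/`t_end`.
#' @export
window_partitions <- function(trace, include_isolated = FALSE) {
  parts <- lapply(trace$snapshots, function(s) {
    p <- detect_communities(snapshot_adjacency(s))
    p$t_start <- s$t_start; p$t_end <- s$t_end
    p
  })
  if (include_isolated) {
    p0 <- structure(list(labels = seq_len(trace$config$N), Q = NA_real_,
                         n_communities = trace$config$N,
                         t_start = 0, t_end = trace$config$t_couple),
                    class = "partition")
    parts <- c(list(p0), parts)
  }
  parts
}

#' Community count and size series
#'
#' @param partitions A list of `partition` objects (see
#'   [window_partitions()]).
#' @return A data frame with `t_start`, `t_end`, `n_communities`, `Q`, and a
#'   list-column `sizes` (community size multisets; each sums to N).
#' @export
community_count_series <- function(partitions) {
  out <- data.frame(
    t_start = vapply(partitions, function(p) p$t_start %||% NA_real_,
                     numeric(1)),
    t_end = vapply(partitions, function(p) p$t_end %||% NA_real_,
                   numeric(1)),
    n_communities = vapply(partitions, `[[`, numeric(1), "n_communities"),
    Q = vapply(partitions, `[[`, numeric(1), "Q"))
  out$sizes <- lapply(partitions, function(p)
    sort(as.integer(table(p$labels)), decreasing = TRUE))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Co-membership probabilities and stable communities
#'
#' `P[i, j]` is the fraction of windows in which neurons `i` and `j` were
#' assigned the same community label.  The stable groups are the connected
#' components of the graph whose edges are the pairs with
#' `P >= threshold` (inclusive); `mode = "clique"` instead grows groups
#' greedily so that every internal pair meets the threshold.
#'
#' @param partitions A list of `partition` objects over the windows of
#'   interest (typically the coupled phase only).
#' @param threshold Co-membership probability threshold, default 0.70.
#' @param mode `"components"` (default) or `"clique"`.
#' @return An object of class `co_membership`: list with `P` (N x N
#'   symmetric matrix, unit diagonal), `threshold` and `stable_groups`
#'   (list of integer vectors).
#' @export
co_membership <- function(partitions, threshold = 0.70,
                          mode = c("components", "clique")) {
  mode <- match.arg(mode)
  if (length(partitions) < 1L) stop("need at least one partition")
  n <- length(partitions[[1]]$labels)
  P <- matrix(0, n, n)
  for (p in partitions) {
    if (length(p$labels) != n) stop("partitions have inconsistent sizes")
    same <- outer(p$labels, p$labels, `==`)
    P <- P + same
  }
  P <- P / length(partitions)
  diag(P) <- 1
  G <- P >= threshold - 1e-12
  diag(G) <- FALSE
  groups <- if (mode == "components") .components(G) else .greedy_cliques(G)
  structure(list(P = P, threshold = threshold, stable_groups = groups),
            class = "co_membership")
}

# Connected components of a logical adjacency matrix, by breadth-first
# search; singletons are kept as their own groups.
.components <- function(G) {
  n <- nrow(G)
  seen <- rep(FALSE, n)
  groups <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- s; seen[s] <- TRUE; frontier <- s
    while (length(frontier)) {
      nbrs <- which(colSums(G[frontier, , drop = FALSE]) > 0)
      nxt <- nbrs[!seen[nbrs]]
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    groups[[length(groups) + 1L]] <- sort(comp)
  }
  groups
}

# Greedy all-pairs grouping: scan nodes in index order, add a node to the
# first group whose every member it matches, else start a new group.
.greedy_cliques <- function(G) {
  n <- nrow(G)
  groups <- list()
  for (v in seq_len(n)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(G[v, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], v); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- v
  }
  groups
}

#' @export
print.co_membership <- function(x, ...) {
  cat(sprintf("co_membership: %d neurons, threshold %.2f, %d stable groups\n",
              nrow(x$P), x$threshold, length(x$stable_groups)))
  invisible(x)
}

#' Synchronization series of the stable communities
#'
#' Delegates to [sync_series()] for each stable group; empty groups are
#' skipped with a warning.
#'
#' @param trace A [run_simulation()] trace.
#' @param groups List of integer index vectors (e.g.
#'   `co_membership(...)$stable_groups`).
#' @return A named list of [sync_series()] data frames, one per group.
#' @export
community_sync_report <- function(trace, groups) {
  if (length(groups) < 1L) stop("'groups' must be non-empty")
  out <- list()
  for (g in seq_along(groups)) {
    if (length(groups[[g]]) == 0L) {
      warning(sprintf("group %d is empty; skipped", g))
      next
    }
    out[[sprintf("group%d", g)]] <- sync_series(trace, groups[[g]])
  }
  out
}
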
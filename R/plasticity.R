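# Potential-driven motion of the position vectors and the resulting
# functional topology: neighborhoods, threshold adjacency, graph Laplacian
# and per-neuron coupling strengths.

#' Plasticity-rule parameters
#'
#' @param gamma Gain of the position update (lattice units per mV^2 per
#'   update).  If too large the displacement exceeds the interaction radius
#'   and no groups can form; default 6e-7.
#' @param R Interaction radius (lattice units) for both the neighborhood
#'   sets and the functional adjacency threshold; default 25.
#' @param epsilon Coupling-force scale: each neuron couples with strength
#'   `epsilon / N_eta_i` where `N_eta_i` is its neighborhood size;
#'   default 18.82.
#' @param update_period Time between position/topology updates (ms); the
#'   topology is frozen in between, which defines the fixed-topology windows
#'   analysed by [window_report()].  Default 1 ms.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(gamma = 6e-7, R = 25, epsilon = 18.82,
                              update_period = 1) {
  if (!is.numeric(R) || R <= 0) stop("'R' must be positive")
  if (!is.numeric(epsilon) || epsilon < 0) stop("'epsilon' must be >= 0")
  if (!is.numeric(gamma) || !is.finite(gamma) || gamma < 0)
    stop("'gamma' must be a finite non-negative scalar")
  if (!is.numeric(update_period) || update_period <= 0)
    stop("'update_period' must be positive")
  structure(list(gamma = gamma, R = R, epsilon = epsilon,
                 update_period = update_period),
            class = "plasticity_params")
}

#' Minimum-image distance on the global torus
#'
#' Euclidean distance between points of the periodic plane, measured to the
#' nearest periodic image; never exceeds `global_L * sqrt(d) / 2`.
#'
#' @param p,q Numeric vectors (single points) or matrices with one point per
#'   row.
#' @param global_L Side length of the periodic plane.
#' @return Distance(s); a scalar for vector input, a vector for row-wise
#'   matrix input.
#' @export
periodic_distance <- function(p, q, global_L) {
  dd <- .min_image(q - p, global_L)
  if (is.matrix(dd)) sqrt(rowSums(dd^2)) else sqrt(sum(dd^2))
}

# Componentwise minimum-image displacement on a torus of side L.
.min_image <- function(delta, L) delta - L * round(delta / L)

# All-pairs minimum-image distance matrix for an N x d position matrix.
.pairwise_periodic <- function(positions, L) {
  n <- nrow(positions)
  D2 <- matrix(0, n, n)
  for (ax in seq_len(ncol(positions))) {
    dx <- .min_image(outer(positions[, ax], positions[, ax], `-`), L)
    D2 <- D2 + dx^2
  }
  sqrt(D2)
}

#' Interaction neighborhoods
#'
#' The neighborhood of neuron `i` is the set of other neurons whose position
#' lies within the interaction radius `R` (boundary inclusive) under the
#' minimum-image metric.  The neuron itself is excluded: its own term would
#' carry no direction and would only inflate the coupling denominator.
#'
#' @param positions N x d matrix of position vectors.
#' @param R Interaction radius.
#' @param global_L Side length of the periodic plane.
#' @return A list with `sets` (list of integer vectors) and `counts`
#'   (integer vector of neighborhood sizes `N_eta_i`).
#' @export
neighborhood <- function(positions, R, global_L) {
  positions <- as.matrix(positions)
  D <- .pairwise_periodic(positions, global_L)
  n <- nrow(positions)
  within <- D <= R + 1e-12
  diag(within) <- FALSE
  sets <- lapply(seq_len(n), function(i) which(within[i, ]))
  list(sets = sets, counts = vapply(sets, length, integer(1)))
}

#' Move the position vectors according to the membrane potentials
#'
#' One step of the structural-plasticity rule: each neuron's position is
#' displaced by `gamma` times the sum, over its neighborhood, of the
#' minimum-image unit vector towards the neighbour scaled by the product of
#' the two membrane potentials.  Same-sign potentials attract, opposite
#' signs repel; coincident positions contribute nothing.  The result is
#' wrapped back into each neuron's own domain, which is what keeps the
#' emergent functional network confined to the fixed structural wiring.
#'
#' @param positions N x d matrix of current positions (global coordinates).
#' @param V Length-N vector of membrane potentials (mV).
#' @param params A [plasticity_params()] object.
#' @param network The [structural_network()] providing each neuron's domain
#'   and the global plane.
#' @param mode `"pairwise"` (default) applies the per-pair product
#'   `V_i * V_j` inside the sum; `"prefactor"` applies the alternative
#'   global-prefactor reading `V_i * sum_j V_j` outside the sum of unit
#'   vectors.
#' @return The updated N x d position matrix.
#' @export
update_positions <- function(positions, V, params, network,
                             mode = c("pairwise", "prefactor")) {
  mode <- match.arg(mode)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (length(V) != n) stop("'V' must have one entry per neuron")
  L <- network$global_L
  nb <- neighborhood(positions, params$R, L)
  out <- positions
  for (i in seq_len(n)) {
    js <- nb$sets[[i]]
    if (length(js) == 0L) next
    delta <- .min_image(positions[js, , drop = FALSE] -
                          matrix(positions[i, ], length(js),
                                 ncol(positions), byrow = TRUE), L)
    len <- sqrt(rowSums(delta^2))
    ok <- len > 0
    if (!any(ok)) next
    uhat <- delta[ok, , drop = FALSE] / len[ok]
    disp <- if (mode == "pairwise") {
      params$gamma * colSums(uhat * (V[i] * V[js][ok]))
    } else {
      params$gamma * V[i] * sum(V[js]) * colSums(uhat)
    }
    out[i, ] <- wrap_position(positions[i, ] + disp, network$domains[[i]])
  }
  out
}

#' Functional topology from the position vectors
#'
#' Thresholds the minimum-image distances at the interaction radius to get
#' the 0/1 coupling matrix, optionally masked by the structural overlap
#' graph (an edge can only be active where the physical wiring allows one),
#' and assembles the graph Laplacian `A - D` together with the per-neuron
#' coupling strengths `epsilon / N_eta_i` (zero for neurons with an empty
#' neighborhood).
#'
#' @param positions N x d matrix of positions.
#' @param params A [plasticity_params()] object (`R` and `epsilon` are used).
#' @param global_L Side length of the periodic plane.
#' @param mask Optional symmetric 0/1 matrix (e.g. the structural overlap
#'   graph); `NULL` disables masking.
#' @param t_start,t_end Validity window of the snapshot (ms).
#' @return An object of class `topology_snapshot` with elements `edges`
#'   (two-column matrix of 1-based index pairs, `i < j`), `degree`, `c`
#'   (coupling strengths), `n`, `t_start`, `t_end`.  Use
#'   [snapshot_adjacency()] and [snapshot_laplacian()] for the dense
#'   matrices.
#' @export
adjacency_from_positions <- function(positions, params, global_L,
                                     mask = NULL, t_start = NA_real_,
                                     t_end = NA_real_) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  D <- .pairwise_periodic(positions, global_L)
  A <- (D <= params$R + 1e-12) * 1L
  diag(A) <- 0L
  nb_counts <- as.integer(rowSums(A))   # unmasked neighborhood sizes
  if (!is.null(mask)) {
    if (!all(dim(mask) == c(n, n))) stop("'mask' has wrong dimensions")
    A <- A * (mask != 0)
  }
  cvec <- ifelse(nb_counts > 0, params$epsilon / nb_counts, 0)
  ij <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  structure(list(edges = unname(ij), degree = as.integer(rowSums(A)),
                 c = cvec, n = n, t_start = t_start, t_end = t_end),
            class = "topology_snapshot")
}

#' @export
print.topology_snapshot <- function(x, ...) {
  cat(sprintf("topology_snapshot [%g, %g] ms: %d neurons, %d edges\n",
              x$t_start, x$t_end, x$n, nrow(x$edges)))
  invisible(x)
}

#' Dense coupling matrix of a snapshot
#'
#' @param snapshot A `topology_snapshot`.
#' @return The symmetric 0/1 coupling matrix with zero diagonal.
#' @export
snapshot_adjacency <- function(snapshot) {
  A <- matrix(0, snapshot$n, snapshot$n)
  if (nrow(snapshot$edges)) {
    A[snapshot$edges] <- 1
    A[snapshot$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

#' Graph Laplacian of a snapshot
#'
#' The network-matrix convention `A = coupling matrix - degree diagonal`:
#' zero row sums, negative semidefinite, diagonal `-k_i`.
#'
#' @param snapshot A `topology_snapshot`.
#' @return The N x N Laplacian matrix.
#' @export
snapshot_laplacian <- function(snapshot) {
  A <- snapshot_adjacency(snapshot)
  A - diag(rowSums(A), nrow(A))
}
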
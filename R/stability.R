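# Per-window exponential-synchronization criterion: the second-largest
# Laplacian eigenvalue, the symmetrized-Jacobian matrix Psi, Sylvester's
# negative-definiteness test and the search for the critical coupling
# parameter d.

# Inner-coupling selector: neurons interact through the membrane potential
# only, so d enters Psi only in its (1,1) entry.
.GAMMA_SEL <- diag(c(1, 0, 0, 0))

#' Second-largest eigenvalue of the network Laplacian
#'
#' For the Laplacian convention `A = coupling matrix - degree diagonal` the
#' largest eigenvalue is always 0; the second-largest is strictly negative
#' iff the graph is connected (has a spanning tree) and equals 0 when it is
#' not -- in particular it is exactly 0 for the edgeless isolated phase.
#'
#' @param A Symmetric Laplacian matrix with zero row sums.
#' @return The second-largest eigenvalue (0 for a 1x1 matrix).
#' @export
lambda2_max <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8)
    stop("'A' must be a symmetric square matrix")
  if (max(abs(rowSums(A))) > 1e-6 * max(1, max(abs(A))))
    stop("'A' must have zero row sums (Laplacian convention)")
  if (nrow(A) == 1L) return(0)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev[2]
}

#' The Psi matrix of the synchronization inequality
#'
#' `Psi = (Df + d * Gamma)' G + G (Df + d * Gamma)` with `Df` the analytic
#' single-neuron Jacobian at `state` and `Gamma = diag(1, 0, 0, 0)` the
#' membrane-potential coupling selector; symmetric by construction, with the
#' parameter `d` entering only the (1,1) entry when `G` is diagonal.
#'
#' @param state Numeric vector `c(V, n, m, h)` (the isolated reference
#'   trajectory sample at which the certificate is evaluated).
#' @param d Coupling parameter (scalar).
#' @param params An [hh_params()] object.
#' @param G Symmetric positive-definite weight matrix; identity by default.
#' @return A symmetric 4x4 matrix.
#' @export
psi_matrix <- function(state, d, params = hh_params(), G = diag(4)) {
  Jd <- hh_jacobian(state, params) + d * .GAMMA_SEL
  M <- t(Jd) %*% G + G %*% Jd
  M <- (M + t(M)) / 2
  dimnames(M) <- list(c("V", "n", "m", "h"), c("V", "n", "m", "h"))
  M
}

#' Sylvester test for negative definiteness
#'
#' A symmetric matrix is negative definite iff its leading principal minors
#' alternate in sign starting negative: `(-1)^k det(M[1:k, 1:k]) > 0` for
#' every `k`.
#'
#' @param M A symmetric numeric matrix.
#' @return `TRUE` iff `M` is negative definite.
#' @export
sylvester_negative_definite <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) ||
      max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop("'M' must be symmetric")
  for (k in seq_len(nrow(M))) {
    if ((-1)^k * det(M[1:k, 1:k, drop = FALSE]) <= 0) return(FALSE)
  }
  TRUE
}

#' Largest coupling parameter certifying negative definiteness
#'
#' Finds `sup { d : Psi(state, d, G) is negative definite }` by bracketing
#' and bisection (relative tolerance `tol`).  Because `d` only shifts the
#' (1,1) entry, negative definiteness for some `d` requires the trailing
#' 3x3 block of the symmetrized Jacobian to be negative definite on its
#' own; if no `d` in the search range certifies, the state is reported as
#' not certifiable (`NA` with a `reason` attribute) rather than a number.
#'
#' @inheritParams psi_matrix
#' @param tol Relative bisection tolerance (default 1e-6).
#' @param d_min Most negative `d` tried while bracketing (default -1e12).
#' @return The critical `d` (possibly positive), or `NA_real_` with
#'   attribute `reason = "not certifiable at this state"`.
#' @export
critical_d <- function(state, params = hh_params(), G = diag(4),
                       tol = 1e-6, d_min = -1e12) {
  critical_d_matrix(hh_jacobian(state, params), G = G, tol = tol,
                    d_min = d_min)
}

#' @rdname critical_d
#' @param Df A Jacobian matrix (any dimension matching `G` and `Gamma`).
#' @param Gamma Inner-coupling selector matrix; defaults to the
#'   membrane-potential selector `diag(1, 0, ..., 0)`.
#' @details `critical_d_matrix()` performs the same search directly on a
#'   supplied Jacobian, which is also how degenerate cases (e.g. a zero
#'   Jacobian, whose trailing block can never be negative definite) are
#'   reported as not certifiable.  Because `Gamma` only adds `d` on (part
#'   of) the diagonal, negative definiteness is monotone in `d`: certified
#'   at some `d` implies certified at every smaller `d`, so bracketing plus
#'   bisection is exact up to the tolerance.
#' @export
critical_d_matrix <- function(Df, G = diag(nrow(Df)), Gamma = NULL,
                              tol = 1e-6, d_min = -1e12) {
  n <- nrow(Df)
  if (is.null(Gamma)) Gamma <- diag(c(1, rep(0, n - 1)))
  nd <- function(d) {
    Jd <- Df + d * Gamma
    M <- t(Jd) %*% G + G %*% Jd
    sylvester_negative_definite((M + t(M)) / 2)
  }
  d_lo <- -1
  while (!nd(d_lo) && d_lo > d_min) d_lo <- d_lo * 10
  if (!nd(d_lo)) {
    out <- NA_real_
    attr(out, "reason") <- "not certifiable at this state"
    return(out)
  }
  d_hi <- max(1, abs(d_lo))
  while (nd(d_hi) && d_hi < 1e15) d_hi <- d_hi * 10
  if (nd(d_hi)) stop("failed to bracket the loss of negative definiteness")
  while (d_hi - d_lo > tol * max(1, abs(d_lo))) {
    mid <- (d_lo + d_hi) / 2
    if (nd(mid)) d_lo <- mid else d_hi <- mid
  }
  d_lo
}

#' Per-window synchronization-stability report
#'
#' For every fixed-topology window of a trace: the second-largest Laplacian
#' eigenvalue and whether the exponential-synchronization condition
#' `lambda2_max <= d_bar < 0` holds.  `d_bar` may be any constant close to
#' 0 from below; windows with a disconnected functional graph
#' (`lambda2_max = 0`) can never satisfy it.
#'
#' @param trace A [run_simulation()] trace.
#' @param d_bar Negative threshold constant (default `-1e-3`).
#' @return A data frame with columns `t_start`, `t_end`, `lambda2_max`,
#'   `d_bar`, `exponential`.
#' @export
window_report <- function(trace, d_bar = -1e-3) {
  if (!is.numeric(d_bar) || d_bar >= 0) stop("'d_bar' must be negative")
  lam <- vapply(trace$snapshots,
                function(s) lambda2_max(snapshot_laplacian(s)), numeric(1))
  data.frame(
    t_start = vapply(trace$snapshots, `[[`, numeric(1), "t_start"),
    t_end = vapply(trace$snapshots, `[[`, numeric(1), "t_end"),
    lambda2_max = lam,
    d_bar = d_bar,
    exponential = lam <= d_bar)
}
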
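# Integration of the full coupled network with the two-phase protocol:
# isolated neurons first, then the evolving coupled network, integrated with
# an adaptive Dormand-Prince Runge-Kutta pair over fixed-topology windows.

#' Simulation configuration
#'
#' Assembles and validates everything a run needs.  Defaults reproduce the
#' reference scenario: 64 neurons on an 8x8 lattice structural network over
#' a periodic plane of side 100, isolated on `[0, 400)` ms and coupled on
#' `[400, 3000]` ms.
#'
#' @param N Number of neurons (default 64).  Must be a perfect square when
#'   the lattice structural network is used.
#' @param t_end End time (ms, default 3000).
#' @param t_couple Time at which coupling switches on (ms, default 400);
#'   must satisfy `0 < t_couple < t_end`.
#' @param output_dt Output sampling interval (ms, default 0.1); decoupled
#'   from the adaptive internal step.
#' @param hh An [hh_params()] object.
#' @param plasticity A [plasticity_params()] object.
#' @param network A [structural_network()]; by default the lattice built
#'   from `N`, `global_L` and `overlap_fraction`.
#' @param global_L Side of the global periodic plane (used when `network`
#'   is not supplied).
#' @param overlap_fraction Lattice domain elongation (see [build_lattice()]).
#' @param rtol,atol Relative/absolute integrator tolerances.
#' @param seed Integer seed; every random draw of the run (initial
#'   potentials, position jitter) derives from it.
#' @param mask_structural If `TRUE` (default) functional edges are masked by
#'   the structural overlap graph, making the fixed structural network a
#'   hard constraint; `FALSE` recovers the purely emergent behaviour.
#' @param update_mode Attraction-rule reading, see [update_positions()].
#' @param init_mode `"limit_cycle"` (default) starts every neuron on the
#'   isolated neuron's spiking limit cycle at an independent random phase,
#'   so the isolated neurons show distinct ongoing behaviour from `t = 0`
#'   and the membrane potential stays inside the spiking envelope;
#'   `"uniform"` draws initial potentials from `V_init` with gates at their
#'   voltage-clamped steady state (this carries an initialisation transient
#'   whose first spike overshoots the steady spiking peak).
#' @param V_init Range (mV) of the uniform initial membrane potentials
#'   (used by `init_mode = "uniform"`, and as fallback when the isolated
#'   neuron does not spike); default `c(-70, -50)`.
#' @param jitter_frac Initial positions are the domain centers plus uniform
#'   jitter of this fraction of the domain side per axis.  The default 1
#'   spreads positions uniformly over their whole domain, so edge make/break
#'   events (the plasticity under study) occur from coupling onset; small
#'   values pin positions near the centers, which freezes the functional
#'   topology for an initial drift period.
#' @param Iext_jitter Optional fractional jitter of the per-neuron drive
#'   current (default 0, i.e. identical drive for all neurons).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(N = 64, t_end = 3000, t_couple = 400,
                              output_dt = 0.1,
                              hh = hh_params(),
                              plasticity = plasticity_params(),
                              network = NULL,
                              global_L = 100, overlap_fraction = 0.25,
                              rtol = 1e-6, atol = 1e-8,
                              seed = 1L,
                              mask_structural = TRUE,
                              update_mode = "pairwise",
                              init_mode = c("limit_cycle", "uniform"),
                              V_init = c(-70, -50),
                              jitter_frac = 1,
                              Iext_jitter = 0) {
  if (!(t_couple > 0 && t_couple < t_end))
    stop("need 0 < t_couple < t_end")
  if (N < 1) stop("'N' must be >= 1")
  if (is.null(network)) {
    network <- build_lattice(N, global_L = global_L,
                             overlap_fraction = overlap_fraction)
  }
  if (length(network$domains) != N)
    stop("'network' must have one domain per neuron")
  stopifnot(inherits(hh, "hh_params"), inherits(plasticity,
                                                "plasticity_params"))
  structure(list(N = as.integer(N), t_end = t_end, t_couple = t_couple,
                 output_dt = output_dt, hh = hh, plasticity = plasticity,
                 network = network, rtol = rtol, atol = atol,
                 seed = as.integer(seed),
                 mask_structural = isTRUE(mask_structural),
                 update_mode = update_mode,
                 init_mode = match.arg(init_mode),
                 V_init = V_init, jitter_frac = jitter_frac,
                 Iext_jitter = Iext_jitter),
            class = "simulation_config")
}

# Push the parameter block of the compiled right-hand side.
.set_engine_params <- function(N, hh, Iext, cvec, lap) {
  pv <- c(N, hh$gNa, hh$gK, hh$gL, hh$ENa, hh$EK, hh$EL, hh$CM, hh$Vrest,
          Iext, cvec, as.numeric(lap))
  invisible(.Call("hhnet_set_params", pv, PACKAGE = "plastinet"))
}

.integrate_block <- function(y0, times, config) {
  out <- deSolve::ode(y = y0, times = times, func = "hhnet_derivs",
                      parms = NULL, dllname = "plastinet", initfunc = NULL,
                      method = deSolve::rkMethod("rk45dp7"),
                      rtol = config$rtol, atol = config$atol,
                      hini = 1e-4, hmax = config$output_dt,
                      maxsteps = 5e5)
  istate <- attr(out, "istate")
  if ((!is.null(istate) && istate[1] < 0) || any(!is.finite(out)))
    stop("integrator failed (non-finite state or step-size breakdown)")
  out
}

# Clip the gate block of a state vector to [0, 1]; adaptive steppers can
# overshoot the invariant region by a rounding-level amount.
.clamp_gates <- function(y, N) {
  y[(N + 1):(4 * N)] <- pmin(pmax(y[(N + 1):(4 * N)], 0), 1)
  y
}

# One period of the isolated neuron's spiking limit cycle: burn in a single
# neuron for 150 ms, then sample the states between the last two upward
# crossings of -20 mV.  Returns NULL when the neuron does not spike.
.reference_cycle <- function(config) {
  hh <- config$hh
  g0 <- hh_steady_state(hh$Vrest, hh)
  y <- c(hh$Vrest, g0$n, g0$m, g0$h)
  .set_engine_params(1L, hh, hh$Iext, 0, matrix(0, 1, 1))
  tt <- seq(0, 150, by = 0.01)
  out <- .integrate_block(y, tt, config)
  V <- out[, 2]
  up <- which(V[-1] >= -20 & V[-length(V)] < -20)
  up <- up[tt[up] > 75]                 # past the burn-in transient
  if (length(up) < 2) return(NULL)
  i0 <- up[length(up) - 1L]; i1 <- up[length(up)]
  out[i0:(i1 - 1L), -1, drop = FALSE]
}

#' Run the full two-phase network simulation
#'
#' Phase 1 (`[0, t_couple)`): all neurons integrated without coupling from
#' seeded heterogeneous initial conditions (uniform initial potentials,
#' gates at their voltage-clamped steady state).  Phase 2: the run
#' alternates between (a) integrating all `4N` equations over one
#' `update_period` with the functional topology frozen and (b) updating the
#' position vectors from the end-of-window membrane potentials and
#' rebuilding the topology snapshot.  The snapshot windows tile
#' `[t_couple, t_end]` exactly.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `simulation_trace` with elements `times`
#'   (output grid), `V`, `n`, `m`, `h` (time x neuron matrices), `positions`
#'   (array: window-start positions), `position_times`, `snapshots` (list of
#'   [adjacency_from_positions()] snapshots) and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  N <- config$N
  hh <- config$hh
  pl <- config$plasticity
  net <- config$network
  L <- net$global_L
  dt <- config$output_dt

  # Forked RNG streams so adding one consumer does not perturb the others.
  cycle <- if (config$init_mode == "limit_cycle") .reference_cycle(config)
  set.seed(config$seed)
  if (!is.null(cycle)) {
    idx <- 1L + floor(stats::runif(N) * nrow(cycle))
    y <- as.numeric(cycle[idx, ])        # column-major: V block, then gates
  } else {
    V0 <- stats::runif(N, config$V_init[1], config$V_init[2])
    g0 <- hh_steady_state(V0, hh)
    y <- c(V0, g0$n, g0$m, g0$h)
  }
  Iext <- rep(hh$Iext, N)
  if (config$Iext_jitter > 0)
    Iext <- Iext * (1 + config$Iext_jitter * stats::runif(N, -1, 1))
  set.seed(config$seed + 1000003L)
  pos <- t(vapply(net$domains, function(dm) {
    ctr <- (dm$lower + dm$upper) / 2
    side <- dm$upper - dm$lower
    ctr + config$jitter_frac * side * stats::runif(length(ctr), -0.5, 0.5)
  }, numeric(net$d)))

  times <- seq(0, config$t_end, by = dt)
  nt <- length(times)
  states <- matrix(NA_real_, nt, 4 * N)

  # ---- phase 1: isolated neurons -------------------------------------
  i_couple <- which.min(abs(times - config$t_couple))
  if (abs(times[i_couple] - config$t_couple) > 1e-9)
    stop("'t_couple' must lie on the output grid")
  .set_engine_params(N, hh, Iext, rep(0, N), matrix(0, N, N))
  out <- .integrate_block(y, times[1:i_couple], config)
  states[1:i_couple, ] <- out[, -1]
  y <- .clamp_gates(out[nrow(out), -1], N)

  # ---- phase 2: coupled, windowed ------------------------------------
  mask <- if (config$mask_structural) net$overlap else NULL
  n_win <- ceiling((config$t_end - config$t_couple) / pl$update_period -
                     1e-9)
  snapshots <- vector("list", n_win)
  positions <- array(NA_real_, c(n_win + 1L, N, net$d))
  position_times <- numeric(n_win + 1L)
  positions[1, , ] <- pos
  position_times[1] <- config$t_couple

  t0 <- config$t_couple
  row0 <- i_couple
  for (w in seq_len(n_win)) {
    t1 <- min(t0 + pl$update_period, config$t_end)
    snap <- adjacency_from_positions(pos, pl, L, mask = mask,
                                     t_start = t0, t_end = t1)
    snapshots[[w]] <- snap
    wt <- times[times > t0 + 1e-9 & times <= t1 + 1e-9]
    .set_engine_params(N, hh, Iext, snap$c, snapshot_laplacian(snap))
    out <- .integrate_block(y, c(t0, wt, if (!length(wt)) t1), config)
    if (length(wt)) {
      rows <- row0 + seq_along(wt)
      states[rows, ] <- out[-1, -1, drop = FALSE]
      row0 <- row0 + length(wt)
    }
    y <- .clamp_gates(out[nrow(out), -1], N)
    Vend <- y[1:N]
    pos <- update_positions(pos, Vend, pl, net, mode = config$update_mode)
    positions[w + 1L, , ] <- pos
    position_times[w + 1L] <- t1
    t0 <- t1
  }

  # clamp recorded gate samples the same way as the carried state
  gates <- states[, (N + 1):(4 * N), drop = FALSE]
  states[, (N + 1):(4 * N)] <- pmin(pmax(gates, 0), 1)

  structure(list(times = times,
                 V = states[, 1:N, drop = FALSE],
                 n = states[, (N + 1):(2 * N), drop = FALSE],
                 m = states[, (2 * N + 1):(3 * N), drop = FALSE],
                 h = states[, (3 * N + 1):(4 * N), drop = FALSE],
                 positions = positions,
                 position_times = position_times,
                 snapshots = snapshots,
                 config = config),
            class = "simulation_trace")
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf(paste0("simulation_trace: %d neurons, t in [0, %g] ms ",
                     "(coupled from %g ms), %d snapshots\n"),
              x$config$N, x$config$t_end, x$config$t_couple,
              length(x$snapshots)))
  invisible(x)
}

#' Coupling current injected into each neuron
#'
#' For a frozen topology the interaction term is
#' `c_i * sum_j A_ij V_j = c_i * sum_{j ~ i} (V_j - V_i)` with `A` the graph
#' Laplacian -- a consensus (proportional-controller) term that vanishes
#' identically when all potentials are equal.
#'
#' @param V Length-N vector of membrane potentials (mV).
#' @param snapshot A `topology_snapshot`.
#' @return Length-N vector of coupling currents (muA/cm^2).
#' @export
coupling_input <- function(V, snapshot) {
  if (length(V) != snapshot$n) stop("'V' must have one entry per neuron")
  # summing pairwise differences (rather than c_i * A %*% V) keeps the
  # consensus null exact: identical potentials give exactly zero input
  out <- numeric(snapshot$n)
  ed <- snapshot$edges
  for (k in seq_len(nrow(ed))) {
    i <- ed[k, 1]; j <- ed[k, 2]
    out[i] <- out[i] + (V[j] - V[i])
    out[j] <- out[j] + (V[i] - V[j])
  }
  snapshot$c * out
}

#' Node-degree time series
#'
#' The functional degree of every neuron on the output grid: zero before
#' coupling starts, then the row sums of the active snapshot's coupling
#' matrix.  The horizontal variation of these series is the signature of
#' structural evolution.
#'
#' @param trace A [run_simulation()] trace.
#' @return A `length(times)` x N integer matrix.
#' @export
degree_series <- function(trace) {
  nt <- length(trace$times)
  deg <- matrix(0L, nt, trace$config$N)
  for (snap in trace$snapshots) {
    sel <- trace$times > snap$t_start + 1e-9 &
      trace$times <= snap$t_end + 1e-9
    if (any(sel))
      deg[sel, ] <- matrix(snap$degree, sum(sel), trace$config$N,
                           byrow = TRUE)
  }
  deg
}
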
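# Single-neuron Hodgkin-Huxley dynamics: rate functions, derivatives,
# steady states and the analytic Jacobian used by the stability analysis.

#' Hodgkin-Huxley membrane parameters
#'
#' Constructs the parameter set of the conductance-based membrane model.
#' Defaults are the squid-axon constants expressed in absolute voltage with a
#' resting potential of -60 mV, so the reversal potentials are the classic
#' values shifted by -60 mV (ENa = 55, EK = -72, EL = -49.4 mV) and the rate
#' functions are evaluated on the shifted variable `u = V - Vrest`.
#'
#' @param gNa,gK,gL Maximal conductances of the sodium, potassium and leak
#'   channels (mS/cm^2); must be positive.
#' @param CM Membrane capacitance (muF/cm^2); must be positive.
#' @param ENa,EK,EL Reversal potentials (mV).
#' @param Iext Constant external drive current (muA/cm^2).  The default
#'   10 muA/cm^2 puts the isolated neuron in its periodic-spiking regime.
#' @param Vrest Resting-potential offset of the rate-function convention (mV).
#' @return An object of class `hh_params`.
#' @examples
#' p <- hh_params()
#' rate_constants(-60, p)
#' @export
hh_params <- function(gNa = 120, gK = 36, gL = 0.3, CM = 1,
                      ENa = 55, EK = -72, EL = -49.4,
                      Iext = 10, Vrest = -60) {
  for (nm in c("gNa", "gK", "gL", "CM")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a positive finite scalar", nm))
  }
  for (nm in c("ENa", "EK", "EL", "Iext", "Vrest")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a finite scalar", nm))
  }
  structure(list(gNa = gNa, gK = gK, gL = gL, CM = CM,
                 ENa = ENa, EK = EK, EL = EL,
                 Iext = Iext, Vrest = Vrest),
            class = "hh_params")
}

# s/(exp(s)-1) with its removable singularity at s = 0 filled by the limit;
# the series branch keeps full precision for |s| below the cutover.
.expm1_ratio <- function(s) {
  out <- ifelse(abs(s) < 1e-8, 1 - s / 2, s / expm1(s))
  out
}

# d/ds of s/(exp(s)-1); near 0 the direct form cancels catastrophically,
# so a short series is used there.
.expm1_ratio_deriv <- function(s) {
  small <- abs(s) < 1e-4
  es <- expm1(s)
  direct <- ifelse(small, NA_real_, (es - s * (es + 1)) / (es * es))
  series <- -0.5 + s / 6 - s^3 / 180
  ifelse(small, series, direct)
}

#' Voltage-dependent channel rate constants
#'
#' Evaluates the six opening/closing rates of the gating variables at
#' membrane potential `V` (mV), using the classic forms on the shifted
#' variable `u = V - Vrest`.  The removable singularities at `u = 10`
#' (`alpha_n`) and `u = 25` (`alpha_m`) are filled with their limit values
#' 0.1 and 1.
#'
#' @param V Membrane potential(s), mV.  Must be finite.
#' @param params An [hh_params()] object.
#' @return A list with components `alpha_n`, `beta_n`, `alpha_m`, `beta_m`,
#'   `alpha_h`, `beta_h` (units 1/ms), each the same length as `V`.
#' @export
rate_constants <- function(V, params = hh_params()) {
  if (!all(is.finite(V))) stop("'V' must be finite")
  u <- V - params$Vrest
  list(
    alpha_n = 0.1 * .expm1_ratio((10 - u) / 10),
    beta_n = 0.125 * exp(-u / 80),
    alpha_m = .expm1_ratio((25 - u) / 10),
    beta_m = 4 * exp(-u / 18),
    alpha_h = 0.07 * exp(-u / 20),
    beta_h = 1 / (exp((30 - u) / 10) + 1)
  )
}

# dr/dV for all six rates, same shapes as rate_constants().
.rate_derivs <- function(V, params) {
  u <- V - params$Vrest
  list(
    alpha_n = 0.1 * .expm1_ratio_deriv((10 - u) / 10) * (-1 / 10),
    beta_n = -0.125 / 80 * exp(-u / 80),
    alpha_m = .expm1_ratio_deriv((25 - u) / 10) * (-1 / 10),
    beta_m = -4 / 18 * exp(-u / 18),
    alpha_h = -0.07 / 20 * exp(-u / 20),
    beta_h = {
      bh <- 1 / (exp((30 - u) / 10) + 1)
      bh * (1 - bh) / 10
    }
  )
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 4L || !all(is.finite(state)))
    stop("'state' must be a finite numeric vector (V, n, m, h)")
  unname(state)
}

#' Time derivative of a single neuron's state
#'
#' The membrane equation sums the sodium, potassium and leak currents plus
#' the external drive and any coupling current; the gates relax at their
#' voltage-dependent rates.
#'
#' @param state Numeric vector `c(V, n, m, h)`.
#' @param I_coupling Additional injected current (muA/cm^2), e.g. from the
#'   network coupling.
#' @param params An [hh_params()] object.
#' @return Named numeric vector `c(V, n, m, h)` of time derivatives
#'   (mV/ms and 1/ms).
#' @export
hh_derivative <- function(state, I_coupling = 0, params = hh_params()) {
  s <- .check_state(state)
  V <- s[1]; n <- s[2]; m <- s[3]; h <- s[4]
  r <- rate_constants(V, params)
  dV <- (-params$gNa * m^3 * h * (V - params$ENa)
         - params$gK * n^4 * (V - params$EK)
         - params$gL * (V - params$EL)
         + params$Iext + I_coupling) / params$CM
  c(V = dV,
    n = r$alpha_n * (1 - n) - r$beta_n * n,
    m = r$alpha_m * (1 - m) - r$beta_m * m,
    h = r$alpha_h * (1 - h) - r$beta_h * h)
}

#' Analytic Jacobian of the single-neuron vector field
#'
#' Partial derivatives of `(dV/dt, dn/dt, dm/dt, dh/dt)` with respect to
#' `(V, n, m, h)`, evaluated at `state`.  This is the `Df` block entering the
#' per-window exponential-synchronization certificate.
#'
#' @inheritParams hh_derivative
#' @return A 4x4 numeric matrix with rows/columns ordered `V, n, m, h`.
#' @export
hh_jacobian <- function(state, params = hh_params()) {
  s <- .check_state(state)
  V <- s[1]; n <- s[2]; m <- s[3]; h <- s[4]
  r <- rate_constants(V, params)
  dr <- .rate_derivs(V, params)
  J <- matrix(0, 4, 4, dimnames = list(c("V", "n", "m", "h"),
                                       c("V", "n", "m", "h")))
  J[1, 1] <- -(params$gNa * m^3 * h + params$gK * n^4 + params$gL) / params$CM
  J[1, 2] <- -4 * params$gK * n^3 * (V - params$EK) / params$CM
  J[1, 3] <- -3 * params$gNa * m^2 * h * (V - params$ENa) / params$CM
  J[1, 4] <- -params$gNa * m^3 * (V - params$ENa) / params$CM
  J[2, 1] <- dr$alpha_n * (1 - n) - dr$beta_n * n
  J[2, 2] <- -(r$alpha_n + r$beta_n)
  J[3, 1] <- dr$alpha_m * (1 - m) - dr$beta_m * m
  J[3, 3] <- -(r$alpha_m + r$beta_m)
  J[4, 1] <- dr$alpha_h * (1 - h) - dr$beta_h * h
  J[4, 4] <- -(r$alpha_h + r$beta_h)
  J
}

#' Gating steady states
#'
#' The voltage-clamped fixed points `x_inf = alpha/(alpha + beta)` of the
#' three gates, used to initialise neurons consistently with their starting
#' potential.
#'
#' @inheritParams rate_constants
#' @return A list with components `n`, `m`, `h`, each in `[0, 1]` and the
#'   same length as `V`.
#' @export
hh_steady_state <- function(V, params = hh_params()) {
  r <- rate_constants(V, params)
  list(n = r$alpha_n / (r$alpha_n + r$beta_n),
       m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h))
}
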
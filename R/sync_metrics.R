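# Synchronization diagnostics: mean membrane potential, its population
# standard deviation, and the synchronization index S = -ln(sigma).

# Below this floor sigma is treated as exact synchrony; keeps S finite.
.SIGMA_FLOOR <- 1e-12

#' Mean membrane potential
#'
#' @param V Numeric vector of membrane potentials (mV); must be non-empty.
#' @return The arithmetic mean (mV).
#' @export
mean_potential <- function(V) {
  if (length(V) < 1L) stop("'V' must be non-empty")
  mean(V)
}

#' Synchronization index of a set of potentials
#'
#' The population standard deviation (divisor `N`, not `N - 1`) of the
#' potentials, and the index `S = -ln(sigma)`.  Positive `S` means the
#' deviation is below 1 mV, i.e. the potentials are close enough to call the
#' set synchronized.  When `sigma` underflows the floor of `1e-12`
#' (identical potentials), `S` is clamped at `-ln(1e-12)` and flagged.
#'
#' @param V Numeric vector of membrane potentials (mV); must be non-empty.
#' @return A list with `sigma` (mV), `S` (dimensionless) and `clamped`
#'   (logical).
#' @export
sync_index <- function(V) {
  if (length(V) < 1L) stop("'V' must be non-empty")
  mu <- mean(V)
  sigma <- sqrt(mean((V - mu)^2))
  clamped <- sigma < .SIGMA_FLOOR
  list(sigma = sigma, S = -log(max(sigma, .SIGMA_FLOOR)), clamped = clamped)
}

#' Synchronization time series of a neuron subset
#'
#' Per-output-time mean potential, population standard deviation and
#' synchronization index over the given neurons (defaulting to the whole
#' network), as used for both the global network and the detected
#' communities.
#'
#' @param trace A [run_simulation()] trace.
#' @param members Integer indices of the neurons to analyse; `NULL` means
#'   all of them.  Must be non-empty.
#' @return A data frame with columns `time`, `mu`, `sigma`, `S`, `clamped`.
#' @export
sync_series <- function(trace, members = NULL) {
  if (is.null(members)) members <- seq_len(trace$config$N)
  members <- as.integer(members)
  if (length(members) < 1L) stop("'members' must be non-empty")
  if (any(members < 1L | members > trace$config$N))
    stop("'members' out of range")
  Vm <- trace$V[, members, drop = FALSE]
  mu <- rowMeans(Vm)
  sigma <- sqrt(rowMeans((Vm - mu)^2))
  clamped <- sigma < .SIGMA_FLOOR
  data.frame(time = trace$times, mu = mu, sigma = sigma,
             S = -log(pmax(sigma, .SIGMA_FLOOR)), clamped = clamped)
}
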
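test_that("rate constants match the classic forms at the resting potential", {
  p <- hh_params()
  r <- rate_constants(p$Vrest, p)
  expect_equal(r$alpha_n, 0.1 / (exp(1) - 1), tolerance = 1e-12)
  expect_equal(r$beta_n, 0.125)
  expect_equal(r$beta_m, 4)
  expect_equal(r$alpha_h, 0.07)
})

test_that("removable singularities are filled with their limit values", {
  p <- hh_params()
  expect_equal(rate_constants(p$Vrest + 10, p)$alpha_n, 0.1)
  expect_equal(rate_constants(p$Vrest + 25, p)$alpha_m, 1)
  # continuity: limit branch agrees with evaluation just off the singularity
  for (u0 in c(10, 25)) {
    at <- rate_constants(p$Vrest + u0, p)
    for (eps in c(-1e-6, 1e-6)) {
      off <- rate_constants(p$Vrest + u0 + eps, p)
      expect_equal(off$alpha_n, at$alpha_n, tolerance = 1e-6)
      expect_equal(off$alpha_m, at$alpha_m, tolerance = 1e-6)
    }
  }
})

test_that("rates are non-negative over a wide voltage range and reject bad input", {
  p <- hh_params()
  r <- rate_constants(seq(-200, 150, by = 0.5), p)
  for (x in r) expect_true(all(x >= 0))
  expect_error(rate_constants(NaN, p), "finite")
  expect_error(rate_constants(Inf, p), "finite")
})

test_that("gating steady states null the gate derivatives", {
  p <- hh_params()
  for (V in c(-90, -60, -30, 0, 30)) {
    g <- hh_steady_state(V, p)
    d <- hh_derivative(c(V, g$n, g$m, g$h), 0, p)
    expect_equal(unname(d[2:4]), c(0, 0, 0), tolerance = 1e-14)
    expect_true(all(unlist(g) >= 0 & unlist(g) <= 1))
  }
  # activation saturates for strong depolarisation
  expect_gt(hh_steady_state(200, p)$m, 0.999)
  # matches a root-finder applied to the gate equation at rest
  r <- rate_constants(p$Vrest, p)
  n_root <- uniroot(function(x) r$alpha_n * (1 - x) - r$beta_n * x,
                    c(0, 1), tol = 1e-12)$root
  expect_equal(hh_steady_state(p$Vrest, p)$n, n_root, tolerance = 1e-9)
})

test_that("membrane derivative vanishes with zero driving force", {
  p <- hh_params(ENa = -60, EK = -60, EL = -60, Iext = 0)
  d <- hh_derivative(c(-60, 0.3, 0.1, 0.6), 0, p)
  expect_equal(unname(d[1]), 0)
})

test_that("membrane derivative agrees with a term-by-term recomputation", {
  p <- hh_params(Iext = 0)
  V <- -60
  g <- hh_steady_state(V, p)
  s <- c(V, g$n, g$m, g$h)
  # independent route: each ionic current computed and summed separately
  ina <- p$gNa * g$m^3 * g$h * (V - p$ENa)
  ik <- p$gK * g$n^4 * (V - p$EK)
  il <- p$gL * (V - p$EL)
  expect_equal(unname(hh_derivative(s, 0, p)[1]),
               (-ina - ik - il) / p$CM, tolerance = 1e-10)
  # coupling current enters linearly through the current slot
  expect_equal(unname(hh_derivative(s, 7.5, p)[1]) -
                 unname(hh_derivative(s, 0, p)[1]),
               7.5 / p$CM, tolerance = 1e-12)
})

test_that("analytic Jacobian matches central finite differences", {
  p <- hh_params()
  set.seed(11)
  for (rep in 1:25) {
    s <- c(runif(1, -90, 30), runif(3))
    J <- hh_jacobian(s, p)
    eps <- 1e-6
    for (k in 1:4) {
      sp <- s; sm <- s
      sp[k] <- sp[k] + eps
      sm[k] <- sm[k] - eps
      fd <- (hh_derivative(sp, 0, p) - hh_derivative(sm, 0, p)) / (2 * eps)
      expect_equal(unname(J[, k]), unname(fd),
                   tolerance = 1e-4)
    }
  }
})

test_that("Jacobian structure: gate self-relaxation and leading entry", {
  p <- hh_params()
  for (V in seq(-90, 40, by = 10)) {
    g <- hh_steady_state(V, p)
    s <- c(V, g$n, g$m, g$h)
    J <- hh_jacobian(s, p)
    r <- rate_constants(V, p)
    expect_lt(J[2, 2], 0)
    expect_equal(J[2, 2], -(r$alpha_n + r$beta_n))
    expect_equal(J[1, 1],
                 -(p$gNa * g$m^3 * g$h + p$gK * g$n^4 + p$gL) / p$CM)
    # gates do not depend on each other
    expect_equal(J[2, 3], 0)
    expect_equal(J[3, 4], 0)
  }
})

test_that("undriven neuron relaxes to a fixed point near rest", {
  p <- hh_params(Iext = 0)
  rhs <- function(t, y, parms) list(hh_derivative(y, 0, p))
  g <- hh_steady_state(-75, p)
  out <- deSolve::ode(c(-75, g$n, g$m, g$h), seq(0, 300, 1), rhs, NULL,
                      method = "lsoda")
  expect_lt(abs(out[nrow(out), 2] - p$Vrest), 5)
})

test_that("default drive produces periodic spiking below 60 mV", {
  p <- hh_params()   # Iext = 10
  rhs <- function(t, y, parms) list(hh_derivative(y, 0, p))
  g <- hh_steady_state(p$Vrest, p)
  out <- deSolve::ode(c(p$Vrest, g$n, g$m, g$h), seq(0, 300, 0.05), rhs,
                      NULL, method = "lsoda", rtol = 1e-8, atol = 1e-8)
  V <- out[out[, 1] > 100, 2]
  peaks <- sum(diff(sign(diff(V))) == -2 & V[-c(1, length(V))] > 0)
  expect_gt(peaks, 5)              # sustained periodic firing
  expect_lt(max(V), 60)
  # gates stay inside [0, 1] along the trajectory
  expect_true(all(out[, 3:5] >= -1e-9 & out[, 3:5] <= 1 + 1e-9))
})
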
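# Gating-scheme registry. A scheme parameterizes Hodgkin-Huxley-type kinetics
# through a generalized rate family: each forward/backward rate of the m, h
# and n gates is a (type, A, Vh, k) quadruple with
#   type 0 (linoid):      A * (v - Vh) / (1 - exp(-(v - Vh)/k))
#   type 1 (exponential): A * exp((v - Vh)/k)
#   type 2 (sigmoid):     A / (1 + exp(-(v - Vh)/k))
# plus a global rate multiplier `phi`, a global voltage shift `vshift`, and a
# KV1.4-like K+ slow-inactivation gate (sigmoid steady state, constant tau)
# that multiplies the n^4 term. Alternative kinetics (e.g. a transcription of
# a published mossy-fiber bouton gating model) can be registered under their
# own name without touching the solver.

.gating_registry <- new.env(parent = emptyenv())

.hh_rate_matrix <- function() {
  m <- matrix(c(
    0, 0.1,   -40, 10,    # alpha_m (linoid)
    1, 4,     -65, -18,   # beta_m  (exponential)
    1, 0.07,  -65, -20,   # alpha_h (exponential)
    2, 1,     -35, 10,    # beta_h  (sigmoid)
    0, 0.01,  -55, 10,    # alpha_n (linoid)
    1, 0.125, -65, -80),  # beta_n  (exponential)
    nrow = 6, byrow = TRUE)
  dimnames(m) <- list(c("alpha_m", "beta_m", "alpha_h", "beta_h",
                        "alpha_n", "beta_n"),
                      c("type", "A", "Vh", "k"))
  m
}

#' Register a Hodgkin-Huxley-type gating scheme
#'
#' Adds a named kinetic scheme to the gating registry. Rates are evaluated at
#' \code{v - vshift} and multiplied by \code{phi}, so existing rate tables can
#' be shifted along the voltage axis and rescaled in time without editing the
#' table itself.
#'
#' @param name scheme name.
#' @param rates 6 x 4 numeric matrix with rows \code{alpha_m, beta_m, alpha_h,
#'   beta_h, alpha_n, beta_n} and columns \code{type, A, Vh, k} (see Details
#'   in the package vignette).
#' @param phi global rate multiplier (dimensionless; temperature-like
#'   scaling).
#' @param vshift global voltage shift, mV.
#' @param kinact numeric vector \code{c(vhalf, slope, tau)} for the K+
#'   slow-inactivation gate: sigmoid steady state
#'   \code{1/(1 + exp((v - vhalf)/slope))} and constant time constant
#'   \code{tau} in ms.
#' @param overwrite replace an existing scheme of the same name.
#' @return The scheme parameter list, invisibly.
#' @export
register_gating_scheme <- function(name, rates, phi = 1, vshift = 0,
                                   kinact = c(vhalf = -50.5, slope = 7,
                                              tau = 300),
                                   overwrite = FALSE) {
  if (!is.matrix(rates) || !all(dim(rates) == c(6, 4)))
    stop("rates must be a 6 x 4 matrix")
  if (phi <= 0) stop("phi must be positive")
  if (kinact[3] <= 0) stop("kinact tau must be positive (ms)")
  if (!overwrite && exists(name, envir = .gating_registry))
    stop("gating scheme '", name, "' already registered")
  scheme <- list(name = name, rates = unname(rates), phi = phi,
                 vshift = vshift, kinact = unname(kinact))
  assign(name, scheme, envir = .gating_registry)
  invisible(scheme)
}

#' Look up a registered gating scheme
#'
#' @param scheme scheme name, or an already-resolved scheme parameter list.
#' @return Scheme parameter list.
#' @export
gating_scheme <- function(scheme = "hh_mf") {
  if (is.list(scheme)) return(scheme)
  if (!exists(scheme, envir = .gating_registry))
    stop("unknown gating scheme '", scheme, "'; registered: ",
         paste(list_gating_schemes(), collapse = ", "))
  get(scheme, envir = .gating_registry)
}

#' @rdname gating_scheme
#' @export
list_gating_schemes <- function() ls(.gating_registry)

#' Voltage-dependent gating rates
#'
#' Forward and backward rate coefficients of the m, h and n gates and the
#' steady state / time constant of the K+ slow-inactivation gate, evaluated
#' at the given membrane potentials.
#'
#' @param v membrane potentials, mV.
#' @param scheme gating scheme name or parameter list.
#' @return A list with matrices \code{alpha}, \code{beta} (columns m, h, n;
#'   1/ms), vector \code{kinf} and scalar \code{ktau} (ms).
#' @export
gating_rates <- function(v, scheme = "hh_mf") {
  gating_rates_cpp(as.numeric(v), gating_scheme(scheme))
}

#' Steady-state gating variables
#'
#' \code{x_inf = alpha/(alpha + beta)} per gate; the K+ inactivation gate uses
#' its sigmoid steady state directly. Used to initialize simulations at the
#' holding potential.
#'
#' @param v membrane potential(s), mV.
#' @param scheme gating scheme name or parameter list.
#' @return A list with components \code{m}, \code{h}, \code{n},
#'   \code{k_inact}, each of length \code{length(v)}; all values in [0, 1].
#' @export
steady_state_gates <- function(v, scheme = "hh_mf") {
  r <- gating_rates(v, scheme)
  list(m = unname(r$alpha[, 1] / (r$alpha[, 1] + r$beta[, 1])),
       h = unname(r$alpha[, 2] / (r$alpha[, 2] + r$beta[, 2])),
       n = unname(r$alpha[, 3] / (r$alpha[, 3] + r$beta[, 3])),
       k_inact = unname(r$kinf))
}

#' Advance gating variables over one time step
#'
#' Exact exponential-integrator update for a fixed membrane potential: each
#' gate relaxes toward \code{x_inf(v)} with time constant
#' \code{1/(alpha(v) + beta(v))} over \code{dt}. Exact for piecewise-constant
#' voltage, and keeps every gate in [0, 1].
#'
#' @param state list with components \code{m}, \code{h}, \code{n},
#'   \code{k_inact} (as from \code{\link{steady_state_gates}}).
#' @param v membrane potential, mV (scalar or one value per state entry).
#' @param dt time step, ms (> 0).
#' @param scheme gating scheme name or parameter list.
#' @param use_kinact advance the K+ slow-inactivation gate (if FALSE the gate
#'   is held at its current value).
#' @return Updated state list.
#' @export
advance_gating <- function(state, v, dt, scheme = "hh_mf", use_kinact = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  r <- gating_rates(v, scheme)
  step <- function(x, a, b)
    unname(x + (a / (a + b) - x) * (1 - exp(-dt * (a + b))))
  out <- list(m = step(state$m, r$alpha[, 1], r$beta[, 1]),
              h = step(state$h, r$alpha[, 2], r$beta[, 2]),
              n = step(state$n, r$alpha[, 3], r$beta[, 3]),
              k_inact = state$k_inact)
  if (use_kinact)
    out$k_inact <- state$k_inact +
      (r$kinf - state$k_inact) * (1 - exp(-dt / r$ktau))
  out
}

#' Channel specification
#'
#' @param channel_id one of \code{"Na"}, \code{"K"}, \code{"leak"}.
#' @param density conductance density, mS/cm^2 (>= 0; exactly 0 encodes a
#'   knockout).
#' @param reversal reversal potential, mV.
#' @param gating_model_id name of the registered kinetics scheme.
#' @return An object of class \code{channel_spec}.
#' @export
channel_spec <- function(channel_id = c("Na", "K", "leak"), density, reversal,
                         gating_model_id = "hh_mf") {
  channel_id <- match.arg(channel_id)
  if (density < 0) stop("density must be >= 0 (0 encodes a knockout)")
  structure(list(channel_id = channel_id, density = density,
                 reversal = reversal, gating_model_id = gating_model_id),
            class = "channel_spec")
}

#' Ionic membrane current of one channel population
#'
#' \code{I_Na = g_Na m^3 h (V - E_Na)}, \code{I_K = g_K n^4 k_inact (V - E_K)},
#' \code{I_leak = g_leak (V - E_leak)}; outward current is positive.
#'
#' @param v membrane potential, mV.
#' @param state gating state list (\code{m}, \code{h}, \code{n},
#'   \code{k_inact}); ignored for leak.
#' @param spec a \code{\link{channel_spec}}.
#' @param area membrane area, um^2.
#' @return Current in nA.
#' @export
ionic_current <- function(v, state, spec, area) {
  g_open <- switch(spec$channel_id,
    Na = spec$density * state$m^3 * state$h,
    K = spec$density * state$n^4 * state$k_inact,
    leak = spec$density)
  # mS/cm^2 * cm^2 * mV = uA; -> nA
  1000 * g_open * (area * 1e-8) * (v - spec$reversal)
}

# Leak reversal that balances the steady-state Na+/K+ currents of one
# membrane composition at holding potential v (densities in mS/cm^2).
.balancing_e_leak <- function(v, gna, gk, e_na, e_k, gl, scheme,
                              use_kinact = TRUE) {
  ss <- steady_state_gates(v, scheme)
  kin <- if (use_kinact) ss$k_inact else 1
  i_na <- gna * ss$m^3 * ss$h * (v - e_na)
  i_k <- gk * ss$n^4 * kin * (v - e_k)
  v + (i_na + i_k) / gl
}

# Default mossy-fiber scheme: classic squid-type rate shapes with two
# physiological calibrations at the mossy-fiber conductance densities:
# (1) the K+ activation gate is shifted +20 mV so the channels are closed at
# the -80 mV resting potential (axonal Kv1-family channels half-activate far
# above rest; without the shift the squid n gate leaves a standing K+
# conductance of ~1/3 of the leak, which would contaminate every passive
# membrane property); (2) the global rate multiplier phi is set so the bouton
# action potential half-width is ~0.8-0.9 ms (room-temperature mossy-fiber
# value).
.hh_mf_rate_matrix <- function() {
  r <- .hh_rate_matrix()
  r["alpha_n", "Vh"] <- r["alpha_n", "Vh"] + 20
  r["beta_n", "Vh"] <- r["beta_n", "Vh"] + 20
  r
}

.onLoad <- function(libname, pkgname) {
  if (!exists("hh_mf", envir = .gating_registry)) {
    register_gating_scheme("hh_mf", .hh_mf_rate_matrix(), phi = 2.5,
                           vshift = 0)
    # unshifted classic squid kinetics, kept for reference and tests
    register_gating_scheme("hh_squid", .hh_rate_matrix(), phi = 1, vshift = 0)
  }
}
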
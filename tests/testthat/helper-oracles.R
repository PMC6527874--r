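# Independent closed-form oracle: membrane-potential deviation of a uniform
# passive cable with sealed ends on [0, L], in response to a current step of
# I_nA injected at x_stim from t = 0, by eigenfunction (cosine-mode) series
# of the continuous cable equation. Distances in um, times in ms, output mV.
analytic_sealed_cable_response <- function(x_rec, t_ms, L, d, Cm, Rm, Ri,
                                           I_nA, x_stim, n_modes = 2000) {
  L_cm <- L * 1e-4
  x <- x_rec * 1e-4
  xs <- x_stim * 1e-4
  d_cm <- d * 1e-4
  cm_len <- Cm * pi * d_cm            # uF/cm
  gm_len <- pi * d_cm / Rm            # S/cm
  ra_len <- 4 * Ri / (pi * d_cm^2)    # Ohm/cm
  I_uA <- I_nA * 1e-3
  k <- 0:n_modes
  phi <- function(x) ifelse(k == 0, sqrt(1 / L_cm),
                            sqrt(2 / L_cm) * cos(k * pi * x / L_cm))
  gamma_k <- gm_len + (k * pi / L_cm)^2 / ra_len   # S/cm
  tau_ms <- (cm_len / gamma_k) * 1e-3              # us -> ms
  coef <- I_uA * phi(xs) * phi(x) / gamma_k        # uV per mode at steady state
  vapply(t_ms, function(t) sum(coef * (1 - exp(-t / tau_ms))) / 1000,
         numeric(1))
}

# full width of a trace at half its peak-to-baseline amplitude
half_width <- function(time, v, baseline) {
  level <- baseline + (max(v) - baseline) / 2
  idx <- which(v >= level)
  time[max(idx)] - time[min(idx)]
}

# Lazily computed simulations shared between test files (everything is
# deterministic, so caching cannot change any result).
.sim_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

cached_passive_propagation <- function()
  cached("pp", run_protocol(protocol_passive_propagation()))

cached_step_family <- function()
  cached("sf", run_protocol(protocol_step_family(), record_sites = "bouton10"))
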
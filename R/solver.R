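#' Simulation settings
#'
#' @param duration total simulated time, ms (>= dt).
#' @param dt time step, ms; default 0.005 ms (5 us).
#' @param record_sites character vector of site names (\code{"soma"},
#'   \code{"boutonK"}, \code{"axonK"}) or segment indices; \code{NULL}
#'   records the soma (if present) and the center of every bouton.
#' @param method \code{"backward_euler"} (default) or
#'   \code{"crank_nicolson"}.
#' @param resting_potential holding potential used as initial condition, mV;
#'   gates start at their steady state there.
#' @param record_every store every k-th time step (thins recordings of long
#'   runs; peak tracking is unaffected).
#' @param record_currents record I_Na, I_K, I_leak, I_cap, I_axial, I_stim at
#'   the recorded sites.
#' @param record_gates record gating trajectories at the recorded sites.
#' @param baseline_time time at which the per-segment baseline voltage is
#'   sampled (ms); per-segment peak tracking starts there. Use the stimulus
#'   onset so peak amplitudes are measured relative to the pre-stimulus
#'   state.
#' @return An object of class \code{simulation_settings}.
#' @export
simulation_settings <- function(duration, dt = 0.005, record_sites = NULL,
                                method = c("backward_euler", "crank_nicolson"),
                                resting_potential = -80,
                                record_every = 1L, record_currents = TRUE,
                                record_gates = FALSE, baseline_time = 0) {
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be > 0")
  if (duration < dt) stop("duration must be >= dt")
  if (record_every < 1) stop("record_every must be >= 1")
  structure(list(duration = duration, dt = dt, record_sites = record_sites,
                 method = method, resting_potential = resting_potential,
                 record_every = as.integer(record_every),
                 record_currents = record_currents,
                 record_gates = record_gates, baseline_time = baseline_time),
            class = "simulation_settings")
}

#' Stimulus event
#'
#' A rectangular current injection at a named site. Positive amplitudes
#' depolarize; negative amplitudes hyperpolarize.
#'
#' @param site site name or segment index.
#' @param amplitude current, nA.
#' @param onset start time, ms.
#' @param duration pulse duration, ms (>= 0).
#' @return An object of class \code{stimulus_event}.
#' @examples
#' stimulus_event("soma", amplitude = 0.2, onset = 5, duration = 2)
#' @export
stimulus_event <- function(site, amplitude, onset, duration) {
  if (duration < 0) stop("stimulus duration must be >= 0")
  if (onset < 0) stop("stimulus onset must be >= 0")
  structure(list(site = site, amplitude = amplitude, onset = onset,
                 duration = duration), class = "stimulus_event")
}

.default_record_sites <- function(chain) {
  secs <- chain$sections$section
  c(if ("soma" %in% secs) "soma",
    grep("^bouton", secs, value = TRUE),
    if (!any(grepl("^bouton", secs)) && !("soma" %in% secs)) secs[1])
}

#' Integrate the compartmental cable equation
#'
#' Solves the chain's membrane-potential dynamics with an implicit scheme on
#' the tridiagonal compartment system (backward Euler by default), advancing
#' the Hodgkin-Huxley gates in an operator-split exponential substep. The
#' initial condition is the gating steady state at
#' \code{settings$resting_potential}. Both chain ends are sealed (zero axial
#' flux).
#'
#' Recorded currents follow the outward-positive convention, so at every
#' recorded instant and site
#' \code{I_cap + I_Na + I_K + I_leak + I_axial_net - I_stim = 0} to solver
#' precision.
#'
#' @param chain a \code{\link{build_mossy_fiber_model}} /
#'   \code{\link{build_single_cable}} chain.
#' @param settings \code{\link{simulation_settings}}.
#' @param stimuli list of \code{\link{stimulus_event}}s.
#' @param use_kinact include the K+ slow-inactivation gate (setting
#'   \code{FALSE} clamps it to 1, recovering a pure n^4 current).
#' @return An object of class \code{trace_set}: the shared time grid,
#'   matrices of Vm and current components per recorded site, per-segment
#'   peak table, and the final voltage vector.
#' @export
integrate_chain <- function(chain, settings, stimuli = list(),
                            use_kinact = TRUE) {
  stopifnot(inherits(chain, "compartment_chain"),
            inherits(settings, "simulation_settings"))
  if (inherits(stimuli, "stimulus_event")) stimuli <- list(stimuli)
  segs <- chain$segments
  area_cm2 <- segs$area * 1e-8
  sites <- settings$record_sites
  if (is.null(sites)) sites <- .default_record_sites(chain)
  rec_idx <- vapply(sites, function(s) site_index(chain, s), integer(1))
  site_names <- vapply(seq_along(sites), function(i) {
    if (is.numeric(sites[[i]])) paste0("seg", rec_idx[i]) else as.character(sites[[i]])
  }, character(1))

  n_steps <- as.integer(round(settings$duration / settings$dt))
  stim_site <- vapply(stimuli, function(s) site_index(chain, s$site), integer(1))
  v0 <- rep(settings$resting_potential, nrow(segs))

  res <- integrate_cpp(
    v0 = v0, cap = segs$cm * area_cm2,
    gna = segs$gna * area_cm2, gk = segs$gk * area_cm2,
    gl = segs$gl * area_cm2,
    ena = segs$e_na, ek = segs$e_k, el = segs$e_leak,
    gax = chain$g_axial_uS / 1000,
    dt = settings$dt, nsteps = n_steps,
    method = if (settings$method == "crank_nicolson") 1L else 0L,
    rec = rec_idx - 1L, record_every = settings$record_every,
    record_currents = settings$record_currents,
    record_gates = settings$record_gates,
    stim_site = stim_site - 1L,
    stim_amp = vapply(stimuli, `[[`, numeric(1), "amplitude"),
    stim_onset = vapply(stimuli, `[[`, numeric(1), "onset"),
    stim_dur = vapply(stimuli, `[[`, numeric(1), "duration"),
    scheme = gating_scheme(chain$gating_scheme),
    use_kinact = use_kinact, baseline_t = settings$baseline_time)

  if (!isTRUE(res$ok)) {
    i <- res$err_segment
    stop("non-finite membrane potential in segment ", i, " (section ",
         segs$section[i], ") at t = ", res$err_time,
         " ms; reduce dt or check the model parameters")
  }

  name_mat <- function(m) {
    if (is.null(m)) return(NULL)
    colnames(m) <- site_names
    m
  }
  peaks <- data.frame(segment = seq_len(nrow(segs)), section = segs$section,
                      x = segs$x, v_base = res$vbase, v_max = res$vmax,
                      t_max = res$tmax, amplitude = res$vmax - res$vbase,
                      stringsAsFactors = FALSE)
  structure(list(time = res$time, vm = name_mat(res$vm),
                 i_na = name_mat(res$i_na), i_k = name_mat(res$i_k),
                 i_leak = name_mat(res$i_leak), i_cap = name_mat(res$i_cap),
                 i_axial = name_mat(res$i_axial), i_stim = name_mat(res$i_stim),
                 gates = if (settings$record_gates)
                   list(m = name_mat(res$gate_m), h = name_mat(res$gate_h),
                        n = name_mat(res$gate_n),
                        k_inact = name_mat(res$gate_kinact)),
                 sites = site_names, peaks = peaks, v_final = res$vfinal,
                 v_base = res$vbase, settings = settings, stimuli = stimuli),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", length(x$time), " samples, dt ", x$settings$dt,
      " ms x record_every ", x$settings$record_every, ", duration ",
      x$settings$duration, " ms\n", sep = "")
  cat("  sites: ", paste(x$sites, collapse = ", "), "\n", sep = "")
  cat("  quantities: vm",
      if (!is.null(x$i_na)) ", i_na, i_k, i_leak, i_cap, i_axial, i_stim",
      if (!is.null(x$gates)) ", gating", "\n", sep = "")
  invisible(x)
}

#' Extract one recorded trace
#'
#' @param ts a \code{trace_set}.
#' @param site recorded site name.
#' @param quantity one of \code{"vm"}, \code{"i_na"}, \code{"i_k"},
#'   \code{"i_leak"}, \code{"i_cap"}, \code{"i_axial"}, \code{"i_stim"}.
#' @return data.frame with columns \code{time} and \code{value}.
#' @export
get_trace <- function(ts, site, quantity = "vm") {
  stopifnot(inherits(ts, "trace_set"))
  m <- ts[[quantity]]
  if (is.null(m)) stop("quantity '", quantity, "' was not recorded")
  if (!site %in% colnames(m))
    stop("site '", site, "' not recorded; available: ",
         paste(colnames(m), collapse = ", "))
  data.frame(time = ts$time, value = m[, site])
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  out <- data.frame(time = x$time)
  for (q in c("vm", "i_na", "i_k", "i_leak", "i_cap", "i_axial", "i_stim")) {
    m <- x[[q]]
    if (is.null(m)) next
    colnames_q <- paste0(q, ".", colnames(m))
    out[colnames_q] <- as.data.frame(m)
  }
  out
}

#' Write recorded traces to CSV with a metadata sidecar
#'
#' Writes the tidy wide table (time column plus one column per
#' site/quantity) and, alongside it, a YAML sidecar capturing the resolved
#' simulation settings and stimuli.
#'
#' @param ts a \code{trace_set}.
#' @param file output CSV path; the sidecar is written to
#'   \code{<file>.meta.yaml}.
#' @return \code{file}, invisibly.
#' @export
write_traces <- function(ts, file) {
  utils::write.csv(as.data.frame(ts), file, row.names = FALSE)
  meta <- list(settings = unclass(ts$settings),
               stimuli = lapply(ts$stimuli, unclass),
               sites = as.list(ts$sites))
  yaml::write_yaml(meta, paste0(file, ".meta.yaml"))
  invisible(file)
}

#' Capacitive current from a voltage trace
#'
#' \code{I_cap = Cm * area * dV/dt}, with a centered finite difference on the
#' uniform time grid (one-sided at the endpoints). Outward positive,
#' consistent with the trace-set conservation identity.
#'
#' @param time uniform time grid, ms.
#' @param vm membrane potential trace, mV.
#' @param cm specific membrane capacitance, uF/cm^2.
#' @param area membrane area, um^2.
#' @return Current trace in nA.
#' @export
capacitive_current <- function(time, vm, cm, area) {
  n <- length(vm)
  if (n < 3) stop("capacitive_current needs at least 3 samples")
  if (length(time) != n) stop("time and vm must have equal length")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("time grid must be uniform")
  dvdt <- c(vm[2] - vm[1],
            (vm[3:n] - vm[1:(n - 2)]) / 2,
            vm[n] - vm[n - 1]) / dt[1]
  1000 * cm * (area * 1e-8) * dvdt
}

#' Self-convergence check by time-step refinement
#'
#' Runs the same simulation at \code{dt} and \code{dt/factor} and compares
#' the recorded voltages on the coarse grid. Reports both the maximum
#' pointwise discrepancy (dominated by sub-sample timing shifts at the spike
#' upstroke) and the discrepancy of the per-site peak voltage.
#'
#' @param chain a \code{compartment_chain}.
#' @param settings \code{\link{simulation_settings}}.
#' @param stimuli list of \code{\link{stimulus_event}}s.
#' @param factor time-step refinement factor (1 compares a run with itself
#'   and must report exactly zero).
#' @return List with \code{max_pointwise}, \code{max_peak_diff} (mV) and the
#'   per-site breakdown.
#' @export
check_convergence <- function(chain, settings, stimuli = list(), factor = 2) {
  s2 <- settings
  s2$dt <- settings$dt / factor
  s2$record_every <- as.integer(settings$record_every * factor)
  r1 <- integrate_chain(chain, settings, stimuli)
  r2 <- integrate_chain(chain, s2, stimuli)
  nt <- min(nrow(r1$vm), nrow(r2$vm))
  dv <- abs(r1$vm[seq_len(nt), , drop = FALSE] -
            r2$vm[seq_len(nt), , drop = FALSE])
  peak1 <- apply(r1$vm, 2, max)
  peak2 <- apply(r2$vm, 2, max)
  per_site <- data.frame(site = r1$sites,
                         pointwise = apply(dv, 2, max),
                         peak_diff = abs(peak1 - peak2),
                         row.names = NULL)
  list(max_pointwise = max(per_site$pointwise),
       max_peak_diff = max(per_site$peak_diff),
       per_site = per_site, dt = settings$dt, dt_fine = s2$dt)
}

#' Retune the leak reversal to a requested resting potential
#'
#' Sets the leak reversal potential so that the all-channels steady state of
#' the chain equals the requested resting potential (the in-silico equivalent
#' of adjusting the leak battery to move the resting potential).
#'
#' Mode \code{"per_segment"} solves the closed-form balance
#' \code{E_leak_i = V + (I_Na,ss + I_K,ss)/g_leak} for every segment, giving
#' an exact, spatially uniform resting state. Mode \code{"global"} adjusts a
#' single uniform leak reversal by secant iteration on the settled membrane
#' potential at \code{site} (the composition of soma and axon differs, so a
#' single value can only pin the potential at one site).
#'
#' @param chain a \code{compartment_chain}.
#' @param target requested resting potential, mV.
#' @param mode \code{"per_segment"} (default) or \code{"global"}.
#' @param site settling site for global mode.
#' @param settle_duration,settle_dt settling run parameters for global mode,
#'   ms.
#' @param tol convergence tolerance on the settled potential, mV.
#' @param max_iter secant iteration cap for global mode.
#' @param use_kinact include the K+ slow-inactivation gate in the balance.
#' @return The chain with adjusted \code{e_leak}.
#' @export
retune_leak_reversal <- function(chain, target,
                                 mode = c("per_segment", "global"),
                                 site = "bouton10",
                                 settle_duration = 300, settle_dt = 0.025,
                                 tol = 0.01, max_iter = 25,
                                 use_kinact = TRUE) {
  mode <- match.arg(mode)
  scheme <- chain$gating_scheme
  segs <- chain$segments
  if (mode == "per_segment") {
    chain$segments$e_leak <- .balancing_e_leak(
      target, segs$gna, segs$gk, segs$e_na, segs$e_k, segs$gl, scheme,
      use_kinact)
    return(chain)
  }
  settle <- function(el) {
    ch <- chain
    ch$segments$e_leak <- el
    st <- simulation_settings(duration = settle_duration, dt = settle_dt,
                              record_sites = site,
                              resting_potential = target,
                              record_every = 1000L,
                              record_currents = FALSE)
    ts <- integrate_chain(ch, st, use_kinact = use_kinact)
    ts$v_final[site_index(ch, site)]
  }
  i <- site_index(chain, site)
  el0 <- .balancing_e_leak(target, segs$gna[i], segs$gk[i], segs$e_na[i],
                           segs$e_k[i], segs$gl[i], scheme, use_kinact)
  el1 <- el0 + 1
  f0 <- settle(el0) - target
  f1 <- settle(el1) - target
  for (iter in seq_len(max_iter)) {
    if (abs(f1) < tol) {
      chain$segments$e_leak <- el1
      return(chain)
    }
    el2 <- el1 - f1 * (el1 - el0) / (f1 - f0)
    el0 <- el1; f0 <- f1
    el1 <- el2; f1 <- settle(el1) - target
  }
  stop("leak-reversal retuning did not converge to ", target,
       " mV at site '", site, "' (residual ", format(f1), " mV after ",
       max_iter, " iterations)")
}
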
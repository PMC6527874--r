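#' Regional model modifier
#'
#' Declarative modification of a whole-section region of the chain:
#' conductance knockouts set the density to exactly 0 (geometry untouched),
#' \code{set_EK} overrides the local K+ reversal potential, \code{set_Cm}
#' overrides the local specific membrane capacitance.
#'
#' @param region character vector of section names
#'   (e.g. \code{c("axon10", "bouton10")}) or \code{list(from = "axon8")} for
#'   "that section through the distal end of the chain".
#' @param action one of \code{"remove_gNa"}, \code{"remove_gK"},
#'   \code{"set_EK"}, \code{"set_Cm"}.
#' @param value mV for \code{set_EK}, uF/cm^2 for \code{set_Cm}; ignored for
#'   knockouts.
#' @return An object of class \code{region_modifier}.
#' @export
region_modifier <- function(region,
                            action = c("remove_gNa", "remove_gK",
                                       "set_EK", "set_Cm"),
                            value = NULL) {
  action <- match.arg(action)
  if (action %in% c("set_EK", "set_Cm")) {
    if (is.null(value) || !is.finite(value))
      stop("action '", action, "' requires a finite value")
    if (action == "set_Cm" && value <= 0) stop("Cm override must be positive")
  }
  structure(list(region = region, action = action, value = value),
            class = "region_modifier")
}

.resolve_region <- function(chain, region) {
  secs <- if (is.list(region) && !is.null(region$from))
    sections_from(chain, region$from)
  else as.character(unlist(region))
  missing <- setdiff(secs, chain$sections$section)
  if (length(missing))
    stop("unknown section(s) in region: ", paste(missing, collapse = ", "))
  secs
}

#' Apply regional modifiers to a chain
#'
#' Modifiers compose: applying them one at a time equals applying all at
#' once.
#'
#' @param chain a \code{compartment_chain}.
#' @param modifiers list of \code{\link{region_modifier}}s.
#' @return The modified chain.
#' @export
apply_modifiers <- function(chain, modifiers) {
  if (inherits(modifiers, "region_modifier")) modifiers <- list(modifiers)
  for (mod in modifiers) {
    idx <- chain$segments$section %in% .resolve_region(chain, mod$region)
    chain$segments[idx, switch(mod$action,
                               remove_gNa = "gna", remove_gK = "gk",
                               set_EK = "e_k", set_Cm = "cm")] <-
      switch(mod$action, remove_gNa = 0, remove_gK = 0,
             set_EK = mod$value, set_Cm = mod$value)
  }
  chain
}

.protocol_spec <- function(name, resting, modifiers = list(),
                           stimuli = list(), members, record_sites = NULL,
                           duration = 60, dt = 0.005, record_every = 1L,
                           record_currents = FALSE, baseline_time = 0,
                           retune = "per_segment") {
  structure(list(name = name, resting = resting, modifiers = modifiers,
                 stimuli = stimuli, members = members,
                 record_sites = record_sites, duration = duration, dt = dt,
                 record_every = as.integer(record_every),
                 record_currents = record_currents,
                 baseline_time = baseline_time, retune = retune),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec> ", x$name, ": ", length(x$members), " member(s), rest ",
      x$resting, " mV, duration ", x$duration, " ms, dt ", x$dt, " ms\n",
      sep = "")
  invisible(x)
}

.member <- function(label, value = NULL, modifiers = list(), stimuli = list(),
                    resting = NULL) {
  list(label = label, value = value, modifiers = modifiers, stimuli = stimuli,
       resting = resting)
}

.soma_ap_stimulus <- function(site = "soma", onset = 5)
  stimulus_event(site, amplitude = 0.2, onset = onset, duration = 2)

#' Protocol: passive propagation beyond a distal conductance knockout
#'
#' Evokes a propagated action potential by somatic current injection
#' (0.2 nA, 2 ms) and removes the Na+ and K+ conductances from
#' \code{knockout_start} through the distal end of the chain, so that only
#' the passively propagated (capacitive) depolarization reaches the distal
#' boutons. Contains a control member (no knockout) and the knockout member.
#'
#' @param knockout_start first knocked-out section (default \code{"axon8"});
#'   \code{NULL} disables the knockout, making both members identical.
#' @param stim_site stimulation site.
#' @param resting resting potential, mV.
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @return A \code{protocol_spec} with members \code{control} and
#'   \code{passive}.
#' @export
protocol_passive_propagation <- function(knockout_start = "axon8",
                                         stim_site = "soma", resting = -80,
                                         duration = 60, dt = 0.005) {
  ko <- if (is.null(knockout_start)) list() else {
    if (identical(knockout_start, "soma") || identical(knockout_start, stim_site))
      stop("knockout region must not cover the stimulated site '",
           stim_site, "'")
    region <- list(from = knockout_start)
    list(region_modifier(region, "remove_gNa"),
         region_modifier(region, "remove_gK"))
  }
  .protocol_spec("passive_propagation", resting,
                 stimuli = list(.soma_ap_stimulus(stim_site)),
                 members = list(.member("control"),
                                .member("passive", modifiers = ko)),
                 duration = duration, dt = dt, baseline_time = 5)
}

#' Protocol: steady-state length constant
#'
#' Long weak current pulse (-4 pA for 500 ms by default) into the 10th
#' bouton of the full model; the steady-state voltage deflection along the
#' chain yields the steady-state length constant.
#'
#' @param amplitude pulse current, nA (negative = hyperpolarizing).
#' @param pulse_duration pulse length, ms.
#' @param site injection site.
#' @param resting resting potential, mV.
#' @param dt time step, ms.
#' @return A \code{protocol_spec} with a single member \code{pulse}; the
#'   simulation ends at the end of the pulse so \code{v_final} is the
#'   steady-state profile.
#' @export
protocol_steady_state_lambda <- function(amplitude = -0.004,
                                         pulse_duration = 500,
                                         site = "bouton10", resting = -80,
                                         dt = 0.005) {
  onset <- 10
  .protocol_spec("steady_state_lambda", resting,
                 members = list(.member("pulse", stimuli = list(
                   stimulus_event(site, amplitude, onset, pulse_duration)))),
                 duration = onset + pulse_duration, dt = dt,
                 record_every = 20L, baseline_time = onset)
}

#' Protocol: voltage dependency of the after potential
#'
#' Full propagation runs at several resting potentials; for each one the
#' leak reversal is retuned so the all-channels steady state equals the
#' requested resting potential, then a somatic action potential is evoked
#' and the after potential at the distal bouton is measured with and without
#' baseline subtraction.
#'
#' @param resting_potentials resting potentials, mV (within [-120, -60]).
#' @param stim_site stimulation site (the reference experiments used the
#'   soma; bouton-9 stimulation is available by argument).
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @return A \code{protocol_spec} with one member per resting potential.
#' @export
protocol_voltage_dependency <- function(resting_potentials = c(-80, -90, -100),
                                        stim_site = "soma",
                                        duration = 60, dt = 0.005) {
  if (any(resting_potentials < -120 | resting_potentials > -60))
    stop("resting potentials must lie within [-120, -60] mV")
  members <- lapply(resting_potentials, function(rp)
    .member(paste0("rest_", rp), value = rp, resting = rp))
  .protocol_spec("voltage_dependency", resting_potentials[1],
                 stimuli = list(.soma_ap_stimulus(stim_site)),
                 members = members, duration = duration, dt = dt,
                 baseline_time = 5)
}

#' Protocol: ionic/capacitive component decomposition
#'
#' Three runs sharing one somatic stimulus: control; K+ conductance removed
#' from the 10th axon and bouton; Na+ and K+ conductance removed from the
#' same region. Subtracting the bouton-10 traces isolates the Na+-channel,
#' K+-channel and capacitive components of the propagating action potential.
#'
#' @param resting resting potential, mV.
#' @param region sections whose conductances are removed.
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @return A \code{protocol_spec} with members \code{control}, \code{no_K},
#'   \code{no_NaK}.
#' @export
protocol_component_decomposition <- function(resting = -80,
                                             region = c("axon10", "bouton10"),
                                             duration = 60, dt = 0.005) {
  .protocol_spec("component_decomposition", resting,
                 stimuli = list(.soma_ap_stimulus()),
                 members = list(
                   .member("control"),
                   .member("no_K", modifiers = list(
                     region_modifier(region, "remove_gK"))),
                   .member("no_NaK", modifiers = list(
                     region_modifier(region, "remove_gNa"),
                     region_modifier(region, "remove_gK")))),
                 duration = duration, dt = dt, baseline_time = 5)
}

#' Protocol: local K+ reversal (E_K10) sweep
#'
#' Overrides the K+ reversal potential in the 10th axon and bouton only, to
#' vary the local K+ driving force; each value has an active member and a
#' passive companion (Na+ and K+ conductances removed from the same region)
#' whose traces must be unaffected by the override.
#'
#' @param values E_K10 values, mV.
#' @param resting resting potential, mV.
#' @param region overridden sections.
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @return A \code{protocol_spec} with members \code{active_<v>} and
#'   \code{passive_<v>} per value.
#' @export
protocol_EK10_sweep <- function(values = c(-65, -75, -85, -95, -105),
                                resting = -80,
                                region = c("axon10", "bouton10"),
                                duration = 60, dt = 0.005) {
  if (any(!is.finite(values))) stop("E_K10 values must be finite")
  members <- list()
  for (v in values) {
    members[[length(members) + 1]] <- .member(
      paste0("active_", v), value = v,
      modifiers = list(region_modifier(region, "set_EK", v)))
    members[[length(members) + 1]] <- .member(
      paste0("passive_", v), value = v,
      modifiers = list(region_modifier(region, "set_EK", v),
                       region_modifier(region, "remove_gNa"),
                       region_modifier(region, "remove_gK")))
  }
  .protocol_spec("EK10_sweep", resting,
                 stimuli = list(.soma_ap_stimulus()),
                 members = members, duration = duration, dt = dt,
                 baseline_time = 5)
}

#' Protocol: current-step family at the recorded bouton
#'
#' Standing current steps (+1 to -6 pA by default) at the 10th bouton,
#' each with a propagated action potential (somatic stimulus) superimposed
#' 50 ms after step onset. The step-response relaxation and the late phase
#' of the after potential are recorded for time-constant comparison.
#'
#' @param steps_pA step currents, pA.
#' @param resting resting potential, mV.
#' @param site step-injection and recording site.
#' @param step_onset step onset, ms.
#' @param ap_onset somatic stimulus onset, ms (default 50 ms after the
#'   step).
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @return A \code{protocol_spec} with one member per step; the 0 pA member
#'   reproduces the plain propagation run.
#' @export
protocol_step_family <- function(steps_pA = c(1, 0, -1, -2, -3, -4, -5, -6),
                                 resting = -80, site = "bouton10",
                                 step_onset = 10, ap_onset = 60,
                                 duration = 110, dt = 0.005) {
  members <- lapply(steps_pA, function(p) {
    stim <- if (p != 0) list(stimulus_event(site, p / 1000, step_onset,
                                            duration - step_onset))
    .member(paste0("step_", p, "pA"), value = p, stimuli = stim)
  })
  .protocol_spec("step_family", resting,
                 stimuli = list(.soma_ap_stimulus(onset = ap_onset)),
                 members = members, duration = duration, dt = dt,
                 baseline_time = step_onset)
}

#' Protocol: specific-membrane-capacitance sweep
#'
#' Repeats the distal-knockout passive-propagation run with the specific
#' membrane capacitance of the passive (knocked-out) region set to each
#' value; cable filtering by the membrane capacitance reduces and prolongs
#' the passively propagated component as Cm grows. The Cm = 1 uF/cm^2 member
#' is identical to the plain passive-propagation run.
#'
#' @param values Cm values, uF/cm^2.
#' @param resting resting potential, mV.
#' @param knockout_start first knocked-out section.
#' @param duration simulated time, ms.
#' @param dt time step, ms.
#' @return A \code{protocol_spec} with one member per Cm value.
#' @export
protocol_Cm_sweep <- function(values = c(0.5, 1, 2), resting = -80,
                              knockout_start = "axon8",
                              duration = 60, dt = 0.005) {
  if (any(values <= 0)) stop("Cm values must be positive")
  region <- list(from = knockout_start)
  members <- lapply(values, function(cm)
    .member(paste0("Cm_", cm), value = cm, modifiers = list(
      region_modifier(region, "remove_gNa"),
      region_modifier(region, "remove_gK"),
      region_modifier(region, "set_Cm", cm))))
  .protocol_spec("Cm_sweep", resting,
                 stimuli = list(.soma_ap_stimulus()),
                 members = members, duration = duration, dt = dt,
                 baseline_time = 5)
}

#' Run a protocol
#'
#' Builds (or takes) the base chain, then for every member applies the
#' protocol-level and member-level modifiers, retunes the leak reversal to
#' the member's resting potential, and integrates. Everything is
#' deterministic: identical inputs give identical trace sets.
#'
#' @param spec a \code{protocol_spec}.
#' @param chain base chain; \code{NULL} builds the default mossy-fiber
#'   model.
#' @param record_sites,method,use_kinact overrides passed to the solver.
#' @return An object of class \code{protocol_result}: list with the spec,
#'   the base chain, and one \code{trace_set} per member under \code{runs}.
#' @export
run_protocol <- function(spec, chain = NULL, record_sites = NULL,
                         method = "backward_euler", use_kinact = TRUE) {
  stopifnot(inherits(spec, "protocol_spec"))
  base <- if (is.null(chain)) build_mossy_fiber_model() else chain
  sites <- if (is.null(record_sites)) spec$record_sites else record_sites
  runs <- list()
  for (member in spec$members) {
    rp <- if (is.null(member$resting)) spec$resting else member$resting
    ch <- apply_modifiers(base, c(spec$modifiers, member$modifiers))
    if (!identical(spec$retune, "none"))
      ch <- retune_leak_reversal(ch, rp, mode = spec$retune)
    st <- simulation_settings(duration = spec$duration, dt = spec$dt,
                              record_sites = sites, method = method,
                              resting_potential = rp,
                              record_every = spec$record_every,
                              record_currents = spec$record_currents,
                              baseline_time = spec$baseline_time)
    runs[[member$label]] <- integrate_chain(ch, st,
                                            c(spec$stimuli, member$stimuli),
                                            use_kinact = use_kinact)
  }
  structure(list(spec = spec, chain = base, runs = runs),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result> ", x$spec$name, ": runs ",
      paste(names(x$runs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

.unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .unclass_deep)
    attr(x, "class") <- NULL
  }
  x
}

#' Serialize / restore a protocol
#'
#' A protocol re-run from its serialized form produces identical output.
#'
#' @param spec a \code{protocol_spec}.
#' @param path YAML file path.
#' @return \code{protocol_to_yaml}: \code{path}, invisibly;
#'   \code{protocol_from_yaml}: the restored \code{protocol_spec}.
#' @export
protocol_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "protocol_spec"))
  yaml::write_yaml(.unclass_deep(unclass(spec)), path, precision = 15)
  invisible(path)
}

#' @rdname protocol_to_yaml
#' @export
protocol_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  restim <- function(s) do.call(stimulus_event, s)
  remod <- function(m) region_modifier(m$region, m$action, m$value)
  x$stimuli <- lapply(x$stimuli, restim)
  x$modifiers <- lapply(x$modifiers, remod)
  x$members <- lapply(x$members, function(m) {
    m$stimuli <- lapply(m$stimuli, restim)
    m$modifiers <- lapply(m$modifiers, remod)
    m
  })
  x$record_every <- as.integer(x$record_every)
  class(x) <- "protocol_spec"
  x
}
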
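test_that("regional modifiers compose and validate their regions", {
  chain <- build_mossy_fiber_model()
  both <- apply_modifiers(chain, list(
    region_modifier(c("axon10", "bouton10"), "remove_gK"),
    region_modifier(c("axon10", "bouton10"), "remove_gNa")))
  stepwise <- apply_modifiers(
    apply_modifiers(chain, region_modifier(c("axon10", "bouton10"), "remove_gK")),
    region_modifier(c("axon10", "bouton10"), "remove_gNa"))
  expect_identical(both, stepwise)

  idx <- chain$segments$section %in% c("axon10", "bouton10")
  expect_true(all(both$segments$gna[idx] == 0) && all(both$segments$gk[idx] == 0))
  expect_identical(both$segments[!idx, ], chain$segments[!idx, ])  # geometry untouched

  expect_error(apply_modifiers(chain, region_modifier("axon99", "remove_gK")),
               "unknown section")
  expect_error(region_modifier("axon10", "set_EK"), "requires a finite value")
  expect_error(region_modifier("axon10", "set_Cm", -1), "positive")
})

test_that("an empty knockout reproduces the control run exactly", {
  spec <- protocol_passive_propagation(knockout_start = NULL, duration = 15,
                                       dt = 0.01)
  res <- run_protocol(spec, record_sites = c("bouton8", "bouton10"))
  expect_identical(res$runs$control$vm, res$runs$passive$vm)
})

test_that("the knockout must not cover the stimulated site", {
  expect_error(protocol_passive_propagation(knockout_start = "soma"),
               "must not cover the stimulated site")
})

test_that("passive depolarization decays with distance beyond the knockout", {
  pp <- cached_passive_propagation()
  ts <- pp$runs$passive
  idx <- vapply(paste0("bouton", 8:10), function(s) site_index(pp$chain, s),
                integer(1))
  amps <- ts$peaks$amplitude[idx]
  expect_true(all(diff(amps) < 0))            # strictly decreasing
  # and the fitted decay length is recovered by the fitting module
  prof <- decay_profile(ts, pp$chain, "bouton7")
  fit <- fit_spatial_decay(prof$distance, prof$amplitude)
  expect_true(is.finite(fit$decay_constant) && fit$decay_constant > 0)
  expect_lt(fit$rms_residual, 0.05 * max(prof$amplitude))
})

test_that("steady-state deflections decay monotonically and scale linearly", {
  # linearity suffices on a shorter pulse; the full 500 ms run is exercised
  # by the length-constant measurement
  s1 <- protocol_steady_state_lambda(amplitude = -0.004, pulse_duration = 80,
                                     dt = 0.01)
  s2 <- protocol_steady_state_lambda(amplitude = -0.008, pulse_duration = 80,
                                     dt = 0.01)
  r1 <- run_protocol(s1)$runs$pulse
  r2 <- run_protocol(s2)$runs$pulse
  chain <- build_mossy_fiber_model()
  bi <- vapply(paste0("bouton", 1:10), function(s) site_index(chain, s),
               integer(1))
  d1 <- r1$v_final[bi] - r1$v_base[bi]
  d2 <- r2$v_final[bi] - r2$v_base[bi]
  expect_true(all(d1 < 0))                     # hyperpolarizing deflection
  expect_true(all(diff(abs(d1)) > 0))          # grows toward the injected bouton
  expect_equal(d2, 2 * d1, tolerance = 0.02)   # near-linear small-signal regime
})

test_that("E_K10 sweep: passive companions identical, active early phase monotone", {
  spec <- protocol_EK10_sweep(values = c(-65, -85, -105), duration = 40)
  res <- run_protocol(spec, record_sites = "bouton10")
  expect_identical(res$runs[["passive_-65"]]$vm, res$runs[["passive_-85"]]$vm)
  expect_identical(res$runs[["passive_-65"]]$vm, res$runs[["passive_-105"]]$vm)
  lev <- vapply(c(-65, -85, -105), function(v)
    measure_afterpotential_level(res$runs[[paste0("active_", v)]], "bouton10",
                                 resting = -80), numeric(1))
  expect_true(all(diff(lev) < 0))              # monotone in E_K10
  expect_gt(lev[1], 0)                         # E_K10 = -65 mV: depolarizing
  expect_lt(lev[3], 0)                         # E_K10 = -105 mV: hyperpolarizing
})

test_that("the zero step of the step family reproduces the plain propagation run", {
  sf <- cached_step_family()
  spec <- sf$spec
  chain <- retune_leak_reversal(build_mossy_fiber_model(), spec$resting)
  st <- simulation_settings(duration = spec$duration, dt = spec$dt,
                            record_sites = "bouton10",
                            resting_potential = spec$resting,
                            record_currents = FALSE,
                            baseline_time = spec$baseline_time)
  plain <- integrate_chain(chain, st, spec$stimuli)
  expect_identical(sf$runs$step_0pA$vm, plain$vm)
})

test_that("hyperpolarizing steps relax like the late after-potential phase", {
  sf <- cached_step_family()
  taus <- vapply(paste0("step_", -(1:6), "pA"), function(lb)
    measure_step_tau(sf$runs[[lb]], "bouton10", onset = 10)$decay_constant,
    numeric(1))
  expect_true(all(is.finite(taus)))
  expect_lt(diff(range(taus)) / mean(taus), 0.05)  # amplitude-independent
  tau_ahp <- measure_afterpotential_tau(sf$runs$step_0pA,
                                        "bouton10")$decay_constant
  expect_lt(abs(mean(taus) - tau_ahp) / mean(taus), 0.15)
})

test_that("raising Cm reduces and prolongs the passive propagating component", {
  spec <- protocol_Cm_sweep(values = c(0.5, 1, 2))
  res <- run_protocol(spec, record_sites = c("bouton8", "bouton9"))
  get8 <- function(lb) {
    i <- site_index(res$chain, "bouton8")
    c(amp = res$runs[[lb]]$peaks$amplitude[i],
      tpk = res$runs[[lb]]$peaks$t_max[i])
  }
  m <- vapply(c("Cm_0.5", "Cm_1", "Cm_2"), get8, numeric(2))
  expect_true(all(diff(m["amp", ]) < 0))       # smaller with larger Cm
  expect_true(all(diff(m["tpk", ]) > 0))       # later peak with larger Cm

  # the Cm = 1 member is the plain passive-propagation run
  pp <- cached_passive_propagation()
  i8 <- site_index(pp$chain, "bouton8")
  expect_equal(res$runs$Cm_1$peaks$amplitude[i8], pp$runs$passive$peaks$amplitude[i8])
})

test_that("protocols serialize to YAML and re-run identically", {
  spec <- protocol_passive_propagation(duration = 10, dt = 0.01)
  f <- file.path(tempdir(), "protocol.yaml")
  protocol_to_yaml(spec, f)
  spec2 <- protocol_from_yaml(f)
  r1 <- run_protocol(spec, record_sites = "bouton8")
  r2 <- run_protocol(spec2, record_sites = "bouton8")
  expect_identical(r1$runs$passive$vm, r2$runs$passive$vm)
  expect_identical(r1$runs$control$vm, r2$runs$control$vm)
  unlink(f)
})

test_that("voltage-dependency protocol validates its resting range", {
  expect_error(protocol_voltage_dependency(c(-80, -130)), "within")
  expect_error(protocol_voltage_dependency(c(-50)), "within")
})
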
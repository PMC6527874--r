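test_that("a retuned chain holds its resting potential at every site", {
  chain <- retune_leak_reversal(build_mossy_fiber_model(), -80)
  st <- simulation_settings(duration = 500, dt = 0.025,
                            record_every = 400L, record_currents = FALSE)
  ts <- integrate_chain(chain, st)
  expect_lt(max(abs(ts$vm - (-80))), 0.1)          # recorded traces
  expect_lt(max(abs(ts$v_final - (-80))), 0.1)     # every segment at the end
})

test_that("a somatic stimulus evokes a spike at every bouton with increasing latency", {
  pp <- cached_passive_propagation()
  ts <- pp$runs$control
  b <- paste0("bouton", 1:10)
  idx <- vapply(b, function(s) site_index(pp$chain, s), integer(1))
  peaks <- ts$peaks[idx, ]
  expect_true(all(peaks$v_max > 0))                # overshooting spikes
  expect_true(all(diff(peaks$t_max) > 0))          # orderly propagation
})

test_that("passive cable response matches the analytic sealed-end solution", {
  L <- 500; d <- 1
  cab <- build_single_cable(L, d, passive = passive_params(E_leak = -80))
  x_stim <- cab$segments$x[100]
  st <- simulation_settings(duration = 20, dt = 0.01,
                            record_sites = c(100, 250, 400),
                            record_currents = FALSE)
  ts <- integrate_chain(cab, st, stimulus_event(100, 0.01, 0, 20))
  for (seg in c(250, 400)) {
    tr <- get_trace(ts, paste0("seg", seg))
    sel <- tr$time >= 1
    oracle <- analytic_sealed_cable_response(cab$segments$x[seg],
                                             tr$time[sel], L, d,
                                             Cm = 1, Rm = 10000, Ri = 110,
                                             I_nA = 0.01, x_stim = x_stim)
    dev <- tr$value[sel] + 80
    expect_lt(max(abs(dev - oracle)) / max(abs(oracle)), 0.01)
  }
})

test_that("per-step current balance holds to 1e-6 of the peak current", {
  chain <- retune_leak_reversal(build_mossy_fiber_model(), -80)
  st <- simulation_settings(duration = 25, record_sites = c("soma", "axon5",
                                                            "bouton10"),
                            baseline_time = 5)
  ts <- integrate_chain(chain, st, stimulus_event("soma", 0.2, 5, 2))
  imbalance <- ts$i_cap + ts$i_na + ts$i_k + ts$i_leak + ts$i_axial - ts$i_stim
  for (site in ts$sites) {
    peak <- max(abs(ts$i_na[, site]), abs(ts$i_cap[, site]))
    expect_lt(max(abs(imbalance[, site])) / peak, 1e-6, label = site)
  }
})

test_that("Crank-Nicolson agrees with backward Euler and conserves charge", {
  chain <- retune_leak_reversal(build_mossy_fiber_model(), -80)
  st <- simulation_settings(duration = 20, record_sites = "bouton5",
                            method = "crank_nicolson", baseline_time = 5)
  stim <- stimulus_event("soma", 0.2, 5, 2)
  ts_cn <- integrate_chain(chain, st, stim)
  imbalance <- ts_cn$i_cap + ts_cn$i_na + ts_cn$i_k + ts_cn$i_leak +
    ts_cn$i_axial - ts_cn$i_stim
  expect_lt(max(abs(imbalance)) / max(abs(ts_cn$i_na)), 1e-6)

  st$method <- "backward_euler"
  ts_be <- integrate_chain(chain, st, stim)
  expect_lt(abs(max(ts_cn$vm) - max(ts_be$vm)), 1)   # peak Vm within 1 mV
})

test_that("without Na+ conductance no regenerative spike can occur", {
  st <- simulation_settings(duration = 30, record_sites = c("soma", "bouton1"),
                            record_currents = FALSE, baseline_time = 5)
  stim <- stimulus_event("soma", 0.2, 5, 2)
  no_na <- retune_leak_reversal(
    build_mossy_fiber_model(gna_axon = 0, gna_soma = 0), -80)
  passive <- retune_leak_reversal(
    build_mossy_fiber_model(gna_axon = 0, gna_soma = 0, gk = 0), -80)
  ts_nona <- integrate_chain(no_na, st, stim)
  ts_pass <- integrate_chain(passive, st, stim)
  # peak depolarization never exceeds the stimulus-driven passive response
  # (K+ channels can only shunt it)
  expect_lt(max(ts_nona$peaks$v_max), max(ts_pass$peaks$v_max) + 1e-6)
  # and scaling is sub-linear, not regenerative
  ts_half <- integrate_chain(no_na, st, stimulus_event("soma", 0.1, 5, 2))
  ratio <- max(ts_nona$peaks$amplitude) / max(ts_half$peaks$amplitude)
  expect_gt(ratio, 1)
  expect_lt(ratio, 2)

  # the full model, in contrast, overshoots 0 mV at the boutons
  full <- retune_leak_reversal(build_mossy_fiber_model(), -80)
  ts_full <- integrate_chain(full, st, stim)
  expect_gt(max(ts_full$peaks$v_max), 0)
  expect_lt(max(ts_nona$peaks$v_max), 0)
})

test_that("a fully passive chain responds linearly in the stimulus", {
  chain <- build_mossy_fiber_model(gna_axon = 0, gna_soma = 0, gk = 0)
  chain <- retune_leak_reversal(chain, -80)
  st <- simulation_settings(duration = 30, record_sites = c("soma", "bouton5"),
                            record_currents = FALSE)
  t1 <- integrate_chain(chain, st, stimulus_event("bouton10", -0.004, 5, 20))
  t2 <- integrate_chain(chain, st, stimulus_event("bouton10", -0.012, 5, 20))
  dev1 <- t1$vm + 80
  dev2 <- t2$vm + 80
  expect_equal(dev2, 3 * dev1, tolerance = 1e-6)
})

test_that("passive transfer is reciprocal between injection and recording sites", {
  chain <- build_mossy_fiber_model(gna_axon = 0, gna_soma = 0, gk = 0)
  chain <- retune_leak_reversal(chain, -80)
  st_ab <- simulation_settings(duration = 25, record_sites = "bouton6",
                               record_currents = FALSE)
  st_ba <- simulation_settings(duration = 25, record_sites = "soma",
                               record_currents = FALSE)
  ab <- integrate_chain(chain, st_ab, stimulus_event("soma", 0.01, 2, 15))
  ba <- integrate_chain(chain, st_ba, stimulus_event("bouton6", 0.01, 2, 15))
  expect_equal(ab$vm[, "bouton6"], ba$vm[, "soma"], tolerance = 1e-9)
})

test_that("identical inputs produce identical trace sets", {
  chain <- retune_leak_reversal(build_mossy_fiber_model(), -80)
  st <- simulation_settings(duration = 10, record_sites = "bouton3",
                            baseline_time = 2)
  stim <- stimulus_event("soma", 0.2, 2, 2)
  expect_identical(integrate_chain(chain, st, stim),
                   integrate_chain(chain, st, stim))
})

test_that("non-finite voltages abort with a diagnostic naming segment and time", {
  chain <- build_single_cable(10, 1, gna = 50, gk = 36)
  chain$segments$e_leak[3] <- NaN     # corrupted model parameter
  st <- simulation_settings(duration = 5, record_sites = 5)
  expect_error(integrate_chain(chain, st, stimulus_event(5, 0.01, 1, 1)),
               "non-finite membrane potential in segment")
})

test_that("capacitive current from a voltage trace", {
  t <- seq(0, 1, by = 0.01)
  cm <- 1; area <- 50
  expect_equal(capacitive_current(t, rep(-80, length(t)), cm, area),
               rep(0, length(t)))
  # ramp of slope s -> constant Cm * area * s
  s <- 12
  expect_equal(capacitive_current(t, -80 + s * t, cm, area),
               rep(1000 * cm * area * 1e-8 * s, length(t)))
  expect_error(capacitive_current(c(0, 1), c(1, 2), cm, area), "3 samples")
})

test_that("time-step self-convergence behaves as expected", {
  # identical dt in both runs -> exactly zero discrepancy
  chain <- build_single_cable(100, 1)
  chain <- retune_leak_reversal(chain, -80)
  st <- simulation_settings(duration = 10, dt = 0.01, record_sites = 50,
                            record_currents = FALSE)
  stim <- stimulus_event(50, 0.005, 1, 5)
  rep0 <- check_convergence(chain, st, list(stim), factor = 1)
  expect_identical(rep0$max_pointwise, 0)

  # passive model: dt halving changes the response by well under 0.01 mV
  rep2 <- check_convergence(chain, st, list(stim), factor = 2)
  expect_lt(rep2$max_peak_diff, 0.01)
})

test_that("trace sets export to tidy tables and CSV with metadata sidecar", {
  chain <- build_single_cable(50, 1)
  st <- simulation_settings(duration = 2, dt = 0.01, record_sites = 25)
  ts <- integrate_chain(chain, st, stimulus_event(25, 0.01, 0.5, 1))
  df <- as.data.frame(ts)
  expect_true(all(c("time", "vm.seg25", "i_cap.seg25") %in% names(df)))
  f <- file.path(tempdir(), "traces.csv")
  write_traces(ts, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".meta.yaml")))
  back <- utils::read.csv(f)
  expect_equal(back$vm.seg25, unname(ts$vm[, 1]), tolerance = 1e-12)
  unlink(c(f, paste0(f, ".meta.yaml")))
})

test_that("global leak retuning settles the requested site to the target", {
  chain <- build_mossy_fiber_model()
  tuned <- retune_leak_reversal(chain, -90, mode = "global",
                                settle_duration = 200)
  st <- simulation_settings(duration = 100, dt = 0.025,
                            record_sites = "bouton10",
                            resting_potential = -90, record_every = 400L,
                            record_currents = FALSE)
  ts <- integrate_chain(tuned, st)
  expect_equal(ts$v_final[site_index(tuned, "bouton10")], -90,
               tolerance = 0.05)
  # a single global value cannot pin the soma exactly, but it stays close
  expect_lt(abs(ts$v_final[site_index(tuned, "soma")] + 90), 3)
})
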
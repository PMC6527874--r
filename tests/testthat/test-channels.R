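test_that("steady-state gates stay in [0,1] across the physiological range", {
  v <- seq(-120, 60, by = 2.5)
  for (scheme in c("hh_mf", "hh_squid")) {
    ss <- steady_state_gates(v, scheme)
    for (g in c("m", "h", "n", "k_inact")) {
      expect_true(all(ss[[g]] >= 0 & ss[[g]] <= 1), label = paste(scheme, g))
    }
    r <- gating_rates(v, scheme)
    expect_true(all(r$alpha >= 0) && all(r$beta >= 0))
  }
})

test_that("limiting behavior at strong hyperpolarization: m ~ 0, h ~ 1", {
  ss <- steady_state_gates(-120)
  expect_lt(ss$m, 0.01)
  expect_gt(ss$h, 0.95)
})

test_that("steady state is a fixed point of the gating update", {
  for (v in c(-100, -80, -50, 0)) {
    ss <- steady_state_gates(v)
    out <- advance_gating(ss, v, dt = 0.5)
    expect_equal(out, ss, tolerance = 1e-12)
  }
})

test_that("gates relax to the steady state of a held potential", {
  state <- steady_state_gates(-80)
  for (i in 1:2000) state <- advance_gating(state, 0, dt = 0.05)  # 100 ms >> tau
  target <- steady_state_gates(0)
  for (g in c("m", "h", "n"))
    expect_equal(state[[g]], target[[g]], tolerance = 1e-8)
})

test_that("dt -> 0 limit of the exponential update matches the rate ODE slope", {
  v <- -55
  state <- steady_state_gates(-80)
  dt <- 1e-7
  out <- advance_gating(state, v, dt)
  r <- gating_rates(v)
  for (i in 1:3) {
    g <- c("m", "h", "n")[i]
    slope <- (out[[g]] - state[[g]]) / dt
    expected <- unname(r$alpha[, i] * (1 - state[[g]]) -
                         r$beta[, i] * state[[g]])
    expect_equal(slope, expected, tolerance = 1e-4, label = g)
  }
})

test_that("gating trajectory under a clamped voltage staircase matches an
           independent high-accuracy ODE integration", {
  v_steps <- c(-80, -20, -55, 10, -90)
  step_len <- 1                    # ms
  dt <- 0.05
  # package path: exponential update stepping through the staircase
  state <- steady_state_gates(v_steps[1])
  traj <- state
  for (v in v_steps) {
    for (i in seq_len(step_len / dt)) traj <- advance_gating(traj, v, dt)
  }
  # oracle: deSolve integration of dx/dt = alpha(V)(1-x) - beta(V)x with the
  # same piecewise-constant V(t)
  v_of_t <- function(t) v_steps[pmin(length(v_steps), floor(t / step_len) + 1)]
  rhs <- function(t, y, parms) {
    r <- gating_rates(v_of_t(t))
    list(c(r$alpha[, 1] * (1 - y[1]) - r$beta[, 1] * y[1],
           r$alpha[, 2] * (1 - y[2]) - r$beta[, 2] * y[2],
           r$alpha[, 3] * (1 - y[3]) - r$beta[, 3] * y[3]))
  }
  y0 <- unlist(steady_state_gates(v_steps[1])[c("m", "h", "n")])
  sol <- deSolve::ode(y0, times = seq(0, length(v_steps) * step_len, by = step_len),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  final <- sol[nrow(sol), -1]
  expect_equal(unname(c(traj$m, traj$h, traj$n)), unname(final),
               tolerance = 1e-6)
})

test_that("ionic currents follow the conductance equations and sign convention", {
  st <- list(m = 0.4, h = 0.6, n = 0.5, k_inact = 0.9)
  area <- 50

  # zero driving force
  expect_equal(ionic_current(-85, st, channel_spec("K", 36, -85), area), 0)

  # saturated Na gates at V = 0, E_Na = +50: inward, -g*area*50
  sat <- list(m = 1, h = 1, n = 0, k_inact = 1)
  expect_equal(ionic_current(0, sat, channel_spec("Na", 50, 50), area),
               -1000 * 50 * (area * 1e-8) * 50)

  # K inactivation acts multiplicatively; k_inact = 1 recovers pure n^4
  i_full <- ionic_current(-20, st, channel_spec("K", 36, -85), area)
  st1 <- st; st1$k_inact <- 1
  expect_equal(i_full, 0.9 * ionic_current(-20, st1, channel_spec("K", 36, -85), area))

  # leak ignores gating
  expect_equal(ionic_current(-80, st, channel_spec("leak", 0.1, -81), area),
               1000 * 0.1 * (area * 1e-8) * (-80 + 81))
})

test_that("the balancing leak reversal zeroes the net membrane current at rest", {
  v <- -80
  el <- pearlchain:::.balancing_e_leak(v, gna = 50, gk = 36, e_na = 50,
                                       e_k = -85, gl = 0.1, scheme = "hh_mf")
  st <- steady_state_gates(v)
  area <- 100
  total <- ionic_current(v, st, channel_spec("Na", 50, 50), area) +
    ionic_current(v, st, channel_spec("K", 36, -85), area) +
    ionic_current(v, st, channel_spec("leak", 0.1, el), area)
  expect_equal(total, 0, tolerance = 1e-12)
})

test_that("the gating registry validates and lists schemes", {
  expect_true(all(c("hh_mf", "hh_squid") %in% list_gating_schemes()))
  expect_error(gating_scheme("no_such_scheme"), "unknown gating scheme")
  expect_error(register_gating_scheme("hh_mf", pearlchain:::.hh_rate_matrix()),
               "already registered")
  expect_error(register_gating_scheme("bad", matrix(0, 2, 2)), "6 x 4")
})
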
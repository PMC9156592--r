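test_that("instantaneous balance: no gradients, Ohm analog, and dense-assembly oracle", {
  sc <- baseline_scenario()
  net <- sc$network
  C <- net$compartments$C

  # all alveolar pressures equal to the applied airway pressure: no flow
  sol <- instantaneous_solve(net, v = C * 7, p_aw = 7)
  expect_equal(unname(sol$Q), rep(0, 5), tolerance = 1e-12)

  # single-compartment degenerate network: Q = (P_aw - v/C)/R_total
  one <- single_comp_net(R0 = 1, R_A = 2, C = 0.05)
  sol1 <- instantaneous_solve(one, v = 0.05 * 3, p_aw = 10)
  expect_equal(unname(sol1$Q), (10 - 3) / 3, tolerance = 1e-12)

  # baseline at PEEP-equilibrium volumes, prescribed flow: flows sum to the
  # prescription and match an independently assembled Kirchhoff solve
  v <- C * 2
  sol <- instantaneous_solve(net, v, q_aw = 1.7)
  expect_equal(sum(sol$Q), 1.7, tolerance = 1e-10)
  orc <- oracle_kirchhoff(net, v, list(q_aw = 1.7))
  expect_equal(sol$Q, orc$Q, tolerance = 1e-10)
  expect_equal(sol$P_aw, unname(orc$P_aw), tolerance = 1e-10)

  # and for the pressure boundary, over several states
  set.seed(7)
  for (r in 1:5) {
    v <- C * runif(5, 0, 12)
    paw <- runif(1, 0, 20)
    expect_equal(instantaneous_solve(net, v, p_aw = paw)$Q,
                 oracle_kirchhoff(net, v, list(p_aw = paw))$Q,
                 tolerance = 1e-10)
  }
})

test_that("phase simulation matches single-compartment RC closed forms", {
  R0 <- 1; RA <- 2; C <- 0.05; Rt <- R0 + RA
  net <- single_comp_net(R0 = R0, R_A = RA, C = C)

  # equilibrium is a fixed point of passive expiration
  eq <- simulate_phase(net, list(p_aw = 2), state0 = C * 2, duration = 5)
  expect_lt(max(abs(eq$v - C * 2)), 1e-9)

  # CF: the single leaf takes all the flow, V(t) = Q_aw t exactly
  cf <- make_drive(ventilator_settings("CF", 2, 1, 3, q_aw = 0.4))
  ph <- simulate_phase(net, cf, state0 = C * 2, duration = 1)
  expect_lt(max(abs((ph$v - C * 2) - 0.4 * ph$time)), 1e-6)

  # CP inspiration: saturating exponential toward C P_set
  p_set <- 12; v0 <- C * 2
  cp <- make_drive(ventilator_settings("CP", 2, 1, 3, p_set = p_set))
  ph <- simulate_phase(net, cp, state0 = v0, duration = 1)
  v_exact <- C * p_set + (v0 - C * p_set) * exp(-ph$time / (Rt * C))
  expect_lt(max(abs(ph$v - v_exact)), 1e-6)

  # passive expiration: RC discharge toward C PEEP
  v0 <- 0.45
  ph <- simulate_phase(net, list(p_aw = 2), state0 = v0, duration = 2)
  v_exact <- C * 2 + (v0 - C * 2) * exp(-ph$time / (Rt * C))
  expect_lt(max(abs(ph$v - v_exact)), 1e-6)

  # DF / SF: forced linear ODE, checked against high-order quadrature of the
  # variation-of-constants integral
  for (m in c("DF", "SF")) {
    amp <- 1.4
    args <- list(m, peep = 2, ti = 1, ttot = 3)
    args[["q_max"]] <- amp
    d <- make_drive(do.call(ventilator_settings, args))
    ph <- simulate_phase(net, d, state0 = C * 2, duration = 1, dt = 0.1)
    # dv/dt = Q_aw(t) for a single compartment under prescribed flow
    v_exact <- C * 2 + vapply(ph$time, function(tt)
      if (tt == 0) 0 else pracma::integral(d$waveform, 0, tt, reltol = 1e-12),
      numeric(1))
    expect_lt(max(abs(ph$v - v_exact)), 1e-6)
  }
})

test_that("periodic steady state equals 200-cycle brute-force iteration", {
  sc <- baseline_scenario()
  traj <- baseline_traj("CF")
  v_iter <- oracle_iterate_cycles(sc$network, sc$ventilator, n_cycles = 200)
  expect_lt(max(abs(traj$v_star - v_iter)), 1e-8)
})

test_that("steady state is unique: same fixed point from zero and from 2x it", {
  sc <- baseline_scenario()
  circ <- ventstrain:::circuit_matrices(sc$network)
  cyc <- ventstrain:::cycle_end_fun(circ, sc$ventilator)
  ss <- ventstrain:::periodic_state_core(sc$network, sc$ventilator)
  # run a few cycles from 2x the fixed point; affine map must pull back
  v <- 2 * ss$v_star
  for (k in 1:40) v <- cyc(v)$end
  expect_lt(max(abs(v - ss$v_star)), 1e-9)
})

test_that("with expiratory time far beyond all time constants, P_ex collapses to PEEP", {
  sc <- baseline_scenario()
  s <- ventilator_settings("CF", peep = 2, ti = 1, ttot = 60, q_aw = 1.7)
  traj <- find_periodic_steady_state(sc$network, s, dt = 0.01)
  expect_lt(max(abs(traj$P_ex - 2)), 0.01)
})

test_that("airways store no gas: compartmental volumes sum to the inspired volume", {
  # composite Simpson on the uniform inspiration grid (odd point count)
  simpson <- function(t, f) {
    n <- length(t); h <- t[2] - t[1]
    stopifnot(n %% 2 == 1)
    sum(h / 3 * (f[seq(1, n - 2, 2)] + 4 * f[seq(2, n - 1, 2)] +
                   f[seq(3, n, 2)]))
  }
  for (m in c("CF", "DF", "SF", "CP")) {
    traj <- baseline_traj(m)
    ni <- traj$ti_index
    vt_quad <- simpson(traj$time[1:ni], traj$Q_aw[1:ni])
    expect_lt(abs(sum(traj$V[ni, ]) - vt_quad), 1e-6)
    if (m != "CP")
      expect_lt(abs(traj$V_T -
                      vt_of_drive(make_drive(traj$settings))), 1e-6)
    # node balance residuals along the whole trajectory
    expect_lt(flow_residuals(traj), 1e-6)
  }
})

test_that("equal terminal twins behave identically (symmetry of D and E)", {
  sc <- baseline_scenario()
  net <- sc$network
  net$compartments$R[net$compartments$label == "E"] <- 15
  net$compartments$C[net$compartments$label == "E"] <- 0.02
  traj <- find_periodic_steady_state(net, sc$ventilator)
  expect_lt(max(abs(traj$V[, "D"] - traj$V[, "E"])), 1e-9)
  expect_lt(max(abs(traj$Q[, "D"] - traj$Q[, "E"])), 1e-9)
  expect_equal(traj$P_ex[["D"]], traj$P_ex[["E"]], tolerance = 1e-10)
})

test_that("auto-PEEP grows when expiration is squeezed and vanishes when PEEP drops", {
  sc <- baseline_scenario()
  # shorter cycle -> less time to empty -> more trapped pressure
  short <- ventilator_settings("CF", 2, 1, 1.8, q_aw = 1.7)
  long <- ventilator_settings("CF", 2, 1, 5, q_aw = 1.7)
  p_short <- find_periodic_steady_state(sc$network, short)$P_ex
  p_long <- find_periodic_steady_state(sc$network, long)$P_ex
  expect_true(all(p_short > p_long))
  expect_true(all(p_long >= 2 - 1e-9))
})
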
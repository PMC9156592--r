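sc <- baseline_scenario()

test_that("modes matched to one tidal volume partition it differently", {
  mc <- mode_comparison(sc$network, sc$ventilator,
                        modes = c("CF", "DF", "CP"))
  vts <- vapply(mc$trajectories, function(tr) tr$V_T, numeric(1))
  expect_lt(max(abs(vts - 1.7)), 1e-4)
  # total compartmental volume conserved across modes ...
  tot <- tapply(mc$summary$V_T_comp, mc$summary$mode, sum)
  expect_lt(diff(range(tot)), 1e-4)
  # ... but the per-compartment split depends on the flow profile
  cf <- mc$summary[mc$summary$mode == "CF", ]
  df <- mc$summary[mc$summary$mode == "DF", ]
  expect_gt(max(abs(cf$V_T_comp - df$V_T_comp)), 1e-3)
  # per-mode elastic energy closes to the work integral of that mode's split
  for (m in c("CF", "DF", "CP")) {
    s <- mc$summary[mc$summary$mode == m, ]
    closed <- s$V_T_comp^2 / (2 * sc$network$compartments$C) +
      s$P_ex * s$V_T_comp
    expect_equal(s$A_ti, closed, tolerance = 1e-4)
  }
})

test_that("maximal strain rises monotonically with PEEP in every compartment and mode", {
  ps <- peep_sweep(sc$network, sc$ventilator,
                   peep_grid = c(0, 2, 5, 8, 11, 12.5))
  expect_true(all(ps$feasible))
  for (m in unique(ps$mode)) for (cc in unique(ps$compartment)) {
    s <- ps$S_max[ps$mode == m & ps$compartment == cc]
    expect_true(all(diff(s) >= -1e-9),
                label = sprintf("S_max nondecreasing in PEEP (%s/%s)", m, cc))
  }
  # P_ex = 0 limit: with zero PEEP and a long expiration, S_max collapses to
  # 1 + V_T_comp / V_rest
  s0 <- ventilator_settings("CF", peep = 0, ti = 1, ttot = 30, q_aw = 1.7)
  tr <- find_periodic_steady_state(sc$network, s0, dt = 5e-3)
  ms <- max_strain(tr)
  expect_equal(ms$S_max, 1 + ms$V_T_comp / sc$network$compartments$V_rest,
               tolerance = 1e-3)
})

test_that("PEEP sensitivity of maximal strain distributes differently under CP than under flow modes", {
  ps <- peep_sweep(sc$network, sc$ventilator, peep_grid = c(0, 12.5))
  inc <- function(m) {
    lo <- ps[ps$peep == 0 & ps$mode == m, ]
    hi <- ps[ps$peep == 12.5 & ps$mode == m, ]
    stats::setNames(hi$S_max - lo$S_max, lo$compartment)
  }
  C <- sc$network$compartments$C
  for (m in c("CF", "DF", "SF")) {
    # fixed flow amplitude: each compartment gains exactly C * dPEEP
    expect_equal(unname(inc(m)), C * 12.5, tolerance = 1e-6)
  }
  # fixed set pressure: smaller gains, differently ranked across compartments
  expect_true(all(inc("CP") < inc("CF")))
  expect_false(identical(order(-inc("CP")), order(-inc("CF"))))
})

test_that("strain rises with tidal volume at fixed peak flow, trapping gas as ti grows", {
  g <- vt_qmax_grid(sc$network, sc$ventilator,
                    vt_grid = seq(0.4, 1.6, by = 0.2),
                    qmax_grid = c(1.2, 3.4), modes = c("DF"))
  for (q in c(1.2, 3.4)) for (cc in unique(g$compartment)) {
    sub <- g[g$q_max == q & g$compartment == cc & g$feasible, ]
    expect_true(all(diff(sub$S_max) >= -1e-9),
                label = sprintf("S_max nondecreasing in VT (q=%g/%s)", q, cc))
    expect_true(all(diff(sub$P_ex) >= -1e-9),
                label = sprintf("P_ex nondecreasing in VT (q=%g/%s)", q, cc))
  }
  # slow peak flow + large VT squeezes expiration: flagged as auto-PEEP cells
  top <- g[g$q_max == 1.2 & g$vt_set == 1.6 & g$feasible, ]
  expect_true(all(top$auto_peep))
  # infeasible cells (ti >= ttot) are marked, not computed
  g2 <- vt_qmax_grid(sc$network, sc$ventilator, vt_grid = c(0.5, 2.5),
                     qmax_grid = c(1.2), modes = "DF")
  bad <- g2[g2$vt_set == 2.5, ]
  expect_true(all(!bad$feasible))
  expect_true(all(is.na(bad$S_max)))
})

test_that("maximal strain vs tidal volume turns superlinear once auto-PEEP builds", {
  g <- vt_qmax_grid(sc$network, sc$ventilator,
                    vt_grid = seq(1.0, 1.6, by = 0.1),
                    qmax_grid = c(1.2), modes = c("DF", "SF"))
  for (m in c("DF", "SF")) for (cc in unique(g$compartment)) {
    s <- g$S_max[g$mode == m & g$compartment == cc & g$feasible]
    expect_true(all(diff(diff(s)) > 0),
                label = sprintf("positive curvature at high VT (%s/%s)", m, cc))
  }
})

test_that("maximal strain falls as the inverse of resting volume", {
  vs <- vrest_sweep(sc$network, sc$ventilator,
                    vrest_grid = seq(0.2, 1.2, by = 0.2),
                    modes = c("CF", "CP"))
  for (m in unique(vs$mode)) for (cc in unique(vs$compartment)) {
    sub <- vs[vs$mode == m & vs$compartment == cc, ]
    expect_true(all(diff(sub$S_max) < 0))
    # (S_max - 1) V_rest is constant: strain is exactly inverse in V_rest
    expect_equal(diff(range((sub$S_max - 1) * sub$v_rest)), 0,
                 tolerance = 1e-9)
  }
  # decelerating and sinusoidal profiles change the picture only marginally
  vs4 <- vrest_sweep(sc$network, sc$ventilator,
                     vrest_grid = c(0.2, 0.7, 1.2),
                     modes = c("CF", "DF", "SF"))
  cf <- vs4[vs4$mode == "CF", ]
  for (m in c("DF", "SF")) {
    other <- vs4[vs4$mode == m, ]
    expect_lt(max(abs(other$S_max - cf$S_max) / cf$S_max), 0.10)
  }
})

test_that("heterogeneous resting volumes redistribute the maximal strains", {
  # uniform map reduces to the baseline run
  uni <- heterogeneous_vrest(sc$network, sc$ventilator,
                             vrest_map = c(A = 1, B = 1, C = 1, D = 1, E = 1))
  base <- max_strain(find_periodic_steady_state(sc$network, sc$ventilator))
  expect_equal(uni$S_max, base$S_max, tolerance = 1e-9)
  # preset: small rest volume for compliant A, large for stiff D
  h <- heterogeneous_vrest(sc$network, sc$ventilator)
  expect_equal(h$compartment[which.max(h$S_max)], "A")
  expect_equal(h$compartment[which.min(h$S_max)], "D")
  # doubling every rest volume halves every S_max - 1
  h2 <- heterogeneous_vrest(sc$network, sc$ventilator,
                            vrest_map = 2 * vrest_map_preset())
  expect_equal(h2$S_max - 1, (h$S_max - 1) / 2, tolerance = 1e-9)
})

test_that("sweeps are deterministic and each record re-derives its own strain", {
  g1 <- peep_sweep(sc$network, sc$ventilator, peep_grid = c(1, 4),
                   modes = c("CF", "CP"))
  g2 <- peep_sweep(sc$network, sc$ventilator, peep_grid = c(1, 4),
                   modes = c("CF", "CP"))
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  expect_identical(attr(g1, "scenario_hash"), attr(g2, "scenario_hash"))
  cp <- sc$network$compartments
  C <- cp$C[match(g1$compartment, cp$label)]
  vr <- cp$V_rest[match(g1$compartment, cp$label)]
  # exact from the stored peak volume; bounded below by the end-inspiratory one
  expect_equal(g1$S_max, 1 + (g1$v_peak + C * g1$P_ex) / vr)
  expect_true(all(g1$S_max >= 1 + (g1$V_T_comp + C * g1$P_ex) / vr - 1e-12))
})
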
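test_that("a spatially uniform resting tube is a fixed point", {
  tube <- tube_spec(n = 101, length = 0.5)
  r <- run_tube(tube, 100, inflow = 0, prox_bc = 1, dist_bc = 1, kr = 0)
  expect_false(r$failed)
  expect_equal(max(abs(r$A[100, ] / tube$A0 - 1)), 0)
  expect_equal(max(abs(r$q[100, ])), 0)
})

test_that("CFL time step scales linearly with grid spacing", {
  tube <- tube_spec(n = 101, length = 1)
  dt1 <- cardiovpd:::cpp_cfl_dt(tube$dx, tube$A0, rep(0, tube$n), tube$A0,
                                tube$f0, tube$rho, tube$p0, 0.9)
  dt2 <- cardiovpd:::cpp_cfl_dt(tube$dx / 2, tube$A0, rep(0, tube$n),
                                tube$A0, tube$f0, tube$rho, tube$p0, 0.9)
  expect_equal(dt1 / dt2, 2, tolerance = 1e-12)
  # with q = 0 the bound is safety * dx / c exactly
  c0 <- wave_speed(tube$A0[1], tube$A0[1], tube$r0,
                   wall_model(k1 = 0, k3 = 8e4))
  expect_equal(dt1, 0.9 * tube$dx / c0, tolerance = 1e-12)
})

test_that("a small pulse propagates at the analytic wave speed", {
  tube <- tube_spec(n = 301, length = 1.5, r0 = 0.01, f0 = 8e4)
  dt <- cardiovpd:::cpp_cfl_dt(tube$dx, tube$A0, rep(0, tube$n), tube$A0,
                               tube$f0, tube$rho, tube$p0, 0.5)
  nst <- round(0.35 / dt)
  infl <- inflow_pulse(nst, dt, amplitude = 3e-6, t0 = 0.04, width = 0.015)
  r <- run_tube(tube, nst, inflow = infl, prox_bc = 0, dist_bc = 0)
  expect_false(r$failed)
  i1 <- 51; i2 <- 251
  t1 <- wave_foot(r$p[, i1], r$dt)
  t2 <- wave_foot(r$p[, i2], r$dt)
  c_meas <- (i2 - i1) * tube$dx / (t2 - t1)
  c_true <- wave_speed(tube$A0[1], tube$A0[1], tube$r0,
                       wall_model(k1 = 0, k3 = 8e4))
  expect_lt(abs(c_meas / c_true - 1), 0.02)
})

test_that("boundary closures reflect as expected", {
  tube <- tube_spec(n = 301, length = 1.5, r0 = 0.01, f0 = 8e4)
  dt <- cardiovpd:::cpp_cfl_dt(tube$dx, tube$A0, rep(0, tube$n), tube$A0,
                               tube$f0, tube$rho, tube$p0, 0.5)
  nst <- round(0.35 / dt)
  infl <- inflow_pulse(nst, dt, amplitude = 3e-6, t0 = 0.04, width = 0.015)
  # non-reflecting end: residual pressure at mid-tube after the pulse
  # has left is far below the incident amplitude
  ra <- run_tube(tube, nst, inflow = infl, prox_bc = 0, dist_bc = 0)
  p_mid <- ra$p[, 151]
  pk <- max(p_mid) - tube$p0
  tail_start <- round(0.25 / ra$dt)
  expect_lt((max(p_mid[tail_start:nst]) - tube$p0) / pk, 0.01)
  # blocked end: pressure doubling, i.e. reflection coefficient near +1
  rb <- run_tube(tube, nst, inflow = infl, prox_bc = 0, dist_bc = 1)
  refl <- (max(rb$p[, 301]) - tube$p0) / pk
  expect_equal(refl, 2, tolerance = 0.02)
})

test_that("volume is conserved in a closed reflective tube", {
  tube <- tube_spec(n = 301, length = 1.5, r0 = 0.01, f0 = 8e4)
  x <- seq(0, tube$length, length.out = tube$n)
  A_init <- tube$A0 * (1 + 0.005 * exp(-((x - 0.75) / 0.1)^2))
  c0 <- wave_speed(tube$A0[1], tube$A0[1], tube$r0,
                   wall_model(k1 = 0, k3 = 8e4))
  dt <- cardiovpd:::cpp_cfl_dt(tube$dx, tube$A0, rep(0, tube$n), tube$A0,
                               tube$f0, tube$rho, tube$p0, 0.5)
  nst <- round(2 * tube$length / c0 / dt)  # one full round trip
  r <- run_tube(tube, nst, inflow = 0, prox_bc = 1, dist_bc = 1,
                A_init = A_init)
  v <- r$volume
  expect_lt(abs(v[length(v)] / v[1] - 1), 1e-8)
})

test_that("a transparent junction behaves as an uninterrupted tube", {
  ref <- default_reference()
  ps <- mean_parameter_set()
  one <- run_patient(apply_parameters(line_topology(FALSE, r_node_ref = 0),
                                      ps, ref), dx = 0.01)
  two <- run_patient(apply_parameters(line_topology(TRUE, r_node_ref = 0),
                                      ps, ref), dx = 0.01)
  expect_true(one$converged && two$converged)
  # same waveform at the shared distal site
  d <- one$site_p[, "distal"] - two$site_p[, "distal"]
  expect_lt(max(abs(d)) / diff(range(one$site_p[, "distal"])), 0.01)
})

test_that("nodal resistance produces the defining pressure drop", {
  ref <- default_reference()
  r_node <- 5e7
  topo <- line_topology(TRUE, r_node_ref = r_node)
  pat <- apply_parameters(topo, mean_parameter_set(), ref)
  sim <- run_patient(pat, dx = 0.01)
  expect_true(sim$converged)
  # sites "a_end" and "mid" flank the junction: the instantaneous drop
  # across it equals R_node times the junction flow
  drop <- sim$site_p[, "a_end"] - sim$site_p[, "mid"]
  q <- sim$site_q[, "mid"]
  keep <- abs(q) > 0.2 * max(abs(q))
  expect_equal(mean(drop[keep] / q[keep]), r_node, tolerance = 0.02)
})

test_that("junction flow balance is conserved to near machine precision", {
  sim <- reference_sim()
  expect_true(sim$converged)
  expect_lt(sim$junction_resid, 1e-10)
})

test_that("the reference patient reaches a periodic converged state", {
  sim <- reference_sim()
  expect_true(sim$converged)
  expect_false(sim$failed)
  expect_lte(sim$cycles, 40)
  # deterministic: identical model and controls give identical output
  pat <- apply_parameters(fixture_tree(), mean_parameter_set(),
                          default_reference())
  again <- run_patient(pat)
  expect_identical(again$site_p, sim$site_p)
  expect_identical(again$co, sim$co)
})

test_that("ideal-diode aortic valve never carries reverse flow", {
  sim <- reference_sim()
  q_av <- sim$heart$q_av
  expect_true(all(q_av >= 0))
  # while the valve is shut, ventricular pressure stays below the root
  # pressure except in the switching instants
  shut <- q_av == 0
  viol <- sim$heart$p_lv[shut] > sim$heart$p_root[shut] + 100
  expect_lt(mean(viol), 0.02)
})

test_that("elastance-driven ventricular pressure spans its design range", {
  sim <- reference_sim()
  p_lv <- sim$heart$p_lv
  v_lv <- sim$heart$v_lv
  h <- sim$patient$heart
  e_eff <- p_lv / (v_lv - h$lv$v0)
  expect_equal(min(e_eff), h$lv$e_min, tolerance = 0.02)
  expect_equal(max(e_eff), h$lv$e_max, tolerance = 0.02)
})

test_that("pathological parameters fail gracefully, not fatally", {
  ps <- mean_parameter_set()
  ps$R_perif <- 1e6
  pat <- apply_parameters(fixture_tree(), ps, default_reference())
  sim <- run_patient(pat, max_cycles = 6)
  expect_false(sim$converged)
  expect_true(nchar(sim$reason) > 0)
  # vacuous periodicity criterion: a single cycle runs
  pat0 <- apply_parameters(fixture_tree(), mean_parameter_set(),
                           default_reference())
  one <- run_patient(pat0, max_cycles = 1, periodicity_tol = Inf)
  expect_equal(one$cycles, 1)
})

test_that("halving the grid changes systolic aortic pressure by < 1%", {
  pat <- apply_parameters(fixture_tree(), mean_parameter_set(),
                          default_reference())
  coarse <- run_patient(pat, dx = 0.015)
  fine <- run_patient(pat, dx = 0.0075)
  sys_c <- max(coarse$site_p[, "aortic_root"])
  sys_f <- max(fine$site_p[, "aortic_root"])
  expect_lt(abs(sys_c / sys_f - 1), 0.01)
})

test_that("cardiac output equals stroke volume times heart rate", {
  pat <- apply_parameters(fixture_tree(), mean_parameter_set(),
                          default_reference())
  sim <- run_patient(pat, periodicity_tol = 1e-5, max_cycles = 80)
  sv <- max(sim$heart$v_lv) - min(sim$heart$v_lv)
  hr <- 1 / sim$period
  expect_equal(sv * hr, sim$co, tolerance = 1e-3)
})
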
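test_that("a fixed point of the dynamics is preserved by the integrator", {
  # no growth, no depletion, no thioesterase: the pre-equilibrated state is
  # a fixed point and must stay put
  p <- model_parameters(K_gr = 1e-12, k_nutr = 0, k_lim = 0, V_tes = 0)
  init <- pre_equilibrate(p)
  traj <- simulate_scenario(scenario(p, init = init, t_end = 500,
                                     output_dt = 50))
  for (v in c("AcylACP", "ppGpp", "rib", "I", "GFP", "N", "nutr", "lim"))
    expect_equal(traj$state[, v], rep(init[[v]], length(traj$time)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(max(abs(traj$state[, "FA"])), 0, tolerance = 1e-12)
})

test_that("the simulator is deterministic and the output grid is inert", {
  sc <- scenario(model_parameters(), t_end = 400, output_dt = 5)
  t1 <- simulate_scenario(sc)
  t2 <- simulate_scenario(sc)
  expect_identical(t1$state, t2$state)
  expect_identical(t1$time, t2$time)

  # halving output_dt must not change values at shared time points
  fine <- simulate_scenario(scenario(model_parameters(), t_end = 400,
                                     output_dt = 2.5))
  shared <- intersect(t1$time, fine$time)
  i1 <- match(shared, t1$time); i2 <- match(shared, fine$time)
  expect_equal(t1$state[i1, ], fine$state[i2, ], tolerance = 1e-7)
})

test_that("reported values converge under tolerance halving", {
  sc <- scenario(model_parameters(V_tes = 1.6))
  a <- simulate_scenario(sc, rtol = 1e-8, atol = 1e-10)
  b <- simulate_scenario(sc, rtol = 5e-9, atol = 5e-11)
  rel <- function(x, y) abs(x - y) / pmax(abs(y), 1e-9)
  expect_lt(rel(a$state[nrow(a$state), "FA"], b$state[nrow(b$state), "FA"]),
            1e-3)
  expect_lt(rel(a$state[nrow(a$state), "N"], b$state[nrow(b$state), "N"]),
            1e-3)
  expect_lt(rel(max(a$state[, "ppGpp"]), max(b$state[, "ppGpp"])), 1e-3)
  expect_lt(rel(peak_gfp(a)$GFP_peak, peak_gfp(b)$GFP_peak), 1e-3)
  expect_lt(rel(detect_phases(a)$t_phase1_end,
                detect_phases(b)$t_phase1_end), 1e-3)
})

test_that("state invariants hold along reference trajectories", {
  for (line in c("line0", "line3")) {
    traj <- ref_line(line)$trajectory
    expect_true(all(traj$state >= 0))
    for (v in c("I", "GFP", "nutr", "lim"))
      expect_true(all(traj$state[, v] <= 1 + 1e-9))
    # monotone depletion, up to absolute-tolerance noise at the floor
    expect_true(all(diff(traj$state[, "nutr"]) <= 1e-9))
    expect_true(all(diff(traj$state[, "lim"]) <= 1e-9))
    expect_true(all(traj$derived >= -1e-12))
    expect_true(all(traj$derived$P1P2 <= 1))
    expect_true(all(diff(traj$time) > 0))
  }
})

test_that("growth-phase boundaries are detected and ordered", {
  traj <- ref_line("line0")$trajectory
  ph <- detect_phases(traj)
  expect_gt(ph$t_phase1_end, 0)
  expect_gt(ph$t_phase2_end, ph$t_phase1_end)

  # a looser threshold is crossed earlier on a monotone depletion curve
  ph50 <- detect_phases(traj, threshold = 0.5)
  expect_lt(ph50$t_phase1_end, ph$t_phase1_end)

  # nutrients that never deplete signal "phase not reached"
  p <- model_parameters(k_lim = 0, k_nutr = 0)
  flat <- simulate_scenario(scenario(p, t_end = 200, output_dt = 20))
  expect_error(detect_phases(flat), class = "ppgpp_phase_not_reached")
})

test_that("events are applied as resets with continuous remaining state", {
  p <- model_parameters()
  traj <- simulate_with_upshift(p, output_dt = 1, t_end = 700)
  ev <- traj$events_applied
  expect_identical(ev$action, "set_lim")
  te <- ev$time[1]
  i <- which(traj$time == te)
  # lim jumps to the restored level right after the event; the slow states
  # stay continuous (the fast ones respond within seconds, which is
  # dynamics, not a reset)
  expect_lt(traj$state[i, "lim"], 0.01)
  expect_gt(traj$state[i + 1, "lim"], 0.95)
  for (v in c("N", "FA"))
    expect_equal(traj$state[i + 1, v], traj$state[i, v],
                 tolerance = 0.01, ignore_attr = TRUE)
  # restored nutrient reactivates ppGpp hydrolysis: ppGpp collapses towards
  # its exponential-phase level and stays below the pre-upshift value until
  # lim depletes again
  win <- traj$time > te & traj$time <= te + 20
  expect_lt(min(traj$state[win, "ppGpp"]), 0.3 * traj$state[i, "ppGpp"])
  expect_lt(max(traj$state[win, "ppGpp"]), traj$state[i, "ppGpp"])

  # a reset to the current value is a no-op for the dynamics
  sc_noop <- scenario(p, t_end = 400, output_dt = 5,
                      events = list(event_when("lim", 0.01, "set_lim", 0.01)))
  noop <- simulate_scenario(sc_noop)
  plain <- simulate_scenario(scenario(p, t_end = 400, output_dt = 5))
  shared <- intersect(noop$time, plain$time)
  expect_equal(noop$state[match(shared, noop$time), ],
               plain$state[match(shared, plain$time), ], tolerance = 1e-6)

  # the trigger never reached within the horizon is signalled
  expect_error(simulate_with_upshift(model_parameters(k_lim = 0),
                                     t_end = 200),
               class = "ppgpp_trigger_not_reached")
})

test_that("ppGpp clamping holds ppGpp fixed until released", {
  p <- model_parameters()
  sc <- scenario(p, init = model_state(), t_end = 300, output_dt = 10,
                 events = list(event_at(0, "clamp_ppGpp", 200),
                               event_at(200, "release_clamp")))
  traj <- simulate_scenario(sc)
  during <- traj$time > 0 & traj$time <= 200
  expect_true(all(abs(traj$state[during, "ppGpp"] - 200) < 1e-9))
  expect_gt(max(abs(traj$state[traj$time > 210, "ppGpp"] - 200)), 1)
})

test_that("ppGpp attains its maximum at the end of the exponential phase", {
  traj <- ref_line("line0")$trajectory
  ph <- detect_phases(traj)
  pk <- ppGppSim:::quad_peak(traj$time, traj$state[, "ppGpp"])
  expect_lt(abs(pk$t - ph$t_phase1_end), traj$scenario$output_dt)
  # and declines through the transition phase afterwards
  at_p2 <- ppGppSim:::traj_interp(traj, "ppGpp", ph$t_phase2_end)
  expect_lt(at_p2, pk$value)
  expect_lt(traj$state[nrow(traj$state), "ppGpp"], pk$value)
})
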
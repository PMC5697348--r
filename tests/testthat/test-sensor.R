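test_that("sensor steady state has the expected closed form", {
  p <- sensor_preset("reference")
  # no ppGpp: promoter fully on, repressor at 1, GFP maximally repressed
  ss0 <- sensor_steady_state(0, p)
  expect_identical(ss0$I, 1)
  expect_equal(ss0$GFP, 1 / (1 + (1 / p$Ki_I)^4))
  # saturating ppGpp: repressor gone, reporter fully on
  ssInf <- sensor_steady_state(1e9, p)
  expect_lt(ssInf$I, 1e-6)
  expect_gt(ssInf$GFP, 1 - 1e-6)
  # repressor at its inhibition constant: GFP at half
  pI <- model_parameters(Ki_I = p1p2_activity(123, p))
  expect_equal(sensor_steady_state(123, pI)$GFP, 0.5)
  # ppGpp at the promoter constant: I = 1/2, GFP from composing the two laws
  ss <- sensor_steady_state(p$Ki_P1P2_ppGpp, p)
  expect_equal(ss$I, 0.5)
  expect_equal(ss$GFP, 1 / (1 + (0.5 / p$Ki_I)^4))
})

test_that("closed-form sensor steady state matches clamped simulation", {
  p <- sensor_preset("reference")
  grid <- 10^seq(log10(10), log10(2000), length.out = 20)
  ss <- sensor_steady_state(grid, p)
  for (i in seq_along(grid)) {
    sc <- scenario(p, init = model_state(ppGpp = grid[i]),
                   t_end = 400, output_dt = 50,
                   events = list(event_at(0, "clamp_ppGpp", grid[i])))
    traj <- simulate_scenario(sc)
    expect_lt(abs(traj$state[nrow(traj$state), "GFP"] - ss$GFP[i]), 1e-6)
    expect_lt(abs(traj$state[nrow(traj$state), "I"] - ss$I[i]), 1e-6)
  }
})

test_that("the GFP dose-response is monotone and spans the observable range", {
  p <- sensor_preset("reference")
  dr <- dose_response_curve(10^seq(log10(50), log10(1000), length.out = 30),
                            p = p)
  expect_true(all(diff(dr$GFP) >= 0))
  expect_lt(dr$GFP[1], 0.25)
  expect_gt(dr$GFP[nrow(dr)], 0.9)
  expect_error(dose_response_curve(c(3, 2, 1), p = p), "increasing")
})

test_that("fully repressed production reduces GFP decay to first order", {
  # with the repressor pinned at 1 the GFP equation collapses to
  # dGFP/dt = -k_GFP * GFP (up to the tiny residual production), so the
  # half-life is log(2)/k_GFP
  p <- unclass(model_parameters(Ki_I = 0.05))
  out <- deSolve::ode(c(I = 1, GFP = 1), seq(0, 30, by = 0.01),
                      ppGppSim:::sensor_rhs, p,
                      p1p2_fun = function(t) 1, rtol = 1e-10, atol = 1e-12)
  t_half <- unname(out[which(out[, "GFP"] <= 0.5)[1], "time"])
  expect_equal(t_half, log(2) / p$k_GFP, tolerance = 0.01)
})

test_that("response time shortens with faster GFP turnover and stronger repression", {
  t_ref <- ref_t05(Ki_I = 0.3, k_GFP = 0.1)
  expect_gt(t_ref, 0)
  # 10x faster GFP degradation
  expect_lt(ref_t05(Ki_I = 0.3, k_GFP = 1), t_ref)
  # 10x stronger inhibition of GFP expression
  expect_lt(ref_t05(Ki_I = 0.03, k_GFP = 0.1), t_ref)
  # monotone along the span
  expect_lt(ref_t05(Ki_I = 0.1), ref_t05(Ki_I = 0.3))
  expect_lt(ref_t05(Ki_I = 0.03), ref_t05(Ki_I = 0.1))
  expect_lt(ref_t05(k_GFP = 0.3), ref_t05(k_GFP = 0.1))
  expect_lt(ref_t05(k_GFP = 1), ref_t05(k_GFP = 0.3))
})

test_that("stronger repression trades response speed against amplitude", {
  # Ki_I 0.1 -> 0.02 must lower both T0.5 and the peak GFP of the upshift
  # scenario: the speed/amplitude trade-off of the relay design
  expect_lt(ref_t05(Ki_I = 0.02), ref_t05(Ki_I = 0.1))
  pk_01 <- peak_gfp(ref_upshift(Ki_I = 0.1))$GFP_peak
  pk_002 <- peak_gfp(ref_upshift(Ki_I = 0.02))$GFP_peak
  expect_lt(pk_002, pk_01)
})

test_that("peak detection is grid-independent and handles edge cases", {
  # exact parabola: quadratic interpolation recovers the off-grid vertex
  t <- seq(0, 10, by = 1)
  g <- 0.8 - 0.01 * (t - 4.3)^2
  fake <- structure(list(time = t, state = cbind(GFP = g)),
                    class = "ppgpp_trajectory")
  pk <- peak_gfp(fake)
  expect_equal(pk$t_GFP_peak, 4.3, tolerance = 1e-9)
  expect_equal(pk$GFP_peak, 0.8, tolerance = 1e-9)

  # monotone decreasing signal peaks at the first point
  fake2 <- structure(list(time = t, state = cbind(GFP = exp(-t))),
                     class = "ppgpp_trajectory")
  expect_identical(peak_gfp(fake2)$t_GFP_peak, 0)
})

test_that("high-Tes lines show a stronger GFP diagnostic signal", {
  pd <- sensor_preset("diagnostic")
  g0 <- peak_gfp(cached("diag_line0", run_line("line0", pd))$trajectory)
  g3 <- peak_gfp(cached("diag_line3", run_line("line3", pd))$trajectory)
  expect_gt(g3$GFP_peak, g0$GFP_peak)
  # stronger repression lowers the attainable peak at fixed Tes activity
  p002 <- model_parameters(Ki_I = 0.02)
  g0_002 <- peak_gfp(cached("ki002_line0", run_line("line0", p002))$trajectory)
  expect_lt(g0_002$GFP_peak, g0$GFP_peak)
})
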
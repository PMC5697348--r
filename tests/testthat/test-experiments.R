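test_that("producer-line presets carry the published Tes activities", {
  pre <- line_presets()
  expect_identical(pre$V_tes[match(c("line0", "line1", "line2", "line3"),
                                   pre$name)],
                   c(0.08, 1.6, 19, 110))
  expect_identical(pre$V_tes[pre$name == "line3_alt"], 100)
  expect_error(run_line("line9"), "unknown line preset")
})

test_that("control and high-Tes lines reproduce the expected contrasts", {
  l0 <- ref_line("line0"); l1 <- ref_line("line1"); l3 <- ref_line("line3")
  # endogenous Tes alone produces an order of magnitude less FA than line 1
  expect_lt(l0$yield_24h, 0.15 * l1$yield_24h)
  # Acyl-ACP depletion and elevated ppGpp in the high-Tes line
  expect_lt(min(l3$trajectory$state[, "AcylACP"]),
            0.1 * min(l0$trajectory$state[, "AcylACP"]))
  expect_gt(max(l3$trajectory$state[, "ppGpp"]),
            max(l0$trajectory$state[, "ppGpp"]))
  # growth penalty of excessive Tes expression
  n_end <- function(r) r$trajectory$state[nrow(r$trajectory$state), "N"]
  expect_lt(n_end(l3), n_end(l0))
})

test_that("the yield curve has one interior optimum and an inverse GFP relation beyond it", {
  sw <- cached("sweep11", tes_sweep(10^seq(log10(0.01), log10(300),
                                           length.out = 11)))
  i <- which.max(sw$yield_24h)
  expect_gt(i, 1)
  expect_lt(i, nrow(sw))
  # vanishing thioesterase -> vanishing yield
  expect_lt(sw$yield_24h[1], 0.02 * max(sw$yield_24h))
  # peak GFP grows with Tes activity across the whole grid
  expect_true(all(diff(sw$GFP_peak) >= -1e-6))
  # beyond the optimum: yields fall while the GFP diagnostic rises
  high <- seq(i, nrow(sw))
  expect_true(all(diff(sw$yield_24h[high]) <= 0))
  expect_true(all(diff(sw$GFP_peak[high]) >= -1e-6))
})

test_that("the GFP-vs-Tes diagnostic steepens under stronger repression", {
  grid <- 10^seq(log10(0.08), log10(110), length.out = 7)
  pk <- function(p) vapply(grid, function(V)
    peak_gfp(run_line(V, p, output_dt = 20)$trajectory)$GFP_peak, numeric(1))
  g_01 <- pk(sensor_preset("diagnostic"))       # Ki_I = 0.1
  g_002 <- pk(model_parameters(Ki_I = 0.02))
  expect_true(all(diff(g_01) >= -1e-6))
  expect_true(all(diff(g_002) >= -1e-6))
  # slope between the grid ends
  expect_gt((g_002[7] - g_002[1]), (g_01[7] - g_01[1]))
})

test_that("Tes calibration inverts the yield curve on the ascending branch", {
  l1 <- ref_line("line1")
  V <- calibrate_vtes(l1$yield_24h, bracket = c(0.5, 3))
  expect_equal(V, 1.6, tolerance = 2e-3)
  # a target above the attainable maximum is refused
  sw <- cached("sweep11", tes_sweep(10^seq(log10(0.01), log10(300),
                                           length.out = 11)))
  expect_error(calibrate_vtes(1.05 * max(sw$yield_24h),
                              bracket = c(0.01, 300)),
               class = "ppgpp_target_unattainable")
})

test_that("the reference calibration is reproducible and satisfies its constraints", {
  cal <- calibrate_reference_set()
  expect_true(all(attr(cal, "constraints")))
  expect_equal(cal$Km_Ac_pp, model_parameters()$Km_Ac_pp, tolerance = 1e-4)
  ratio <- run_line("line1", cal, output_dt = 20)$yield_24h /
    run_line("line3", cal, output_dt = 20)$yield_24h
  expect_equal(ratio, 3, tolerance = 0.15)
})

test_that("the sensor stage is read-only for growth, FA and ppGpp", {
  base <- simulate_scenario(scenario(model_parameters(), t_end = 500))
  core <- c("AcylACP", "FA", "N", "nutr", "lim", "ppGpp", "rib")
  for (ov in list(list(k_I = 0.5), list(k_GFP = 1), list(Ki_I = 0.02),
                  list(l_hill = 2))) {
    p <- do.call(model_parameters, ov)
    pert <- simulate_scenario(scenario(p, t_end = 500))
    expect_identical(pert$state[, core], base$state[, core])
  }
})

test_that("one-at-a-time perturbations preserve the qualitative phenotype", {
  scan <- sensitivity_scan(parameters = c("kp_ppGpp", "Vm_FAS", "k_GFP"),
                           fold = c(0.5, 2))
  expect_identical(nrow(scan), 6L)
  feat <- c("ppGpp_declines_phase2", "growth_stops_with_nutr",
            "interior_yield_max", "monotone_dose_response")
  expect_true(all(as.matrix(scan[feat]), na.rm = TRUE))
  expect_false(any(is.na(as.matrix(scan[feat]))))
  # GFP turnover cannot feed back on the yield
  kg <- scan$parameter == "k_GFP"
  expect_identical(scan$rel_change_yield[kg], c(0, 0))
  expect_true(all(abs(scan$rel_change_yield[!kg]) > 0))

  # identity perturbation: everything unchanged
  id <- sensitivity_scan(parameters = "Km_tes", fold = 1)
  expect_identical(id$rel_change_yield, 0)
  expect_identical(id$rel_change_GFP_peak, 0)
  feat_all <- c("ppGpp_peak_at_phase1", feat, "ppGpp_peak_in_range")
  expect_true(all(as.matrix(id[feat_all])))
})
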
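test_that("breath segmentation finds interior cycles of a sinusoid", {
  fx <- generate_pv_fixture("linear_sinusoid", cycles = 10,
                            samples_per_cycle = 200)
  cyc <- segment_breaths(fx$data)
  # 10 periods sampled minimum-to-minimum yield 9 interior cycles
  expect_equal(nrow(cyc), 9)
  per <- 60 / 44
  expect_equal(cyc$t_end - cyc$t_start, rep(per, 9), tolerance = 0.02)
})

test_that("segmentation rejects degenerate records", {
  flat <- tibble::tibble(t_s = 1:100 / 10, p_mbar = 0, V_mL = 50)
  expect_error(segment_breaths(flat), "minima")
  expect_error(segment_breaths(tibble::tibble(t_s = c(1, 1, 2),
                                              p_mbar = 0,
                                              V_mL = c(1, 2, 1))),
               "strictly increasing")
})

test_that("simulator output segments at the breathing period", {
  sim <- run_simulation(quick_config(max_breaths = 21))
  cyc <- segment_breaths(sim$trace)
  per <- 60 / 44
  dt <- diff(sim$trace$t_s[1:2])
  expect_true(all(abs((cyc$t_end - cyc$t_start) - per) <= dt + 1e-9))
})

test_that("negative-side loop area matches closed-form oracles", {
  # half-ellipse: pi * a * b / 2 in mbar mL
  fx <- generate_pv_fixture("ellipse", a_mbar = 10, b_mL = 17.5)
  w <- wob_cycles(fx$data)
  expect_equal(fx$expected_wob_J, pi * 10 * 17.5 / 2 * 1e-4)
  expect_equal(mean(w$work_J), fx$expected_wob_J, tolerance = 0.01)
  # linear resistance, sinusoidal driver: pi R omega VT^2 / 8
  fx2 <- generate_pv_fixture("linear_sinusoid", r_lin = 0.01)
  expect_equal(fx2$expected_wob_J, 2.2165486551e-3, tolerance = 1e-9)
  w2 <- wob_cycles(fx2$data)
  expect_equal(mean(w2$work_J), fx2$expected_wob_J, tolerance = 0.01)
  # quadratic orifice: K Q0^3 (4/3) / omega
  fx3 <- generate_pv_fixture("orifice_sinusoid", diameter_mm = 2.64)
  w3 <- wob_cycles(fx3$data)
  expect_equal(mean(w3$work_J), fx3$expected_wob_J, tolerance = 0.01)
  # flat pressure: zero work
  fx4 <- generate_pv_fixture("flat")
  expect_equal(max(wob_cycles(fx4$data)$work_J), 0)
})

test_that("loop area is invariant to sampling density", {
  w_ref <- mean(wob_cycles(generate_pv_fixture(
    "linear_sinusoid", samples_per_cycle = 200)$data)$work_J)
  w_dense <- mean(wob_cycles(generate_pv_fixture(
    "linear_sinusoid", samples_per_cycle = 800)$data)$work_J)
  # quadrupling the density moves the area by < 0.1%
  expect_lt(abs(w_dense - w_ref) / w_ref, 1e-3)
  # resampling the same loop leaves work within 0.5%
  w_coarse <- mean(wob_cycles(generate_pv_fixture(
    "linear_sinusoid", samples_per_cycle = 73)$data)$work_J)
  expect_lt(abs(w_coarse - w_ref) / w_ref, 5e-3)
})

test_that("work scales to the minute by the breathing rate", {
  expect_equal(wob_per_minute(0, 44), 0)
  expect_equal(wob_per_minute(2.22e-3, 44), 9.768e-2)
  expect_equal(wob_per_minute(0.5, 0), 0)
  expect_error(wob_per_minute(-1, 44), "non-negative")
})

test_that("wob_summary aggregates cycles and infers the rate", {
  fx <- generate_pv_fixture("linear_sinusoid", cycles = 8)
  s <- wob_summary(fx$data)
  expect_equal(s$n_cycles, 7)
  expect_equal(s$rate_bpm, 44, tolerance = 0.02)
  expect_equal(s$wob_J_min, s$mean_work_J * s$rate_bpm)
})

test_that("simulated WOB through a linear tube matches the closed form", {
  sim <- run_simulation(quick_config(max_breaths = 12))
  r_lin <- tube_resistance(300, 5)
  expected <- wob_linear_closed_form(r_lin, 35, 44)
  expect_equal(sim$summary$work_per_cycle_J, expected, tolerance = 0.01)
})
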
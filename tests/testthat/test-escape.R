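test_that("exponential mean is recovered within sampling error", {
  ev <- generate_escape_events(1e4, t_esc_ms = 50, seed = 21)
  fit <- fit_escape_time(ev, n_excluded_lags = 0)
  expect_lt(abs(fit$t_esc_ms - 50), 3 * 50 / sqrt(1e4))
  expect_equal(fit$se_ms, fit$t_esc_ms / sqrt(fit$n_events))
})

test_that("left truncation is handled by memorylessness", {
  set.seed(5)
  dt <- rexp(2e4, 1 / 50)
  kept <- dt[dt > 20]
  ev <- escape_events(kept)
  fit <- fit_escape_time(ev, n_excluded_lags = 0)
  # truncated-aware MLE stays unbiased; the naive mean-minus-offset agrees
  expect_lt(abs(fit$t_esc_ms - 50), 3 * 50 / sqrt(length(kept)))
  expect_equal(fit$t_esc_ms, mean(kept) - min(kept), tolerance = 1e-12)
})

test_that("short-lived contaminants are removed by lag exclusion", {
  ev <- generate_escape_events(2e4, t_esc_ms = 50, frame_ms = 2, seed = 3,
                               contaminant_frac = 0.05,
                               contaminant_mean_ms = 2)
  fit <- fit_escape_time(ev, n_excluded_lags = 2)
  expect_lt(abs(fit$t_esc_ms - 50) / 50, 0.05)
  # without exclusion the contaminant biases the estimate low
  fit0 <- fit_escape_time(ev, n_excluded_lags = 0)
  expect_lt(fit0$t_esc_ms, fit$t_esc_ms)
})

test_that("frame-discretized events are fitted without bias", {
  # frame interval comparable to the mean: the geometric MLE matters here
  ev <- generate_escape_events(4e4, t_esc_ms = 9.6, frame_ms = 5, seed = 11)
  fit <- fit_escape_time(ev, n_excluded_lags = 2)
  expect_lt(abs(fit$t_esc_ms - 9.6), 3 * fit$se_ms)
})

test_that("degenerate inputs error cleanly", {
  expect_error(fit_escape_time(escape_events(rexp(50, 1 / 10))), "100")
  expect_error(escape_events(c(1, NA)), "finite")
  expect_error(escape_events(c(1, 5), frame_ms = 2), "frame")
})

test_that("Kramers ratio closed form", {
  expect_equal(kramers_ratio(3, 3), 1)
  expect_equal(kramers_ratio(4, 3), exp(1))
})

test_that("calibration recovers the surface potential and round-trips", {
  fx <- generate_device_fixture("fig3_device")
  trap <- trap_model(fx$device, fx$electrolyte, r_H = 3.5)
  ev <- generate_escape_events(2e4, q_eff = -28.2, trap = trap,
                               phi_s = -2.24, frame_ms = 5, seed = 11)
  cal <- calibrate_surface_potential(-28.2, fit_escape_time(ev), trap)
  expect_equal(cal$phi_s, -2.24, tolerance = 0.02)
  # calibration fixed point: the calibrator infers its own charge
  ev2 <- generate_escape_events(2e4, q_eff = -28.2, trap = trap,
                                phi_s = cal$phi_s, frame_ms = 0, seed = 12)
  inf <- infer_qeff(fit_escape_time(ev2, 0), cal)
  expect_equal(inf$q_eff, -28.2, tolerance = 0.02)
})

test_that("longer trapping at fixed charge implies stronger surface potential", {
  fx <- generate_device_fixture("fig3_device")
  trap <- trap_model(fx$device, fx$electrolyte, r_H = 3.5)
  mk <- function(t) {
    f <- tibble::tibble(t_esc_ms = t, se_ms = t / 100, n_events = 10000L,
                        n_excluded_lags = 2L, truncation_ms = 0)
    class(f) <- c("escape_fit", class(f))
    f
  }
  c1 <- calibrate_surface_potential(-28.2, mk(10), trap)
  c2 <- calibrate_surface_potential(-28.2, mk(20), trap)
  expect_gt(abs(c2$phi_s), abs(c1$phi_s))
})

test_that("escape time grows with |q_eff| across a species panel", {
  fx <- generate_device_fixture("fig3_device")
  trap <- trap_model(fx$device, fx$electrolyte, r_H = 3.5)
  q <- c(-20, -28.2, -35, -40.7, -44.3)
  t <- vapply(q, function(qq) electrometry:::.model_tesc(qq, -2.24, trap),
              numeric(1))
  expect_true(all(diff(t) > 0))
})

test_that("round trip q_eff -> events -> q_eff closes over a random panel", {
  fx <- generate_device_fixture("fig3_device")
  trap <- trap_model(fx$device, fx$electrolyte, r_H = 3.5)
  cal_ev <- generate_escape_events(5e4, q_eff = -28.2, trap = trap,
                                   phi_s = -2.24, seed = 40)
  cal <- calibrate_surface_potential(-28.2, fit_escape_time(cal_ev, 0), trap)
  set.seed(77)
  qs <- runif(10, -50, -20)
  ns <- sample(c(5e3, 1e4, 2e4), 10, replace = TRUE)
  for (k in seq_along(qs)) {
    ev <- generate_escape_events(ns[k], q_eff = qs[k], trap = trap,
                                 phi_s = -2.24, seed = 100 + k)
    inf <- infer_qeff(fit_escape_time(ev, 0), cal)
    # propagated error: species-fit term plus the calibration-fit term
    # (sigma_phi_m = sigma_ln(t_cal)/|q_cal| maps to |q|-proportional error)
    se_cal <- abs(qs[k]) / (abs(cal$phi_m) * abs(cal$calibrator_q_eff) *
                              sqrt(5e4))
    se_tot <- sqrt(inf$q_eff_se^2 + se_cal^2)
    expect_lt(abs(inf$q_eff - qs[k]), 3 * se_tot)
  }
})
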
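test_that("event generation is bit-reproducible under a fixed seed", {
  e1 <- generate_escape_events(1e4, t_esc_ms = 100, frame_ms = 5, seed = 7)
  e2 <- generate_escape_events(1e4, t_esc_ms = 100, frame_ms = 5, seed = 7)
  expect_identical(e1$dt_ms, e2$dt_ms)
  expect_error(generate_escape_events(0, t_esc_ms = 10), "at least 1")
})

test_that("fitting generated events recovers the true mean", {
  ev <- generate_escape_events(1e4, t_esc_ms = 100, frame_ms = 5, seed = 8)
  fit <- fit_escape_time(ev)
  expect_lt(abs(fit$t_esc_ms - 100), 3 * 100 / sqrt(1e4))
})

test_that("a 1 kT difference in trap depth gives an e-fold mean ratio", {
  fx <- generate_device_fixture("fig3_device")
  trap <- trap_model(fx$device, fx$electrolyte, r_H = 3.5)
  # two species whose q_eff differ by exactly 1 kT of electrostatic depth
  phi_m <- 2 * (-2.24) * exp(-fx$device$h / debye_length(fx$electrolyte))
  dq <- 1 / abs(phi_m)
  e1 <- generate_escape_events(4e4, q_eff = -30, trap = trap,
                               phi_s = -2.24, seed = 61)
  e2 <- generate_escape_events(4e4, q_eff = -30 - dq, trap = trap,
                               phi_s = -2.24, seed = 62)
  r <- fit_escape_time(e2, 0)$t_esc_ms / fit_escape_time(e1, 0)$t_esc_ms
  expect_equal(r, exp(1), tolerance = 0.05)
})

test_that("stiff chains straighten; flexible chains obey the FJC law", {
  # rigid limit: R -> full contour length
  stiff <- generate_chain_ensemble(50, 30, b_c = 0.5, l_p = 500, seed = 3)
  expect_true(all(stiff$metrics$R > 0.97 * 30 * 0.5))
  expect_true(all(stiff$metrics$R <= stiff$metrics$l_c + 1e-9))

  # near-freely-jointed: <R^2> ~= N b^2 (weak residual correlation enters
  # through the discrete-WLC closed form)
  fjc <- generate_chain_ensemble(2000, 30, b_c = 0.5, l_p = 0.25, seed = 4)
  expect_equal(mean(fjc$metrics$R^2), wlc_mean_square_R(30, 0.5, 0.25),
               tolerance = 0.05)
})

test_that("semiflexible ensembles match the discrete worm-like-chain law", {
  ens <- generate_chain_ensemble(2000, 60, b_c = 0.5, l_p = 2, seed = 5)
  expect_equal(mean(ens$metrics$R^2), wlc_mean_square_R(60, 0.5, 2),
               tolerance = 0.05)
  # all members respect R <= l_c and populate a connected (R_g, R) region
  expect_true(all(ens$metrics$R <= ens$metrics$l_c + 1e-9))
  expect_gt(stats::sd(ens$metrics$R), 0)
  expect_error(generate_chain_ensemble(10, 30, b_c = 0.5, l_p = 0.01),
               "stiffness")
})

test_that("device fixtures carry the study conditions", {
  f1 <- generate_device_fixture("fig1_device")
  expect_equal(2 * f1$device$h, 70)
  expect_equal(f1$device$phi_s, -1.91)
  expect_equal(f1$electrolyte$species$c[1], 0.6e-3)
  # the printed slit-regime parameter is stored verbatim, the geometric
  # ratio is derivable: h / debye = 2.8
  expect_equal(f1$kappa_h_printed, 5.5)
  expect_equal(f1$device$h / debye_length(f1$electrolyte), 2.8,
               tolerance = 0.01)

  f3 <- generate_device_fixture("fig3_device")
  expect_equal(2 * f3$device$h, 75)
  expect_equal(f3$device$phi_s, -2.24)
  expect_equal(f3$device$h / debye_length(f3$electrolyte), 4.27,
               tolerance = 0.01)

  fc <- generate_device_fixture("fig1c_geometry")
  expect_equal(fc$device$d, 210)
  expect_error(generate_device_fixture("nope"))
})
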
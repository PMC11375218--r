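test_that("renormalization factor reproduces the measured-panel arithmetic", {
  # 60-base poly-dT: |q_eff| = 44.1 e against |q_str| = 63 e
  expect_equal(renormalization_factor(-44.1, -63), 0.70, tolerance = 0.005)
  expect_equal(renormalization_factor(5, 5), 1)
  # 5-base fragment: measured eta 0.94 implies |q_str| ~ 6.7 e
  expect_equal(renormalization_factor(-6.3, -6.7), 0.94, tolerance = 0.005)
  expect_error(renormalization_factor(1, 0), "zero")
})

test_that("analytic cylinder formula: identities and limits", {
  lB <- bjerrum_length(el_12)
  # log argument unity: |q_str| lB / l = 1 -> q_eff = Manning value l/lB
  l <- 30
  q <- analytic_cylinder_qeff(l, -l / lB, 0.1, el_12)
  expect_equal(q$q_eff_abs, l / lB, tolerance = 1e-12)
  expect_equal(q$manning_limit, l / lB)
  # direct evaluation oracle at the rod-model conditions
  kap <- 1 / debye_length(el_12)
  ref <- (30 / lB) * (1 - log(61 * lB / 30) / (2 * log(kap * 0.4)))
  expect_equal(analytic_cylinder_qeff(30, -61, 0.4, el_12)$q_eff_abs, ref,
               tolerance = 1e-12)
  # kappa R -> 0 approaches the Manning line density
  r1 <- analytic_cylinder_qeff(60, -122, 1e-3, el_12)$q_eff_abs
  r2 <- analytic_cylinder_qeff(60, -122, 1e-6, el_12)$q_eff_abs
  expect_lt(abs(r2 - 60 / lB), abs(r1 - 60 / lB))
  expect_error(analytic_cylinder_qeff(30, -61, 20, el_12), "regime")
  expect_warning(analytic_cylinder_qeff(5, -10, 0.1, el_12), "short")
})

test_that("analytic cylinder and nonlinear infinite rod agree at moderate kR", {
  lB <- bjerrum_length(el_12)
  kap <- 1 / debye_length(el_12)
  for (kR in c(0.2, 0.3)) {
    r <- kR / kap
    nu <- -2 / lB
    s <- solve_rod_infinite(r, nu, el_12)
    a <- analytic_cylinder_qeff(200, nu * 200, r, el_12)
    expect_equal(abs(s$nu_eff) * 200, a$q_eff_abs, tolerance = 0.1)
  }
})

test_that("dye bookkeeping: totals, structural charge, identity at zero", {
  core <- electrometry:::new_effective_charge(-12.0, -13, "far-field")
  with_dyes <- add_dye_effective_charge(core, n_dyes = 2)
  expect_equal(with_dyes$q_calc, -12.62)
  expect_equal(with_dyes$q_str, -15)       # -(n_b+3) for n_b = 12
  expect_equal(with_dyes$q_core, -12.0)
  expect_identical(add_dye_effective_charge(core, 0), core)
  expect_error(add_dye_effective_charge(core, -1), "negative")
})

test_that("gamma-eta fit recovers exact linear synthetic data", {
  eta <- seq(0.5, 0.9, length.out = 6)
  sweep <- tibble::tibble(eta = eta, gamma = 1.3 - 0.8 * eta)
  fit <- gamma_eta_fit(sweep)
  expect_equal(fit$a1, 1.3, tolerance = 1e-10)
  expect_equal(fit$a2, -0.8, tolerance = 1e-10)
  # constant gamma: slope exactly zero
  flat <- gamma_eta_fit(tibble::tibble(eta = eta, gamma = 2))
  expect_identical(flat$a2, 0)
  expect_error(gamma_eta_fit(sweep[1:3, ]), "at least 4")
})

test_that("counterion excess falls linearly with eta (a2 < 0) over a sweep", {
  opts <- solver_options(spacing_fine = 0.05, padding_debye = 6)
  rows <- lapply(seq(0.35, 0.65, length.out = 4), function(b) {
    f <- solve_rod(rod_model(0.4, b, 30), el_12, opts)
    tibble::tibble(
      gamma = counterion_excess(f, per_phosphate = 31)$gamma_plus_per_site,
      eta = abs(qcalc_farfield(f)$q_calc / 31))
  })
  fit <- gamma_eta_fit(dplyr::bind_rows(rows))
  expect_lt(fit$a2, 0)
})

test_that("denser rod charge accumulates more counterions per site", {
  opts <- solver_options(spacing_fine = 0.05, padding_debye = 6)
  g <- vapply(c(0.35, 0.65), function(b) {
    f <- solve_rod(rod_model(0.4, b, 30), el_12, opts)
    counterion_excess(f, per_phosphate = 31)$gamma_plus_per_site
  }, numeric(1))
  expect_gt(g[1], g[2])
})

test_that("|q_calc| increases with axial spacing at fixed base count", {
  opts <- solver_options(spacing_fine = 0.05, padding_debye = 5)
  q <- vapply(c(0.35, 0.5, 0.65), function(b) {
    abs(qcalc_farfield(solve_rod(rod_model(0.4, b, 30), el_12, opts))$q_calc)
  }, numeric(1))
  expect_true(all(diff(q) > 0))
})
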
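test_that("linear-limit rod field matches screened-Coulomb superposition", {
  rod <- rod_model(0.4, 0.5, 60, q_str = -0.001)
  f <- solve_rod(rod, el_12, opts_rod_fine)
  kap <- 1 / debye_length(el_12)
  lB <- bjerrum_length(el_12)
  hl <- rod$l / 2
  cap <- rod$r + 2.5 / kap
  tt <- seq(0, 1, length.out = 20)
  al <- seq(0.05, pi / 2, length.out = 15)
  pz <- c(tt * hl, hl + cap * sin(al))
  pr <- c(rep(cap, 20), cap * cos(al))
  num <- -exp(electrometry:::.interp2(f$z_centers, f$rho_centers,
                                      log(pmax(-f$psi_matrix, 1e-300)),
                                      pz, pr))
  zq <- seq(-hl, hl, length.out = 801)
  wq <- rep(1, 801); wq[c(1, 801)] <- 0.5
  wq <- wq * rod$q_str / sum(wq)
  dh <- vapply(seq_along(pz), function(k) {
    d <- sqrt((pz[k] - zq)^2 + pr[k]^2)
    lB * sum(wq * exp(-kap * d) / d)
  }, numeric(1))
  expect_lt(max(abs(num / dh - 1)), 0.01)
  # and the fitted far-field charge recovers the structural charge
  expect_equal(qcalc_farfield(f)$eta, 1, tolerance = 0.01)
})

test_that("screening cloud is electroneutral within discretization", {
  rod <- rod_model(0.4, 0.5, 60)     # q_str = -61 e
  f <- solve_rod(rod, el_12, solver_options(spacing_fine = 0.05,
                                            padding_debye = 6.5))
  expect_equal(ionic_charge_integral(f), 61, tolerance = 0.02)
  ce <- counterion_excess(f, per_phosphate = 61)
  expect_gt(ce$gamma_plus, 0)
  expect_gt(ce$gamma_minus, 0)
  expect_equal(ce$total, 61, tolerance = 0.02)
})

test_that("PB saturation: doubling the charge less than doubles the field", {
  rod1 <- rod_model(0.4, 0.5, 60)
  rod2 <- rod_model(0.4, 0.5, 60, q_str = -122)
  f1 <- solve_rod(rod1, el_12, opts_rod)
  f2 <- solve_rod(rod2, el_12, opts_rod)
  expect_gt(abs(f2$surface_potential), abs(f1$surface_potential))
  expect_lt(abs(f2$surface_potential), 2 * abs(f1$surface_potential))
  q1 <- abs(qcalc_farfield(f1)$q_calc)
  q2 <- abs(qcalc_farfield(f2)$q_calc)
  expect_gt(q2, q1)
  expect_lt(q2, 2 * q1)
})

test_that("free energy is positive and decreases with added salt", {
  rod <- rod_model(0.4, 0.5, 20)
  f1 <- free_energy(solve_rod(rod, electrolyte(0.6e-3), opts_rod))
  f2 <- free_energy(solve_rod(rod, electrolyte(1.2e-3), opts_rod))
  f3 <- free_energy(solve_rod(rod, electrolyte(4.8e-3), opts_rod))
  expect_gt(f1, 0)
  expect_true(f1 > f2 && f2 > f3)
})

test_that("zero field has zero free energy and ionic charge", {
  rod <- rod_model(0.4, 0.5, 20, q_str = 0)
  f <- solve_rod(rod, el_12, opts_rod)
  expect_equal(free_energy(f), 0, tolerance = 1e-12)
  expect_equal(ionic_charge_integral(f), 0, tolerance = 1e-12)
  ce <- counterion_excess(f)
  expect_equal(ce$gamma_plus, 0, tolerance = 1e-9)
})

test_that("linearized free-energy functional agrees in the weak limit", {
  rod <- rod_model(0.4, 0.5, 60, q_str = -0.01)
  f <- solve_rod(rod, el_12, opts_rod_fine)
  kap2 <- (1 / debye_length(el_12))^2
  lB <- bjerrum_length(el_12)
  psi <- f$psi
  act <- which(f$lambda > 0 & !is.na(psi))
  ec <- f$energy_conns
  grad2 <- sum(ec$w * (psi[ec$i] - psi[ec$j])^2)
  # cosh(psi) - psi sinh(psi) - 1 -> -psi^2/2
  lin_ionic <- sum(f$volume[act] * (-psi[act]^2 / 2))
  F_lin <- f$symmetry * (grad2 / (8 * pi * lB) -
                           kap2 / (4 * pi * lB) * lin_ionic)
  expect_equal(free_energy(f), F_lin, tolerance = 0.02)
})

test_that("infinite-rod solver matches the linear K0 oracle and saturates", {
  # linear limit: nu_eff -> nu
  s_lin <- solve_rod_infinite(0.4, -0.01, el_12)
  expect_equal(s_lin$nu_eff, -0.01, tolerance = 0.01)
  # saturation: increasing bare density barely moves the effective density
  lB <- bjerrum_length(el_12)
  kap <- 1 / debye_length(el_12)
  r <- 0.01 / kap
  s1 <- solve_rod_infinite(r, -2 / lB, el_12)
  s2 <- solve_rod_infinite(r, -5 / lB, el_12)
  expect_lt(abs(s2$nu_eff - s1$nu_eff) / abs(s1$nu_eff), 0.15)
})

test_that("degenerate rod inputs error", {
  expect_error(rod_model(0, 0.5, 60))
  expect_error(rod_model(0.4, -1, 60))
  expect_error(solve_rod(rod_model(20, 0.5, 60), el_12,
                         solver_options(padding_debye = 1.5)),
               "padding")
})
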
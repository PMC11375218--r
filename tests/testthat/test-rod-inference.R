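test_that("published-fit inversions reproduce the quoted spacings", {
  # r = 0.05 nm line: |q_calc| = 44.2 b + 13.22; poly-rU60 mean |q_eff|
  fit_thin <- rod_curve_from_fit(44.2, 13.22, r = 0.05, n_b = 60)
  b_rU <- invert_spacing((41.5 + 40.7) / 2, fit_thin)$b_inferred
  expect_equal(b_rU, 0.63, tolerance = 0.01)
  # r = 0.4 nm line: |q_calc| = 37.36 b + 21.25; poly-dT60 mean |q_eff|
  fit_thick <- rod_curve_from_fit(37.36, 21.25, r = 0.4, n_b = 60)
  b_dT <- invert_spacing((44.3 + 44.1) / 2, fit_thick)$b_inferred
  expect_equal(b_dT, 0.61, tolerance = 0.01)
  # intercept maps to zero spacing
  expect_equal(invert_spacing(21.25, fit_thick)$b_inferred, 0)
})

test_that("inversion propagates uncertainty and flags extrapolation", {
  curve <- rod_curve_from_fit(40, 20, fit_range = c(0.45, 0.65))
  inv <- invert_spacing(c(38, 50), curve, se = c(0.4, 0.4),
                        species = c("in", "out"))
  expect_equal(inv$b_se, c(0.01, 0.01))
  expect_identical(inv$extrapolated, c(FALSE, TRUE))
  expect_error(invert_spacing(30, rod_curve_from_fit(1, 0)) , NA)
  expect_error(rod_curve_from_fit(-1, 0), "positive")
})

test_that("computed curve: linearity, monotonicity and inversion round trip", {
  # coarse, fast variant of the full sweep: 5 points across the window
  curve <- compute_qcalc_vs_b(
    r = 0.4, n_b = 30, elec = el_12,
    b_grid = seq(0.45, 0.65, length.out = 5), fit_range = c(0.45, 0.65),
    options = solver_options(spacing_fine = 0.05, padding_debye = 5))
  expect_true(all(diff(curve$points$q_calc_abs) > 0))
  expect_gt(curve$r_squared, 0.99)
  # fit residual below 1% of |q_calc| at every fitted point
  resid <- abs(curve$points$q_calc_abs - curve$points$fitted)
  expect_true(all(resid / curve$points$q_calc_abs < 0.01))
  # inversion round trip to 1e-6 nm
  b_star <- 0.52
  q_star <- curve$intercept + curve$slope * b_star
  expect_equal(invert_spacing(q_star, curve)$b_inferred, b_star,
               tolerance = 1e-6)
})

test_that("spacing report joins references and preserves ordering", {
  inv <- tibble::tibble(species = c("poly-dT", "poly-rU"),
                        q_eff_abs = c(44.2, 41.1),
                        b_inferred = c(0.61, 0.54),
                        b_se = NA_real_, extrapolated = FALSE)
  rep <- spacing_report(inv)
  saxs <- rep[rep$source == "SAXS" & !is.na(rep$source), ]
  # same species ordering in inferred and reference columns
  expect_gt(saxs$b_inferred[saxs$species == "poly-dT"],
            saxs$b_inferred[saxs$species == "poly-rU"])
  expect_gt(saxs$b_c_nm[saxs$species == "poly-dT"],
            saxs$b_c_nm[saxs$species == "poly-rU"])
  # projected spacing above the contour spacing is flagged
  expect_true(all(saxs$b_exceeds_bc))
  # empty input -> empty table
  expect_equal(nrow(spacing_report(inv[0, ])), 0)
  # missing reference entries keep the row with blank reference
  inv2 <- dplyr::mutate(inv[1, ], species = "poly-dX")
  rep2 <- spacing_report(inv2)
  expect_equal(nrow(rep2), 1)
  expect_true(is.na(rep2$b_c_nm))
})
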
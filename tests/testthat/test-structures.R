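test_that("PQR write/read round-trips all fields", {
  hh <- build_half_helix(5)
  tmp <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(hh, tmp)
  back <- read_pqr(tmp)
  expect_equal(back$atoms$x, hh$atoms$x, tolerance = 1e-4)
  expect_equal(back$atoms$charge, hh$atoms$charge, tolerance = 1e-4)
  expect_equal(back$atoms$radius, hh$atoms$radius, tolerance = 1e-4)
  expect_equal(back$q_str, hh$q_str, tolerance = 1e-3)
})

test_that("PQR coordinates are converted from Angstrom to nm", {
  tmp <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1 P    MOL     1      10.000    0.000    0.000  -1.00000  2.00000",
    "ATOM      2 O    MOL     1       0.000    5.000    0.000   0.50000  1.50000",
    "ATOM      3 H5T  MOL     1       0.000    0.000    2.500  -0.30000  1.20000"
  ), tmp)
  s <- read_pqr(tmp)
  expect_equal(s$atoms$x, c(1, 0, 0))
  expect_equal(s$atoms$y[2], 0.5)
  expect_equal(s$atoms$radius, c(0.2, 0.15, 0.12))
  expect_equal(s$q_str, -0.8, tolerance = 1e-9)
})

test_that("malformed PQR records are rejected", {
  tmp <- withr::local_tempfile(fileext = ".pqr")
  writeLines("ATOM 1 P MOL 1 1.0 2.0", tmp)
  expect_error(read_pqr(tmp), "malformed")
})

test_that("terminal-charge adjustment restores -(n_b+1)e and is guarded", {
  # forcefield-like chain: n_b = 30, raw charge -(n_b - 1) = -29 e
  n_b <- 30
  atoms <- tibble::tibble(
    name = c("H5T", rep("P", n_b - 2), "H3T"),
    x = seq(0, 15, length.out = n_b), y = 0, z = 0,
    charge = c(-0.7, rep(-1, n_b - 2), -0.3), radius = 0.2)
  s <- atomic_structure(atoms)
  expect_equal(s$q_str, -29)
  adj <- adjust_terminal_charges(s)
  expect_equal(adj$q_str, -31, tolerance = 1e-3)
  expect_equal(adj$q_str - s$q_str, -2, tolerance = 1e-12)
  expect_error(adjust_terminal_charges(adj), "twice")
  # missing termini: no silent fallback
  s2 <- atomic_structure(dplyr::mutate(atoms, name = "P"))
  expect_error(adjust_terminal_charges(s2), "H5T")
})

test_that("half-helix bookkeeping and geometry", {
  hh <- build_half_helix(12)
  expect_equal(nrow(hh$atoms), 13)
  expect_equal(hh$q_str, -13)
  # chord between consecutive phosphates from rise/twist/radius:
  # sqrt((2*0.89*sin(18 deg))^2 + 0.338^2) = 0.6456 nm
  seg <- sqrt(rowSums((hh$atoms[-1, c("x", "y", "z")] -
                         hh$atoms[-13, c("x", "y", "z")])^2))
  expect_equal(unique(round(seg, 6)), 0.645634, tolerance = 1e-4)
  # total charge exact for every n_b
  for (nb in c(1, 5, 60)) expect_equal(build_half_helix(nb)$q_str, -(nb + 1))
  # size grows with chain length
  rg5 <- conformer_metrics(build_half_helix(5))$R_g
  rg12 <- conformer_metrics(build_half_helix(12))$R_g
  expect_lt(rg5, rg12)
  expect_error(build_half_helix(0), "n_b")
})

test_that("ion-accessible surface voxelization approximates sphere volumes", {
  s <- atomic_structure(tibble::tibble(name = "A", x = 0, y = 0, z = 0,
                                       charge = -1, radius = 0.2), w = 0.2)
  g <- seq(-0.8, 0.8, by = 0.04)
  inside <- ias_voxelize(s, g, g, g, probe = 0)
  vol <- sum(inside) * 0.04^3
  expect_equal(vol, 4 / 3 * pi * 0.4^3, tolerance = 0.05)

  # w = 0 reduces to the van der Waals union
  s0 <- atomic_structure(s$atoms, w = 0)
  inside0 <- ias_voxelize(s0, g, g, g, probe = 0)
  expect_equal(sum(inside0) * 0.04^3, 4 / 3 * pi * 0.2^3, tolerance = 0.08)

  # overlapping atoms: union volume below the sum of parts
  s2 <- atomic_structure(tibble::tibble(name = c("A", "B"), x = c(0, 0.25),
                                        y = 0, z = 0, charge = -1,
                                        radius = 0.2), w = 0.2)
  inside2 <- ias_voxelize(s2, g, g, g, probe = 0)
  expect_lt(sum(inside2), 2 * sum(inside))
  expect_gt(sum(inside2), sum(inside))

  # labeled volume is monotone in w
  vols <- vapply(c(0.1, 0.2, 0.3), function(w) {
    sum(ias_voxelize(atomic_structure(s$atoms, w = w), g, g, g, probe = 0))
  }, numeric(1))
  expect_true(all(diff(vols) > 0))

  expect_error(ias_voxelize(s, seq(-1, 1, by = 0.5), g, g),
               "coarser")
})

test_that("PDB loader assigns table radii and flags unknown elements", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P   DT  A   1      10.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  O5' DT  A   1      11.000   1.000   0.000  1.00  0.00           O"
  ), tmp)
  s <- load_structure(tmp, "pdb")
  expect_equal(s$atoms$radius, c(0.18, 0.152))
  expect_equal(s$atoms$x, c(1.0, 1.1))
  expect_match(s$provenance, "radii from table")
})
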
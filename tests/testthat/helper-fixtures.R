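# shared fixtures: small, fast solver settings for unit tests
el_12 <- electrolyte(1.2e-3)
el_06 <- electrolyte(0.6e-3)

opts_rod <- solver_options(spacing_fine = 0.05, padding_debye = 5)
opts_rod_fine <- solver_options(spacing_fine = 0.02, ratio = 1.12,
                                padding_debye = 6)
opts_3d <- solver_options(spacing_fine = 0.15, ratio = 1.22,
                          padding_debye = 3.2)

# independent 1D PB oracle: shooting-method integration of
# psi'' = kappa^2 sinh(psi) from the midplane (psi'(0) = 0) to the wall,
# root-solving the midplane value so the wall gradient matches the charge BC
shoot_planar <- function(sigma_w, h, elec, n_steps = 4000) {
  kap <- 1 / debye_length(elec)
  lB <- bjerrum_length(elec)
  target <- 4 * pi * lB * sigma_w        # psi'(h) (normal into wall at +h)
  integrate_to_wall <- function(psi0) {
    dx <- h / n_steps
    y <- c(psi0, 0)                       # psi, psi'
    for (i in seq_len(n_steps)) {         # RK4 (sinh clamped: off-branch
      # shots diverge and only their sign matters to the root finder)
      f <- function(y) c(y[2], kap^2 * sinh(pmax(pmin(y[1], 50), -50)))
      k1 <- f(y); k2 <- f(y + dx / 2 * k1); k3 <- f(y + dx / 2 * k2)
      k4 <- f(y + dx * k3)
      y <- y + dx / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  root <- stats::uniroot(function(p0) integrate_to_wall(p0)[2] - target,
                         c(-3, 0), tol = 1e-12)
  psi0 <- root$root
  list(psi_mid = psi0, psi_wall = integrate_to_wall(psi0)[1])
}

# brute-force radius of gyration (unit weights)
brute_rg <- function(m) {
  ctr <- colMeans(m)
  sqrt(mean(rowSums((m - matrix(ctr, nrow(m), 3, byrow = TRUE))^2)))
}
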
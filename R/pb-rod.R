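#' Uniformly charged rigid-rod model
#'
#' The simplest continuum model of a single-stranded nucleic acid: a rod of
#' radius `r` and length \eqn{l = n_b b} carrying a total structural charge
#' `q_str` (default \eqn{-(n_b+1)e}) spread uniformly over its lateral
#' surface.
#'
#' @param r Rod radius (nm).
#' @param b Axial inter-charge spacing (nm).
#' @param n_b Number of bases (charged monomers).
#' @param q_str Total structural charge in e; defaults to \eqn{-(n_b+1)}.
#' @return A `rod_model` object.
#' @export
rod_model <- function(r, b, n_b, q_str = -(n_b + 1)) {
  stopifnot(r > 0, b > 0, n_b >= 1)
  l <- n_b * b
  structure(list(r = r, b = b, n_b = n_b, l = l, q_str = q_str,
                 sigma = q_str / (2 * pi * r * l)),
            class = "rod_model")
}

#' @export
print.rod_model <- function(x, ...) {
  cat("<rod_model> r =", x$r, "nm, b =", x$b, "nm, n_b =", x$n_b,
      "(l =", x$l, "nm), q_str =", x$q_str, "e\n")
  invisible(x)
}

#' Nonlinear PB solution around a finite charged rod
#'
#' Solves the axisymmetric nonlinear Poisson-Boltzmann equation in bulk
#' electrolyte around a finite rod with constant surface charge density
#' (Neumann condition on the lateral surface), on a graded finite-volume
#' (z, rho) grid with a radiation boundary condition at the open boundary.
#'
#' @param rod A [rod_model()].
#' @param elec An [electrolyte()].
#' @param options [solver_options()]; `padding_debye` sets the clearance
#'   between the rod surface and the open boundary.
#' @param scale Dimensionless scaling of the rod charge (used by linear-limit
#'   tests); the surface charge is `scale * rod$sigma`.
#' @return A `potential_field` (geometry `"axisymmetric-2d"`) with extra
#'   fields `surface_potential` (area-averaged, kT/e) and the grid needed by
#'   [qcalc_farfield()] and the energy functionals.
#' @export
solve_rod <- function(rod, elec, options = solver_options(padding_debye = 4.5),
                      scale = 1) {
  kap <- elec$kappa_nm1
  lB <- elec$bjerrum_nm
  r <- rod$r
  hl <- rod$l / 2
  if (rod$l <= 0) stop("rod length must be positive")
  pad <- options$padding_debye / kap
  if (r >= pad) stop("rod radius exceeds domain padding")

  # radial axis: a couple of excluded interior cells, fine cells at the
  # surface, stretched to the open boundary
  hr0 <- min(r / 3, 0.05, options$spacing_fine)
  f_rho <- c(seq(0, r, length.out = 3),
             grade_up(r, r + pad, hr0, options$ratio,
                      min(options$spacing_max, 0.3 / kap))[-1])
  # axial half-grid (rod centred at z = 0, symmetric)
  hz_rod <- min(0.5, rod$l / 24)
  f_z <- c(seq(0, hl, length.out = max(2, ceiling(hl / hz_rod)) + 1),
           grade_up(hl, hl + pad, hr0 * 2, options$ratio,
                    min(options$spacing_max, 0.3 / kap))[-1])

  g <- .axisym_assemble(f_z, f_rho, inside = function(zc, rc) rc < r & zc < hl,
                        kap = kap)
  # lateral surface flux: faces in the rho direction crossing rho = r
  sig <- rod$sigma * scale
  b0 <- numeric(g$n_active)
  lat <- g$rho_faces[abs(g$rho_faces$rho - r) < 1e-9 &
                       g$rho_faces$boundary_into_active, , drop = FALSE]
  b0[lat$active_j] <- b0[lat$active_j] + lat$area * 4 * pi * lB * sig

  fit <- pb_newton(g$L, b0, kap^2 * g$vol_active, tol = options$tol,
                   maxit = options$maxit)
  if (!fit$converged)
    stop("rod solve did not converge at b = ", rod$b,
         " (residual ", format(fit$residual, digits = 3), ")")

  psi_full <- rep(NA_real_, g$n_cells)
  psi_full[g$active] <- fit$psi

  # area-averaged surface potential, corrected from the first-cell value by
  # the known surface gradient (flux ~ 1/rho in the thin first cell)
  psi_lat <- fit$psi[lat$active_j]
  rho_c <- g$rc_all[lat$cell_j]
  psi_surf <- psi_lat - (-4 * pi * lB * sig) * r * log(rho_c / r)
  surface_potential <- sum(psi_surf * lat$area) / sum(lat$area)

  new_potential_field(
    "axisymmetric-2d",
    list(z = g$zc_all, rho = g$rc_all), psi_full,
    ifelse(g$active_mask, "electrolyte", "molecular interior"),
    fit$residual, elec,
    meta = list(volume = g$vol_all, lambda = as.numeric(g$active_mask),
                symmetry = 2,   # solved on the z >= 0 half-domain
                energy_conns = g$energy_conns, rod = rod, sigma = sig,
                z_centers = g$z_c, rho_centers = g$rho_c,
                psi_matrix = matrix(psi_full, nrow = length(g$z_c)),
                surface_potential = surface_potential,
                iterations = fit$iterations))
}

# Assemble the axisymmetric FV operator on a tensor grid with an excluded
# (ion-free, charge-on-surface) region given by `inside`(z, rho).
.axisym_assemble <- function(f_z, f_rho, inside, kap) {
  z_c <- axis_centers(f_z); dz <- axis_widths(f_z)
  rho_c <- axis_centers(f_rho); drho <- axis_widths(f_rho)
  nz <- length(z_c); nr <- length(rho_c)
  idx <- function(iz, ir) iz + (ir - 1L) * nz
  zc_all <- rep(z_c, nr); rc_all <- rep(rho_c, each = nz)
  vol_all <- rep(dz, nr) * rep(pi * (f_rho[-1]^2 - f_rho[-(nr + 1)]^2), each = nz)
  excl <- inside(zc_all, rc_all)
  active_mask <- !excl
  act_id <- cumsum(active_mask)            # active index per cell
  n_cells <- nz * nr
  n_active <- sum(active_mask)

  # rho-direction faces between (iz, ir) and (iz, ir+1)
  ir <- rep(seq_len(nr - 1L), each = nz); iz <- rep(seq_len(nz), nr - 1L)
  ci <- idx(iz, ir); cj <- idx(iz, ir + 1L)
  rho_f <- f_rho[ir + 1L]
  area_r <- 2 * pi * rho_f * dz[iz]
  w_r <- area_r / (rho_c[ir + 1L] - rho_c[ir])
  rho_faces <- data.frame(cell_i = ci, cell_j = cj, rho = rho_f,
                          area = area_r, w = w_r)
  rho_faces$boundary_into_active <- excl[ci] & active_mask[cj]
  rho_faces$active_j <- act_id[cj]

  # z-direction faces between (iz, ir) and (iz+1, ir)
  iz2 <- rep(seq_len(nz - 1L), nr); ir2 <- rep(seq_len(nr), each = nz - 1L)
  ci2 <- idx(iz2, ir2); cj2 <- idx(iz2 + 1L, ir2)
  area_z <- pi * (f_rho[ir2 + 1L]^2 - f_rho[ir2]^2)
  w_z <- area_z / (z_c[iz2 + 1L] - z_c[iz2])

  both <- active_mask[ci] & active_mask[cj]
  both2 <- active_mask[ci2] & active_mask[cj2]
  conns <- data.frame(i = act_id[c(ci[both], ci2[both2])],
                      j = act_id[c(cj[both], cj2[both2])],
                      w = c(w_r[both], w_z[both2]))
  energy_conns <- data.frame(i = c(ci[both], ci2[both2]),
                             j = c(cj[both], cj2[both2]),
                             w = c(w_r[both], w_z[both2]))

  # Robin radiation condition on the outer rho and z boundaries
  out_r <- idx(seq_len(nz), nr)
  out_z <- idx(nz, seq_len(nr))
  rR <- sqrt(zc_all[out_r]^2 + f_rho[nr + 1L]^2)
  rZ <- sqrt(f_z[nz + 1L]^2 + rc_all[out_z]^2)
  robin <- data.frame(
    i = c(act_id[out_r], act_id[out_z]),
    w = c(2 * pi * f_rho[nr + 1L] * dz * (kap + 1 / rR),
          pi * (f_rho[-1]^2 - f_rho[-(nr + 1)]^2) * (kap + 1 / rZ)))
  robin <- robin[active_mask[c(out_r, out_z)], , drop = FALSE]

  L <- fv_operator(n_active, conns, robin)

  list(L = L, n_active = n_active, n_cells = n_cells, active = which(active_mask),
       active_mask = active_mask, vol_active = vol_all[active_mask],
       vol_all = vol_all, zc_all = zc_all, rc_all = rc_all,
       z_c = z_c, rho_c = rho_c, rho_faces = rho_faces,
       energy_conns = energy_conns)
}

#' Nonlinear PB solution around an infinite charged cylinder
#'
#' Radial (1D) nonlinear PB solve for an infinitely long cylinder of radius
#' `r` carrying a fixed line charge density, used as the closed-geometry
#' oracle for charge renormalization (Manning limit) and for the analytic
#' cylinder formula.
#'
#' @param r Cylinder radius (nm).
#' @param nu Line charge density (e/nm, negative for nucleic acids).
#' @param elec An [electrolyte()].
#' @param options [solver_options()].
#' @return A list with the radial profile (`rho`, `psi`), the surface
#'   potential, and `nu_eff`: the effective (renormalized) line density from
#'   matching the far field to the linearized form
#'   \eqn{\psi = 2\nu_{eff} l_B K_0(\kappa\rho)}.
#' @export
solve_rod_infinite <- function(r, nu, elec, options = solver_options()) {
  kap <- elec$kappa_nm1
  lB <- elec$bjerrum_nm
  sig <- nu / (2 * pi * r)
  pad <- max(options$padding_debye, 4.5) / kap
  hr0 <- min(r / 4, 0.02)
  f_rho <- grade_up(r, r + pad, hr0, options$ratio,
                    min(options$spacing_max, 0.25 / kap))
  rho <- axis_centers(f_rho)
  n <- length(rho)
  area <- 2 * pi * f_rho          # per unit length
  vol <- pi * (f_rho[-1]^2 - f_rho[-(n + 1)]^2)
  w <- area[2:n] / diff(rho)
  conns <- data.frame(i = seq_len(n - 1L), j = 2:n, w = w)
  robin <- data.frame(i = n, w = area[n + 1L] * (kap + 1 / f_rho[n + 1L]))
  L <- fv_operator(n, conns, robin)
  b0 <- numeric(n)
  b0[1] <- area[1] * 4 * pi * lB * sig
  fit <- pb_newton(L, b0, kap^2 * vol, tol = options$tol, maxit = options$maxit)
  if (!fit$converged) stop("infinite-rod solve did not converge")
  psi <- fit$psi
  # far-field match on 1.5-3 Debye lengths
  sel <- rho >= r + 1.5 / kap & rho <= r + 3 / kap
  K0 <- besselK(kap * rho[sel], 0)
  nu_eff <- sum(psi[sel] * K0) / sum(K0^2) / (2 * lB)
  psi_surf <- psi[1] - (-4 * pi * lB * sig) * r * log(rho[1] / r)
  list(rho = rho, psi = psi, surface_potential = psi_surf,
       nu_eff = nu_eff, residual = fit$residual)
}
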
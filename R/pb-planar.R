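#' Solver options for the Poisson-Boltzmann solvers
#'
#' @param spacing_fine Fine grid spacing (nm) used in the uniform band around
#'   charged surfaces / molecular structures.
#' @param ratio Geometric stretching factor of cell widths away from the fine
#'   band (1 = uniform grid).
#' @param spacing_max Cap on the stretched cell width (nm).
#' @param padding_debye Clearance between the object and the open boundary,
#'   in Debye lengths.  Must be >= 1.5; the open boundary carries a radiation
#'   (Robin) condition so moderate padding already gives boundary errors well
#'   below 1e-3 kT/e.
#' @param tol Relative nonlinear residual tolerance.
#' @param maxit Maximum Newton iterations.
#' @param eps_mol Relative permittivity of the ion-free molecular interior.
#' @return A `solver_options` list.
#' @export
solver_options <- function(spacing_fine = 0.1, ratio = 1.2, spacing_max = Inf,
                           padding_debye = 8, tol = 1e-8, maxit = 60,
                           eps_mol = 2) {
  stopifnot(tol > 0, spacing_fine > 0, ratio >= 1, padding_debye >= 1.5)
  structure(list(spacing_fine = spacing_fine, ratio = ratio,
                 spacing_max = spacing_max, padding_debye = padding_debye,
                 tol = tol, maxit = maxit, eps_mol = eps_mol),
            class = "solver_options")
}

#' Nonlinear PB solution of the parallel-plate slit
#'
#' Solves the 1D nonlinear Poisson-Boltzmann equation
#' \eqn{\psi'' = \kappa^2 \sinh\psi} between two constant-charge walls at
#' \eqn{x = \pm h}, exploiting midplane symmetry.
#'
#' @param device A [slit_device()]; its wall charge (or surface potential,
#'   converted via the Grahame relation) sets the Neumann flux at the walls.
#' @param elec An [electrolyte()] (1:1 salt).
#' @param options [solver_options()].
#' @param halfwidth Optional override of the half-gap (nm); defaults to
#'   `device$h`.  Use a large value to recover the isolated wall.
#' @return A `potential_field` (geometry `"planar-1d"`) with extra fields
#'   `wall_potential` and `midplane_potential` (kT/e).
#' @export
solve_planar_slit <- function(device, elec, options = solver_options(),
                              halfwidth = NULL) {
  h <- if (is.null(halfwidth)) device$h else halfwidth
  sig <- .device_sigma(device, elec)
  lB <- elec$bjerrum_nm
  kap <- elec$kappa_nm1

  # fine cells against the wall, stretched toward the midplane
  h0 <- min(options$spacing_fine, 0.02 / kap, h / 40)
  faces <- grade_down(0, h, h0, options$ratio,
                      min(options$spacing_max, 0.25 / kap))
  x <- axis_centers(faces)
  dx <- axis_widths(faces)
  n <- length(x)

  # interior fluxes; midplane face (x=0) is zero-flux by symmetry
  w <- 1 / (x[-1] - x[-n])
  conns <- data.frame(i = seq_len(n - 1L), j = seq_len(n - 1L) + 1L, w = w)
  L <- fv_operator(n, conns)
  b0 <- numeric(n)
  b0[n] <- 4 * pi * lB * sig      # wall-charge flux into the last cell
  svol <- kap^2 * dx

  fit <- pb_newton(L, b0, svol, tol = options$tol, maxit = options$maxit)
  if (!fit$converged)
    stop("planar slit solve did not converge (residual ",
         format(fit$residual, digits = 3), "); refine grid or tolerance")

  psi <- fit$psi
  # wall potential from the cell value and the known wall-normal gradient
  psi_wall <- psi[n] + 4 * pi * lB * sig * (h - x[n])
  # midplane value by symmetric (zero-slope) quadratic extrapolation
  psi_mid <- if (n >= 2) {
    (psi[1] * x[2]^2 - psi[2] * x[1]^2) / (x[2]^2 - x[1]^2)
  } else psi[1]

  new_potential_field(
    "planar-1d", list(x = x), psi, rep("electrolyte", n), fit$residual, elec,
    meta = list(volume = dx, device = device, sigma_w = sig,
                wall_potential = psi_wall, midplane_potential = psi_mid,
                iterations = fit$iterations))
}

#' Isolated-wall surface potential by direct solution
#'
#' Numerically solves the single charged wall (a slit of very large gap) and
#' reports the wall potential; the closed-form counterpart is
#' [phis_from_sigma()].
#'
#' @inheritParams solve_planar_slit
#' @param sigma_w Wall charge density (e/nm^2).
#' @return Wall potential in kT/e.
#' @export
isolated_wall_potential <- function(sigma_w, elec,
                                    options = solver_options()) {
  dev <- slit_device(h = 14 * elec$debye_nm, sigma_w = sigma_w)
  solve_planar_slit(dev, elec, options)$wall_potential
}
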
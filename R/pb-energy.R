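#' Electrostatic free energy of a solved field
#'
#' Evaluates the Poisson-Boltzmann free-energy functional
#' \deqn{F_{el} = \int_V \left[\frac{\epsilon\epsilon_0}{2} E\cdot E
#'   - 2 c_0 N_A k_B T(\cosh\psi - \psi\sinh\psi - 1)\right] dV}
#' over the solvent (electrolyte) region only, using the same finite-volume
#' discretization as the solve: the gradient term is accumulated over
#' solvent-solvent faces, the ionic term over solvent cells.
#'
#' @param field A converged `potential_field`.
#' @return Free energy in units of \eqn{k_B T}.
#' @export
free_energy <- function(field) {
  .check_converged(field)
  elec <- field$electrolyte
  lB <- elec$bjerrum_nm
  kap2 <- elec$kappa_nm1^2
  psi <- field$psi
  lam <- field$lambda
  act <- which(lam > 0 & !is.na(psi))
  # gradient term: sum over faces of (A/d) (dpsi)^2 equals int |grad psi|^2
  ec <- field$energy_conns       # full-grid cell indices, solvent-solvent faces
  grad2 <- sum(ec$w * (psi[ec$i] - psi[ec$j])^2)
  psa <- psi[act]
  ionic <- sum(field$volume[act] * (cosh(psa) - psa * sinh(psa) - 1))
  sym <- if (is.null(field$symmetry)) 1 else field$symmetry
  sym * (grad2 / (8 * pi * lB) - kap2 / (4 * pi * lB) * ionic)
}

#' Net ionic charge in the electrolyte
#'
#' Volume integral of the mobile ion charge density
#' \eqn{\rho_e = \sum_i c_i N_A e z_i e^{-z_i\psi}} over the solvent region.
#' For an isolated charged object in bulk this must equal minus the object's
#' structural charge (screening-cloud electroneutrality).
#'
#' @param field A converged `potential_field` of an isolated object in bulk.
#' @return Ionic charge in units of e.
#' @export
ionic_charge_integral <- function(field) {
  .check_converged(field)
  elec <- field$electrolyte
  lB <- elec$bjerrum_nm
  kap2 <- elec$kappa_nm1^2
  psi <- field$psi
  act <- which(field$lambda > 0 & !is.na(psi))
  sym <- if (is.null(field$symmetry)) 1 else field$symmetry
  -sym * kap2 / (4 * pi * lB) * sum(field$volume[act] * sinh(psi[act]))
}

#' Counterion excess and coion deficit of the ion atmosphere
#'
#' Integrates the excess counterion density \eqn{c_0(e^{-z\psi} - 1)} and the
#' coion depletion \eqn{c_0(1 - e^{z\psi})} over the electrolyte region for a
#' 1:1 salt around a (negatively charged) object.  The coion deficit is
#' reported as a positive depletion, so `gamma_plus + gamma_minus` equals the
#' object's structural charge magnitude by electroneutrality.
#'
#' @param field A converged bulk `potential_field`.
#' @param per_phosphate Optional number of charge sites by which to normalise
#'   (e.g. `n_b + 1`); if given, per-site columns are added.
#' @return A one-row tibble with `gamma_plus`, `gamma_minus` (ions per
#'   molecule) and their sum.
#' @export
counterion_excess <- function(field, per_phosphate = NULL) {
  .check_converged(field)
  elec <- field$electrolyte
  ctilde <- elec$kappa_nm1^2 / (8 * pi * elec$bjerrum_nm)   # salt density nm^-3
  psi <- field$psi
  act <- which(field$lambda > 0 & !is.na(psi))
  sym <- if (is.null(field$symmetry)) 1 else field$symmetry
  v <- sym * field$volume[act]
  gp <- ctilde * sum(v * (exp(-psi[act]) - 1))
  gm <- ctilde * sum(v * (1 - exp(psi[act])))
  out <- tibble::tibble(gamma_plus = gp, gamma_minus = gm, total = gp + gm)
  if (!is.null(per_phosphate)) {
    out$gamma_plus_per_site <- gp / per_phosphate
    out$gamma_minus_per_site <- gm / per_phosphate
  }
  out
}

.check_converged <- function(field) {
  stopifnot(inherits(field, "potential_field"))
  if (is.null(field$residual) || !is.finite(field$residual))
    stop("field carries no residual; not a converged solve")
}
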
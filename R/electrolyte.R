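#' Define an electrolyte
#'
#' Bundles the ionic composition and solvent parameters that set the two
#' lengths governing screened electrostatics in solution: the Debye length
#' \eqn{\kappa^{-1}} and the Bjerrum length \eqn{l_B}.
#'
#' @param c0 Convenience shortcut: molar concentration of a symmetric 1:1
#'   salt (mol/L).  Ignored when `species` is given.
#' @param species A data frame with columns `z` (integer valence) and
#'   `c` (bulk concentration, mol/L), one row per ionic species.
#' @param temperature Absolute temperature in K.
#' @param epsilon_r Relative permittivity of the solvent.
#'
#' @return An object of class `electrolyte`: a list with the species table,
#'   `temperature`, `epsilon_r`, and derived `debye_nm` and `bjerrum_nm`.
#'
#' @details Bulk electroneutrality (\eqn{\sum_i z_i c_i = 0}) is enforced.
#'   For a 1:1 salt at 298.15 K in water (\eqn{\epsilon_r = 78.5}) the
#'   derived Debye length agrees with the familiar
#'   \eqn{\kappa^{-1} \approx 0.304/\sqrt{c_0}} nm to better than 1%.
#'
#' @examples
#' debye_length(electrolyte(1.2e-3))  # ~ 8.78 nm
#' @export
electrolyte <- function(c0 = NULL, species = NULL, temperature = 298.15,
                        epsilon_r = 78.5) {
  if (is.null(species)) {
    if (is.null(c0)) stop("supply either `c0` (1:1 salt) or a `species` table")
    if (c0 <= 0) stop("salt concentration must be positive")
    species <- tibble::tibble(z = c(1L, -1L), c = c(c0, c0))
  } else {
    species <- tibble::as_tibble(species)
    if (!all(c("z", "c") %in% names(species)))
      stop("`species` needs columns `z` and `c`")
    if (nrow(species) == 0) stop("empty species list")
    if (any(species$c <= 0)) stop("species concentrations must be positive")
  }
  if (abs(sum(species$z * species$c)) > 1e-9 * sum(abs(species$z) * species$c))
    stop("bulk electrolyte is not electroneutral (sum z_i c_i != 0)")
  lB <- .bjerrum_nm(temperature, epsilon_r)
  # kappa^2 = 4 pi l_B sum_i n_i z_i^2  (n_i in nm^-3, lengths in nm)
  kap2 <- 4 * pi * lB * sum(.molar_to_nm3(species$c) * species$z^2)
  structure(list(
    species = species, temperature = temperature, epsilon_r = epsilon_r,
    bjerrum_nm = lB, kappa_nm1 = sqrt(kap2), debye_nm = 1 / sqrt(kap2)
  ), class = "electrolyte")
}

.bjerrum_nm <- function(temperature, epsilon_r) {
  with(.const, e^2 / (4 * pi * eps0 * epsilon_r * kB * temperature)) * 1e9
}

#' Debye screening length
#'
#' @param elec An [electrolyte()].
#' @return Screening length \eqn{\kappa^{-1}} in nm, from the full
#'   ionic-strength definition.
#' @export
debye_length <- function(elec) {
  stopifnot(inherits(elec, "electrolyte"))
  elec$debye_nm
}

#' Bjerrum length
#'
#' @param elec An [electrolyte()].
#' @return The Bjerrum length \eqn{l_B = e^2/(4\pi\epsilon_0\epsilon_r k_B T)}
#'   in nm (about 0.71 nm in water at 298 K).
#' @export
bjerrum_length <- function(elec) {
  stopifnot(inherits(elec, "electrolyte"))
  elec$bjerrum_nm
}

#' @export
print.electrolyte <- function(x, ...) {
  cat("<electrolyte>", nrow(x$species), "species, T =", x$temperature,
      "K, eps_r =", x$epsilon_r, "\n  kappa^-1 =",
      signif(x$debye_nm, 4), "nm, l_B =", signif(x$bjerrum_nm, 4), "nm\n")
  invisible(x)
}

# is this a single symmetric 1:1 salt?
.is_11_salt <- function(elec) {
  s <- elec$species
  nrow(s) == 2 && setequal(s$z, c(1L, -1L)) && diff(range(s$c)) < 1e-12
}

#' Nanoslit trap device geometry
#'
#' Describes the parallel-plate nanoslit with a nanostructured pocket that
#' forms the electrostatic fluidic trap.  Exactly one of `sigma_w` (wall
#' surface charge density, e/nm^2) and `phi_s` (effective wall surface
#' potential, kT/e) is primary; the other is derived for a given
#' electrolyte via the isolated-wall Grahame relation.
#'
#' @param h Slit half-height (nm); the wall-to-wall gap is `2h`.
#' @param d Pocket depth (nm); the gap in the pocket region is `2h + d`.
#' @param pocket_radius In-plane pocket radius (nm).
#' @param sigma_w Wall surface charge density (e/nm^2, negative for silica).
#' @param phi_s Effective wall surface potential (kT/e, negative).
#' @param span Channel span (nm); metadata only.
#' @return A `slit_device` object.
#' @export
slit_device <- function(h, d = 280, pocket_radius = 300,
                        sigma_w = NULL, phi_s = NULL, span = 5000) {
  if (h <= 0 || d <= 0) stop("h and d must be positive")
  if (is.null(sigma_w) == is.null(phi_s))
    stop("give exactly one of `sigma_w` or `phi_s`")
  structure(list(h = h, d = d, pocket_radius = pocket_radius,
                 sigma_w = sigma_w, phi_s = phi_s, span = span),
            class = "slit_device")
}

#' @export
print.slit_device <- function(x, ...) {
  cat("<slit_device> 2h =", 2 * x$h, "nm, pocket d =", x$d, "nm")
  if (!is.null(x$phi_s)) cat(", phi_s =", x$phi_s, "kT/e")
  if (!is.null(x$sigma_w)) cat(", sigma_w =", x$sigma_w, "e/nm^2")
  cat("\n")
  invisible(x)
}

#' Wall charge density from isolated-wall surface potential (and back)
#'
#' For a single charged plate in a 1:1 electrolyte the nonlinear
#' Poisson-Boltzmann problem has the closed-form Grahame solution
#' \eqn{4\pi l_B \sigma = 2\kappa \sinh(\psi_s/2)}; these helpers convert
#' between the constant-charge boundary condition used by the solvers and
#' the effective surface potential quoted for the devices.
#'
#' @param phi_s,sigma_w Surface potential (kT/e) / charge density (e/nm^2).
#' @param elec An [electrolyte()] (must be a single 1:1 salt).
#' @return The converted quantity.
#' @export
sigma_from_phis <- function(phi_s, elec) {
  stopifnot(.is_11_salt(elec))
  2 * elec$kappa_nm1 * sinh(phi_s / 2) / (4 * pi * elec$bjerrum_nm)
}

#' @rdname sigma_from_phis
#' @export
phis_from_sigma <- function(sigma_w, elec) {
  stopifnot(.is_11_salt(elec))
  2 * asinh(4 * pi * elec$bjerrum_nm * sigma_w / (2 * elec$kappa_nm1))
}

# resolve device wall charge for a given electrolyte
.device_sigma <- function(device, elec) {
  if (!is.null(device$sigma_w)) device$sigma_w
  else sigma_from_phis(device$phi_s, elec)
}

# midplane potential estimate phi_m = 2 phi_s exp(-kappa h) (superposition)
#' Superposition estimate of the slit midplane potential
#'
#' @param device A [slit_device()] with `phi_s` set (or derivable).
#' @param elec An [electrolyte()].
#' @return \eqn{\phi_m \approx 2\phi_s e^{-\kappa h}} in kT/e.
#' @export
midplane_potential_estimate <- function(device, elec) {
  phis <- if (!is.null(device$phi_s)) device$phi_s
          else phis_from_sigma(device$sigma_w, elec)
  2 * phis * exp(-device$h / elec$debye_nm)
}
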
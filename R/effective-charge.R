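#' Effective charge from far-field matching
#'
#' Matches the numerical nonlinear PB far field of an isolated object in bulk
#' to the linearized (Debye-Hueckel) field of the same charge geometry with an
#' adjustable total charge.  The fitted amplitude is the renormalized
#' effective charge \eqn{q_{calc}}: the charge a far-away observer (or a
#' weakly coupled trap wall) attributes to the molecule.
#'
#' @param field A converged bulk `potential_field` from [solve_rod()] or
#'   [solve_structure_grid()].
#' @param shell_debye Distance of the sampling shell from the molecular
#'   surface, in Debye lengths (default 2.5, i.e. within the 2-3
#'   \eqn{\kappa^{-1}} far-field window).
#' @param n_points Number of sample points on the shell.
#' @return An `effective_charge_result`: a one-row tibble with `q_calc` (e),
#'   `eta`, `phi_m`, `dF_el`, the core/dye components and a method tag.
#' @export
qcalc_farfield <- function(field, shell_debye = 2.5, n_points = 48) {
  .check_converged(field)
  elec <- field$electrolyte
  kap <- elec$kappa_nm1
  lB <- elec$bjerrum_nm
  d <- shell_debye / kap

  if (field$geometry == "axisymmetric-2d") {
    rod <- field$rod
    hl <- rod$l / 2
    cap <- rod$r + d
    # sample points on the capsule at distance d from the rod surface
    t_side <- seq(0, 1, length.out = ceiling(n_points * 0.6))
    alpha <- seq(1e-3, pi / 2, length.out = n_points - length(t_side))
    pz <- c(t_side * hl, hl + cap * sin(alpha))
    pr <- c(rep(cap, length(t_side)), cap * cos(alpha))
    # the far field decays exponentially: interpolate its log magnitude
    sgn <- sign(rod$q_str)
    psi_num <- sgn * exp(.interp2(field$z_centers, field$rho_centers,
                                  log(pmax(sgn * field$psi_matrix, 1e-300)),
                                  pz, pr))
    # unit-charge linearized field: screened Coulomb integrated along the axis
    zq <- seq(-hl, hl, length.out = 241)
    wq <- rep(1, length(zq)); wq[c(1, length(zq))] <- 0.5
    wq <- wq / sum(wq)
    psi_unit <- vapply(seq_along(pz), function(k) {
      dist <- sqrt((pz[k] - zq)^2 + pr[k]^2)
      lB * sum(wq * exp(-kap * dist) / dist)
    }, numeric(1))
    q_str <- rod$q_str
  } else if (field$geometry == "cartesian-3d") {
    ctr <- field$centroid
    sites <- field$charge_sites      # matrix x,y,z + column q
    # shell: distance d from the site cloud measured from each direction's
    # maximal extent -> sample on a sphere of radius max site radius + d
    rad <- max(sqrt(rowSums((sites[, 1:3, drop = FALSE] -
                               matrix(ctr, nrow(sites), 3, byrow = TRUE))^2)))
    rs <- rad + d
    pts <- .fibonacci_sphere(n_points) * rs +
      matrix(ctr, n_points, 3, byrow = TRUE)
    sgn <- sign(field$q_str)
    psi_num <- sgn * exp(.interp3(field$x_centers, field$y_centers,
                                  field$z_centers,
                                  log(pmax(sgn * field$psi_array, 1e-300)),
                                  pts))
    qtot <- sum(sites[, 4])
    psi_unit <- vapply(seq_len(nrow(pts)), function(k) {
      dist <- sqrt(colSums((t(sites[, 1:3, drop = FALSE]) - pts[k, ])^2))
      lB * sum(sites[, 4] / qtot * exp(-kap * dist) / dist)
    }, numeric(1))
    q_str <- field$q_str
  } else {
    stop("far-field matching needs a bulk rod or 3D structure field")
  }
  keep <- is.finite(psi_num) & is.finite(psi_unit)
  if (!all(keep)) stop("far-field shell leaves the solved domain; increase padding")
  q_calc <- sum(psi_num * psi_unit) / sum(psi_unit^2)
  new_effective_charge(q_calc, q_str, method = "far-field")
}

new_effective_charge <- function(q_calc, q_str, method,
                                 phi_m = NA_real_, dF_el = NA_real_,
                                 q_dye = 0) {
  out <- tibble::tibble(
    q_calc = q_calc + q_dye, q_core = q_calc, q_dye = q_dye,
    q_str = q_str, eta = (q_calc + q_dye) / q_str,
    phi_m = phi_m, dF_el = dF_el, method = method)
  class(out) <- c("effective_charge_result", class(out))
  out
}

#' Charge renormalization factor
#'
#' @param q_eff Effective charge (e).
#' @param q_str Structural charge (e); must be nonzero.
#' @return \eqn{\eta = q_{eff}/q_{str}} (dimensionless, 1 means no
#'   renormalization).
#' @export
renormalization_factor <- function(q_eff, q_str) {
  if (any(q_str == 0)) stop("zero structural charge")
  q_eff / q_str
}

#' Analytic effective charge of a long charged cylinder
#'
#' Closed-form estimate of the renormalized charge of a uniformly charged
#' cylinder of radius `R` and length \eqn{l \gg \kappa^{-1}}:
#' \deqn{|q_{eff}/e| = (l/l_B)\left(1 -
#'   \frac{\ln[|q_{str}/e|\, l_B/l]}{2\ln(\kappa R)}\right)}
#' valid for \eqn{\kappa R < 1}.  As \eqn{\kappa R \to 0} the effective line
#' density tends to the Manning limit \eqn{1/l_B}.
#'
#' @param l Cylinder length (nm).
#' @param q_str Structural charge (e).
#' @param R Cylinder radius (nm).
#' @param elec An [electrolyte()].
#' @return A one-row tibble with `q_eff_abs` (e) and `manning_limit`
#'   (\eqn{l/l_B}, e).
#' @export
analytic_cylinder_qeff <- function(l, q_str, R, elec) {
  kap <- elec$kappa_nm1
  lB <- elec$bjerrum_nm
  if (kap * R >= 1) stop("outside stated validity regime: kappa R >= 1")
  if (l < 3 / kap)
    warning("l is not >> 1/kappa; the analytic formula degrades for short rods")
  q <- (l / lB) * (1 - log(abs(q_str) * lB / l) / (2 * log(kap * R)))
  tibble::tibble(q_eff_abs = q, manning_limit = l / lB)
}

#' Add the dye effective-charge contribution
#'
#' Fluorescent labels carry structural charge of their own; their renormalized
#' contribution is added to the dye-free molecular effective charge after the
#' PB calculation, and the structural-charge bookkeeping is updated in step
#' (two labels shift an \eqn{-(n_b+1)e} core to \eqn{-(n_b+3)e}).
#'
#' @param result An `effective_charge_result` (dye-free core).
#' @param n_dyes Number of attached dye molecules (>= 0).
#' @param q_dye_total Total renormalized dye contribution (e) for the labelled
#'   configuration; the default -0.62 e is the two-dye value for a 60-base
#'   strand and can be overridden per `n_b`.
#' @param q_str_dye Structural charge per dye (e), default -1.
#' @return The updated `effective_charge_result` with separate core and dye
#'   components.
#' @export
add_dye_effective_charge <- function(result, n_dyes,
                                     q_dye_total = -0.62, q_str_dye = -1) {
  stopifnot(inherits(result, "effective_charge_result"))
  if (n_dyes < 0) stop("negative dye count")
  if (n_dyes == 0) return(result)
  out <- result
  out$q_dye <- q_dye_total
  out$q_calc <- out$q_core + q_dye_total
  out$q_str <- out$q_str + n_dyes * q_str_dye
  out$eta <- out$q_calc / out$q_str
  out
}

#' Linear relation between counterion excess and renormalization factor
#'
#' Fits \eqn{\Gamma_i = a_1 + a_2 \eta} by least squares over a sweep of rod
#' models (varying axial spacing at fixed length and salt); stronger
#' renormalization (smaller \eqn{\eta}) goes with a larger counterion excess,
#' so \eqn{a_2 < 0}.
#'
#' @param sweep A data frame with columns `gamma` and `eta` (>= 4 rows).
#' @return A one-row tibble with `a1`, `a2`, and the residual standard error.
#' @export
gamma_eta_fit <- function(sweep) {
  sweep <- tibble::as_tibble(sweep)
  stopifnot(all(c("gamma", "eta") %in% names(sweep)))
  if (nrow(sweep) < 4) stop("need at least 4 (gamma, eta) pairs")
  if (diff(range(sweep$eta)) < 1e-12) {
    # degenerate eta range: slope exactly zero by convention
    return(tibble::tibble(a1 = mean(sweep$gamma), a2 = 0, sigma = 0))
  }
  if (diff(range(sweep$gamma)) < 1e-12) {
    # gamma constant over eta: the slope is exactly zero
    return(tibble::tibble(a1 = sweep$gamma[1], a2 = 0, sigma = 0))
  }
  fit <- stats::lm(gamma ~ eta, data = sweep)
  rss <- sum(stats::residuals(fit)^2)
  tibble::tibble(a1 = unname(stats::coef(fit)[1]),
                 a2 = unname(stats::coef(fit)[2]),
                 sigma = sqrt(rss / max(1, nrow(sweep) - 2)))
}

# bilinear interpolation on a tensor grid (matrix v indexed [x, y])
.interp2 <- function(xg, yg, v, xp, yp) {
  ix <- findInterval(xp, xg, all.inside = TRUE)
  iy <- findInterval(yp, yg, all.inside = TRUE)
  tx <- (xp - xg[ix]) / (xg[ix + 1] - xg[ix])
  ty <- (yp - yg[iy]) / (yg[iy + 1] - yg[iy])
  v00 <- v[cbind(ix, iy)]; v10 <- v[cbind(ix + 1, iy)]
  v01 <- v[cbind(ix, iy + 1)]; v11 <- v[cbind(ix + 1, iy + 1)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

# trilinear interpolation on a tensor grid (3D array v)
.interp3 <- function(xg, yg, zg, v, pts) {
  ix <- findInterval(pts[, 1], xg, all.inside = TRUE)
  iy <- findInterval(pts[, 2], yg, all.inside = TRUE)
  iz <- findInterval(pts[, 3], zg, all.inside = TRUE)
  tx <- (pts[, 1] - xg[ix]) / (xg[ix + 1] - xg[ix])
  ty <- (pts[, 2] - yg[iy]) / (yg[iy + 1] - yg[iy])
  tz <- (pts[, 3] - zg[iz]) / (zg[iz + 1] - zg[iz])
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
      (if (dz) tz else 1 - tz)
    out <- out + wgt * v[cbind(ix + dx, iy + dy, iz + dz)]
  }
  out
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Effective charge from the slit/pocket free-energy difference
#'
#' The measurement-route definition: solve the molecule at the midplane of
#' the charged slit and in bulk (the deep pocket, where the walls are too far
#' to matter), form the electrostatic free-energy difference
#' \eqn{\Delta F_{el} = F_{slit} - F_{pocket}}, and divide by the
#' molecule-free midplane potential, \eqn{q_{calc} = \Delta F_{el}/\phi_m}.
#' Identical to the far-field definition in the linear-response regime of
#' the trap; substantially more expensive (two 3D solves).
#'
#' @param structure An `atomic_structure`, or a [rod_model()] (converted to
#'   an equivalent axial bead chain whose ion-accessible surface reproduces
#'   the rod radius).
#' @param device A [slit_device()].
#' @param elec An [electrolyte()].
#' @param options [solver_options()] for the 3D solves.
#' @return An `effective_charge_result` with `dF_el` and `phi_m` filled in.
#' @export
qcalc_slit_pocket <- function(structure, device, elec,
                              options = solver_options(spacing_fine = 0.15,
                                                       ratio = 1.22,
                                                       padding_debye = 3.2)) {
  if (inherits(structure, "rod_model")) structure <- rod_to_beads(structure)
  f_slit <- solve_structure_grid(structure, elec, options, "slit", device)
  phi_m <- f_slit$phi_m
  if (abs(phi_m) < 1e-4)
    stop("midplane potential below 1e-4 kT/e: effective charge ill-conditioned")
  F_slit <- free_energy(f_slit) -
    f_slit$walls_free_energy_per_area * f_slit$domain_area
  # pocket (deep-gap) reference on the identical grid, so the molecular
  # self-energy discretization cancels exactly in the difference
  f_bulk <- solve_structure_grid(structure, elec, options, "bulk",
                                 axes = f_slit$axes)
  F_pocket <- free_energy(f_bulk)
  dF <- F_slit - F_pocket
  new_effective_charge(dF / phi_m, structure$q_str, method = "slit-pocket",
                       phi_m = phi_m, dF_el = dF)
}

#' Axial bead-chain equivalent of a rigid rod
#'
#' Beads of van der Waals radius \eqn{r - w} on the rod axis at the charge
#' spacing, carrying the rod charge in equal point charges; with the
#' ion-exclusion width `w` the ion-accessible surface is a capsule of the
#' rod radius.
#'
#' @param rod A [rod_model()].
#' @param w Ion-exclusion width (nm).
#' @return An `atomic_structure`.
#' @export
rod_to_beads <- function(rod, w = 0.2) {
  n_sites <- rod$n_b + 1L
  # chain along x: in the slit geometry the molecular axis lies parallel to
  # the walls (the free-energy minimum orientation); z is the gap direction
  x <- seq(-rod$l / 2, rod$l / 2, length.out = n_sites)
  atomic_structure(
    tibble::tibble(name = "P", x = x, y = 0, z = 0,
                   charge = rod$q_str / n_sites,
                   radius = max(rod$r - w, 0.05)),
    w = w, provenance = sprintf("bead rod r=%g b=%g n_b=%d",
                                rod$r, rod$b, rod$n_b))
}
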
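#' Nonlinear PB solution of the slit-with-pocket cross-section
#'
#' Solves the 2D nonlinear Poisson-Boltzmann equation on a cross-section
#' through the trap: a slit of gap `2h` whose lower wall is recessed by the
#' pocket depth `d` over the pocket radius, all walls carrying the same
#' constant charge density.  The key device observable is the midplane
#' potential offset \eqn{\Delta\phi_{mid}} between the slit region and the
#' (much deeper, essentially field-free) pocket region: the lever arm that
#' converts molecular effective charge into trap depth.
#'
#' @param device A [slit_device()].
#' @param elec An [electrolyte()].
#' @param options [solver_options()].
#' @return A `potential_field` (geometry `"slit-pocket-2d"`) with extra
#'   fields `dphi_mid` (kT/e), `phi_mid_slit`, `phi_mid_pocket`.
#' @export
solve_slit_pocket <- function(device, elec, options = solver_options()) {
  h <- device$h; d <- device$d; a <- device$pocket_radius
  kap <- elec$kappa_nm1
  lB <- elec$bjerrum_nm
  sig <- .device_sigma(device, elec)
  if (d < 3 * elec$debye_nm)
    warning("pocket depth < 3 Debye lengths: pocket is not decoupled from the slit")

  # in-plane axis s: pocket edge at s = a, far slit out to a + several kappa^-1
  S <- a + max(6 / kap, 60)
  hs <- min(2.5, a / 12)
  f_s <- axis_banded(0, max(0, a - 12), a + 12, S, hs,
                     ratio = 1.25, hmax = max(4, 0.5 / kap))
  if (!any(abs(f_s - a) < 1e-9)) f_s <- sort(c(f_s, a))
  # gap axis y: fine cells against every wall level (y = h, -h, -h-d)
  hy <- min(0.35, h / 30)
  hymax <- min(2.5, 0.25 / kap)
  f_y <- merge_faces(c(
    grade_up(-h - d, -h - d / 2, hy, 1.3, hymax),
    grade_down(-h - d / 2, -h, hy, 1.3, hymax),
    grade_up(-h, 0, hy, 1.3, hymax),
    grade_down(0, h, hy, 1.3, hymax)), tol = hy * 1e-4)

  s_c <- axis_centers(f_s); ds <- axis_widths(f_s); ns <- length(s_c)
  y_c <- axis_centers(f_y); dy <- axis_widths(f_y); ny <- length(y_c)
  idx <- function(is, iy) is + (iy - 1L) * ns
  sc_all <- rep(s_c, ny); yc_all <- rep(y_c, each = ns)
  vol_all <- rep(ds, ny) * rep(dy, each = ns)       # per unit depth
  # masked wall material: below the lower wall outside the pocket
  excl <- yc_all < -h & sc_all > a
  active_mask <- !excl
  act_id <- cumsum(active_mask)
  n_active <- sum(active_mask)

  # s-direction faces
  is1 <- rep(seq_len(ns - 1L), ny); iy1 <- rep(seq_len(ny), each = ns - 1L)
  ci <- idx(is1, iy1); cj <- idx(is1 + 1L, iy1)
  w1 <- dy[iy1] / (s_c[is1 + 1L] - s_c[is1])
  a1 <- dy[iy1]
  # y-direction faces
  is2 <- rep(seq_len(ns), ny - 1L); iy2 <- rep(seq_len(ny - 1L), each = ns)
  ci2 <- idx(is2, iy2); cj2 <- idx(is2, iy2 + 1L)
  w2 <- ds[is2] / (y_c[iy2 + 1L] - y_c[iy2])
  a2 <- ds[is2]

  both1 <- active_mask[ci] & active_mask[cj]
  both2 <- active_mask[ci2] & active_mask[cj2]
  conns <- data.frame(i = act_id[c(ci[both1], ci2[both2])],
                      j = act_id[c(cj[both1], cj2[both2])],
                      w = c(w1[both1], w2[both2]))
  energy_conns <- data.frame(i = c(ci[both1], ci2[both2]),
                             j = c(cj[both1], cj2[both2]),
                             w = c(w1[both1], w2[both2]))
  L <- fv_operator(n_active, conns)

  b0 <- numeric(n_active)
  add_flux <- function(cells, areas) {
    ids <- act_id[cells]
    ok <- active_mask[cells]
    b0[ids[ok]] <<- b0[ids[ok]] + areas[ok] * 4 * pi * lB * sig
  }
  # top wall (y = h): boundary of cells in the last y row
  add_flux(idx(seq_len(ns), ny), ds)
  # pocket floor (y = -h - d): first y row, pocket side only
  add_flux(idx(seq_len(ns), 1L), ds * (s_c <= a))
  # slit lower wall (y = -h): faces between active and masked cells
  low <- which(active_mask[cj2] & excl[ci2])       # cell above a wall cell
  b0[act_id[cj2[low]]] <- b0[act_id[cj2[low]]] + a2[low] * 4 * pi * lB * sig
  # pocket side wall (s = a): faces between pocket cells and masked cells
  side <- which(active_mask[ci] & excl[cj])
  b0[act_id[ci[side]]] <- b0[act_id[ci[side]]] + a1[side] * 4 * pi * lB * sig

  fit <- pb_newton(L, b0, kap^2 * vol_all[active_mask], tol = options$tol,
                   maxit = options$maxit)
  if (!fit$converged)
    stop("slit-pocket solve did not converge (residual ",
         format(fit$residual, digits = 3), ")")

  psi_full <- rep(NA_real_, ns * ny)
  psi_full[active_mask] <- fit$psi
  pm <- matrix(psi_full, nrow = ns)
  # slit midplane (y = 0) far from the pocket; pocket mid-gap at s = 0
  iy_mid <- which.min(abs(y_c - 0))
  phi_slit <- .interp1(y_c, pm[ns, ], 0)
  phi_pocket <- .interp1(y_c, pm[1, ], -d / 2)
  new_potential_field(
    "slit-pocket-2d", list(s = sc_all, y = yc_all), psi_full,
    ifelse(active_mask, "electrolyte", "wall"), fit$residual, elec,
    meta = list(volume = vol_all, lambda = as.numeric(active_mask),
                energy_conns = energy_conns, device = device, sigma_w = sig,
                s_centers = s_c, y_centers = y_c, psi_matrix = pm,
                phi_mid_slit = phi_slit, phi_mid_pocket = phi_pocket,
                dphi_mid = phi_slit - phi_pocket,
                iterations = fit$iterations))
}

.interp1 <- function(x, y, xo) {
  ok <- is.finite(y)
  stats::approx(x[ok], y[ok], xout = xo, rule = 2)$y
}
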
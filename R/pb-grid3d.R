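#' Nonlinear PB solution around a 3D molecular charge distribution
#'
#' Solves the nonlinear Poisson-Boltzmann equation on a graded 3D Cartesian
#' finite-volume grid around an atomistic or bead structure.  The molecular
#' interior (the ion-accessible surface of [ias_voxelize()]) is an ion-free
#' dielectric of relative permittivity `eps_mol`; the dielectric matching
#' conditions are satisfied discretely through harmonic-mean face
#' permittivities.  Partial charges are spread onto the eight surrounding
#' cell centres of the grid (their tiny-seed self-energy is interior and
#' cancels from all reported quantities).
#'
#' @param structure An `atomic_structure`.
#' @param elec An [electrolyte()].
#' @param options [solver_options()]; `spacing_fine` is the cell size in the
#'   molecular region.
#' @param environment `"bulk"` (isolated molecule, radiation boundary) or
#'   `"slit"` (molecule at the midplane of a charged slit; requires
#'   `device`).
#' @param device A [slit_device()] when `environment = "slit"`.
#' @param axes Optional list `(fx, fy, fz)` of face coordinates overriding
#'   the internal axis construction (used to solve the slit and pocket
#'   states of a free-energy difference on identical grids).
#' @return A `potential_field` (geometry `"cartesian-3d"`).  For the slit
#'   environment the field is the total (walls + molecule) field and the
#'   walls-only reference free energy is attached.
#' @export
solve_structure_grid <- function(structure, elec,
                                 options = solver_options(spacing_fine = 0.15,
                                                          ratio = 1.22,
                                                          padding_debye = 3.2),
                                 environment = c("bulk", "slit"),
                                 device = NULL, axes = NULL) {
  environment <- match.arg(environment)
  a <- structure$atoms
  kap <- elec$kappa_nm1
  lB <- elec$bjerrum_nm
  pad <- options$padding_debye / kap
  hfine <- options$spacing_fine
  margin <- max(a$radius) + structure$w + 2 * hfine

  ctr <- c(mean(range(a$x)), mean(range(a$y)), mean(range(a$z)))
  lo <- c(min(a$x), min(a$y), min(a$z)) - margin
  hi <- c(max(a$x), max(a$y), max(a$z)) + margin
  hmax <- min(options$spacing_max, 0.32 / kap)

  ax <- function(k) axis_banded(lo[k] - pad, lo[k], hi[k], hi[k] + pad,
                                hfine, options$ratio, hmax)
  if (!is.null(axes)) {
    fx <- axes$fx; fy <- axes$fy; fz <- axes$fz
    zbc <- if (environment == "slit")
      .slit_1d_on_faces(fz, ctr[3], device, elec, options) else NULL
  } else if (environment == "bulk") {
    fx <- ax(1); fy <- ax(2); fz <- ax(3)
    zbc <- NULL
  } else {
    if (is.null(device)) stop("slit environment needs a device")
    h <- device$h
    if (hi[3] - ctr[3] >= h || ctr[3] - lo[3] >= h)
      stop("structure does not fit inside the slit")
    fx <- ax(1); fy <- ax(2)
    hw <- min(0.3, h / 40)
    fz <- merge_faces(c(
      grade_up(ctr[3] - h, lo[3], hw, 1.3, hmax),
      seq(lo[3], hi[3], length.out = max(2, ceiling((hi[3] - lo[3]) / hfine)) + 1),
      grade_down(hi[3], ctr[3] + h, hw, 1.3, hmax)), tol = min(hw, hfine) * 1e-4)
    # walls-only 1D reference on the same z-faces
    zbc <- .slit_1d_on_faces(fz, ctr[3], device, elec, options)
  }
  if (environment == "slit" && is.null(device)) stop("slit environment needs a device")

  xc <- axis_centers(fx); yc <- axis_centers(fy); zc <- axis_centers(fz)
  nx <- length(xc); ny <- length(yc); nz <- length(zc)
  n <- nx * ny * nz

  # sub-grid-scale objects (e.g. bare charge seeds) carry no resolvable
  # ion-excluded interior: treat them as point charges in solvent
  inside <- if (max(a$radius) + structure$w < min(diff(xc), diff(yc), diff(zc)))
    array(FALSE, c(nx, ny, nz))
  else ias_voxelize(structure, xc, yc, zc)
  lam <- as.numeric(!inside)
  epsc <- ifelse(inside, options$eps_mol / elec$epsilon_r, 1)

  sys <- .cart3d_assemble(fx, fy, fz, epsc, kap,
                          boundary = if (environment == "bulk") "robin" else "mixed",
                          ctr = ctr, zbc = zbc, lB = lB,
                          sigma_w = if (environment == "slit")
                            .device_sigma(device, elec) else 0)
  b0 <- sys$b0
  # spread the point charges trilinearly (aggregate repeated cell indices)
  sp <- .spread_charges(a, xc, yc, zc)
  agg <- rowsum(sp$q, sp$idx)
  b0[as.integer(rownames(agg))] <- b0[as.integer(rownames(agg))] +
    4 * pi * lB * agg[, 1]
  svol <- kap^2 * lam * sys$vol
  psi0 <- if (is.null(zbc)) NULL else zbc$psi[.cell_zindex(nx, ny, nz)]

  fit <- pb_newton(sys$L, b0, svol, psi0 = psi0, tol = options$tol,
                   maxit = options$maxit, linsolve = "cg")
  if (!fit$converged)
    stop("3D structure solve did not converge (residual ",
         format(fit$residual, digits = 3), ")")

  ec <- sys$energy_conns
  ec <- ec[lam[ec$i] > 0 & lam[ec$j] > 0, , drop = FALSE]

  coords <- list(x = rep(xc, ny * nz),
                 y = rep(rep(yc, each = nx), nz),
                 z = rep(zc, each = nx * ny))
  new_potential_field(
    "cartesian-3d", coords, fit$psi,
    as.vector(ifelse(inside, "molecular interior", "electrolyte")),
    fit$residual, elec,
    meta = list(volume = sys$vol, lambda = lam, energy_conns = ec,
                x_centers = xc, y_centers = yc, z_centers = zc,
                psi_array = array(fit$psi, c(nx, ny, nz)),
                charge_sites = cbind(a$x, a$y, a$z, a$charge),
                q_str = structure$q_str, centroid = ctr,
                structure = structure, environment = environment,
                device = device,
                walls_free_energy_per_area = if (is.null(zbc)) NULL else zbc$f_per_area,
                domain_area = if (is.null(zbc)) NULL else
                  (fx[length(fx)] - fx[1]) * (fy[length(fy)] - fy[1]),
                phi_m = if (is.null(zbc)) NULL else zbc$psi_mid,
                axes = list(fx = fx, fy = fy, fz = fz),
                iterations = fit$iterations))
}

# index helper: full-grid z-profile initial guess
.cell_zindex <- function(nx, ny, nz) rep(seq_len(nz), each = nx * ny)

# 1D walls-only slit solve on prescribed z faces (z in device coordinates
# centred at `zctr`), plus its free energy per unit wall area on that grid
.slit_1d_on_faces <- function(fz, zctr, device, elec, options) {
  kap <- elec$kappa_nm1
  lB <- elec$bjerrum_nm
  sig <- .device_sigma(device, elec)
  zc <- axis_centers(fz); dz <- axis_widths(fz); n <- length(zc)
  w <- 1 / (zc[-1] - zc[-n])
  L <- fv_operator(n, data.frame(i = seq_len(n - 1L), j = 2:n, w = w))
  b0 <- numeric(n)
  b0[c(1, n)] <- 4 * pi * lB * sig
  fit <- pb_newton(L, b0, kap^2 * dz, tol = options$tol, maxit = options$maxit)
  if (!fit$converged) stop("walls-only 1D solve did not converge")
  psi <- fit$psi
  grad2 <- sum(w * diff(psi)^2)
  ionic <- sum(dz * (cosh(psi) - psi * sinh(psi) - 1))
  f_per_area <- grad2 / (8 * pi * lB) - kap^2 / (4 * pi * lB) * ionic
  list(psi = psi, f_per_area = f_per_area,
       psi_mid = .interp1(zc, psi, zctr))
}

# trilinear spreading of point charges to the 8 surrounding cell centres
.spread_charges <- function(a, xc, yc, zc) {
  nx <- length(xc); ny <- length(yc)
  ix <- findInterval(a$x, xc, all.inside = TRUE)
  iy <- findInterval(a$y, yc, all.inside = TRUE)
  iz <- findInterval(a$z, zc, all.inside = TRUE)
  tx <- (a$x - xc[ix]) / (xc[ix + 1] - xc[ix])
  ty <- (a$y - yc[iy]) / (yc[iy + 1] - yc[iy])
  tz <- (a$z - zc[iz]) / (zc[iz + 1] - zc[iz])
  idx <- integer(0); q <- numeric(0)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
      (if (dz) tz else 1 - tz)
    idx <- c(idx, (ix + dx) + (iy + dy - 1L) * nx + (iz + dz - 1L) * nx * ny)
    q <- c(q, a$charge * wgt)
  }
  list(idx = idx, q = q)
}

# 3D Cartesian FV assembly with per-cell relative permittivity.
# boundary = "robin": radiation condition on all six faces;
# boundary = "mixed": wall flux on the two z faces, Dirichlet(zbc) on x/y.
.cart3d_assemble <- function(fx, fy, fz, epsc, kap, boundary, ctr, zbc,
                             lB, sigma_w) {
  xc <- axis_centers(fx); dx <- axis_widths(fx); nx <- length(xc)
  yc <- axis_centers(fy); dy <- axis_widths(fy); ny <- length(yc)
  zc <- axis_centers(fz); dz <- axis_widths(fz); nz <- length(zc)
  n <- nx * ny * nz
  vol <- as.vector(outer(outer(dx, dy), dz))
  eharm <- function(e1, e2) 2 * e1 * e2 / (e1 + e2)

  conn_list <- vector("list", 3); en_list <- vector("list", 3)
  # x faces
  i1 <- rep(rep(seq_len(nx - 1L), ny), nz)
  j1 <- rep(rep(seq_len(ny), each = nx - 1L), nz)
  k1 <- rep(seq_len(nz), each = (nx - 1L) * ny)
  ci <- i1 + (j1 - 1L) * nx + (k1 - 1L) * nx * ny
  cj <- ci + 1L
  A <- dy[j1] * dz[k1]; dd <- xc[i1 + 1L] - xc[i1]
  conn_list[[1]] <- data.frame(i = ci, j = cj,
                               w = eharm(epsc[ci], epsc[cj]) * A / dd)
  en_list[[1]] <- data.frame(i = ci, j = cj, w = A / dd)
  # y faces
  i2 <- rep(rep(seq_len(nx), ny - 1L), nz)
  j2 <- rep(rep(seq_len(ny - 1L), each = nx), nz)
  k2 <- rep(seq_len(nz), each = nx * (ny - 1L))
  ci <- i2 + (j2 - 1L) * nx + (k2 - 1L) * nx * ny
  cj <- ci + nx
  A <- dx[i2] * dz[k2]; dd <- yc[j2 + 1L] - yc[j2]
  conn_list[[2]] <- data.frame(i = ci, j = cj,
                               w = eharm(epsc[ci], epsc[cj]) * A / dd)
  en_list[[2]] <- data.frame(i = ci, j = cj, w = A / dd)
  # z faces
  i3 <- rep(rep(seq_len(nx), ny), nz - 1L)
  j3 <- rep(rep(seq_len(ny), each = nx), nz - 1L)
  k3 <- rep(seq_len(nz - 1L), each = nx * ny)
  ci <- i3 + (j3 - 1L) * nx + (k3 - 1L) * nx * ny
  cj <- ci + nx * ny
  A <- dx[i3] * dy[j3]; dd <- zc[k3 + 1L] - zc[k3]
  conn_list[[3]] <- data.frame(i = ci, j = cj,
                               w = eharm(epsc[ci], epsc[cj]) * A / dd)
  en_list[[3]] <- data.frame(i = ci, j = cj, w = A / dd)
  conns <- do.call(rbind, conn_list)

  b0 <- numeric(n)
  # boundary cell index sets and face areas
  bidx <- function(fix, dim) {
    if (dim == 1) as.vector(outer(outer(fix, (seq_len(ny) - 1L) * nx, `+`),
                                  (seq_len(nz) - 1L) * nx * ny, `+`))
    else if (dim == 2) as.vector(outer(outer(seq_len(nx), (fix - 1L) * nx, `+`),
                                       (seq_len(nz) - 1L) * nx * ny, `+`))
    else as.vector(outer(outer(seq_len(nx), (seq_len(ny) - 1L) * nx, `+`),
                         (fix - 1L) * nx * ny, `+`))
  }
  robin <- NULL
  if (boundary == "robin") {
    rb <- list()
    for (dim in 1:3) for (side in 1:2) {
      fix <- if (side == 1) 1L else c(nx, ny, nz)[dim]
      cells <- bidx(fix, dim)
      Af <- if (dim == 1) as.vector(outer(dy, dz))
            else if (dim == 2) as.vector(outer(dx, dz))
            else as.vector(outer(dx, dy))
      # distance of each boundary cell from the centroid
      px <- ((cells - 1L) %% nx) + 1L
      py <- (((cells - 1L) %/% nx) %% ny) + 1L
      pz <- ((cells - 1L) %/% (nx * ny)) + 1L
      R <- sqrt((xc[px] - ctr[1])^2 + (yc[py] - ctr[2])^2 + (zc[pz] - ctr[3])^2)
      rb[[length(rb) + 1L]] <- data.frame(i = cells,
                                          w = Af * (kap + 1 / pmax(R, 1)))
    }
    robin <- do.call(rbind, rb)
  } else {
    # z boundaries: constant-charge walls
    for (side in 1:2) {
      fix <- if (side == 1) 1L else nz
      cells <- bidx(fix, 3)
      Af <- as.vector(outer(dx, dy))
      b0[cells] <- b0[cells] + Af * 4 * pi * lB * sigma_w
    }
    # x/y boundaries: Dirichlet to the walls-only profile
    rb <- list()
    for (dim in 1:2) for (side in 1:2) {
      fix <- if (side == 1) 1L else c(nx, ny)[dim]
      cells <- bidx(fix, dim)
      pz <- ((cells - 1L) %/% (nx * ny)) + 1L
      Af <- if (dim == 1) as.vector(outer(dy, dz)) else as.vector(outer(dx, dz))
      dd <- if (dim == 1) {
        if (side == 1) xc[1] - fx[1] else fx[length(fx)] - xc[nx]
      } else {
        if (side == 1) yc[1] - fy[1] else fy[length(fy)] - yc[ny]
      }
      wb <- Af / dd
      rb[[length(rb) + 1L]] <- data.frame(i = cells, w = wb)
      b0[cells] <- b0[cells] + wb * zbc$psi[pz]
    }
    robin <- do.call(rbind, rb)
  }
  L <- fv_operator(n, conns, robin)
  # full-grid face list for the energy functional (weights A/d, eps-free)
  energy_conns <- do.call(rbind, en_list)
  list(L = L, b0 = b0, vol = vol, energy_conns = energy_conns)
}
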
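# Graded 1D grids ------------------------------------------------------------
#
# All solvers use tensor products of graded 1D axes: a fine uniform band where
# the solution varies on sub-nm scales (charged surfaces, molecular interior)
# and geometrically stretched cells towards the open boundary, where the field
# decays on the Debye scale.  Faces are returned; cell centers are midpoints.

# faces from `from` to `to`, fine spacing h0 at the `from` end, stretching by
# `ratio` up to `hmax`
grade_up <- function(from, to, h0, ratio = 1.2, hmax = Inf) {
  stopifnot(to > from, h0 > 0, ratio >= 1)
  x <- from
  h <- h0
  repeat {
    nx <- x[length(x)] + h
    if (nx >= to - 1e-9 * h) break
    x <- c(x, nx)
    h <- min(h * ratio, hmax)
  }
  # stretch slightly so the last face lands exactly on `to`
  if (length(x) < 2) return(c(from, to))
  x <- from + (x - from) * (to - from) / (x[length(x)] + h - from)
  c(x, to)
}

# mirror image: fine at the `to` end
grade_down <- function(from, to, h0, ratio = 1.2, hmax = Inf) {
  rev(from + to - grade_up(from, to, h0, ratio, hmax))
}

# uniform band [a,b] with spacing ~h0, stretched on both sides out to lo/hi
axis_banded <- function(lo, a, b, hi, h0, ratio = 1.2, hmax = Inf) {
  n <- max(1L, ceiling((b - a) / h0))
  mid <- seq(a, b, length.out = n + 1L)
  left <- if (lo < a) grade_down(lo, a, h0, ratio, hmax) else a
  right <- if (hi > b) grade_up(b, hi, h0, ratio, hmax) else b
  merge_faces(c(left, mid, right), tol = min(h0, 1) * 1e-4)
}

# drop faces closer than `tol` to their predecessor (float-level duplicates
# from unioning axis segments would otherwise create zero-width cells)
merge_faces <- function(faces, tol = 1e-7) {
  faces <- sort(faces)
  keep <- c(TRUE, diff(faces) > tol)
  faces[keep]
}

axis_centers <- function(faces) (faces[-1] + faces[-length(faces)]) / 2
axis_widths  <- function(faces) diff(faces)

# Sparse FV system assembly ---------------------------------------------------
#
# A discrete problem is   L psi + b0 - svol * sinh(psi) = 0
# with L the (symmetric, negative semi-definite) flux operator, b0 the fixed
# sources (point charges, wall-charge fluxes), and svol = kappa^2 * lambda * V
# per cell (lambda = 1 in electrolyte, 0 in ion-free regions).

# conns: data.frame(i, j, w) with w = eps_face * A_face / dist(i,j)
# robin: optional data.frame(i, w) added to the diagonal (outflow BC)
fv_operator <- function(n, conns, robin = NULL) {
  ii <- c(conns$i, conns$j, conns$i, conns$j)
  jj <- c(conns$j, conns$i, conns$i, conns$j)
  xx <- c(conns$w, conns$w, -conns$w, -conns$w)
  if (!is.null(robin) && nrow(robin)) {
    ii <- c(ii, robin$i); jj <- c(jj, robin$i); xx <- c(xx, -robin$w)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# Jacobi-preconditioned conjugate gradient for SPD `A` (passed as -J)
cg_spd <- function(A, b, x0 = NULL, tol = 1e-10, maxit = 2000L) {
  n <- length(b)
  x <- if (is.null(x0)) numeric(n) else x0
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  r <- b - as.numeric(A %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b * b))
  if (nb == 0) return(list(x = numeric(n), iter = 0L))
  for (k in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r * r)) <= tol * nb) return(list(x = x, iter = k))
    z <- r / d
    rz2 <- sum(r * z)
    p <- z + (rz2 / rz) * p
    rz <- rz2
  }
  warning("CG did not reach tolerance in ", maxit, " iterations")
  list(x = x, iter = maxit)
}

# Damped Newton iteration for the nonlinear PB system.
pb_newton <- function(L, b0, svol, psi0 = NULL, tol = 1e-8, maxit = 60L,
                      linsolve = c("direct", "cg"), dmax = 2) {
  linsolve <- match.arg(linsolve)
  n <- length(b0)
  psi <- if (is.null(psi0)) numeric(n) else psi0
  ref <- max(sqrt(sum(b0^2)), 1e-300)
  res_hist <- numeric(0)
  for (it in seq_len(maxit)) {
    sh <- .safe_sinh_cosh(psi, svol)
    r <- as.numeric(L %*% psi) + b0 - sh$s
    rn <- sqrt(sum(r^2)) / ref
    res_hist <- c(res_hist, rn)
    if (rn <= tol) {
      return(list(psi = psi, residual = rn, iterations = it - 1L,
                  converged = TRUE, history = res_hist))
    }
    Jd <- sh$c   # svol * cosh(psi) >= 0
    if (linsolve == "direct") {
      J <- L - Matrix::Diagonal(n, Jd)
      delta <- as.numeric(Matrix::solve(J, -r))
    } else {
      A <- Matrix::Diagonal(n, Jd) - L   # SPD
      # inexact Newton: loose linear solves while far from the root
      eta <- max(min(0.01, rn * 0.1), 1e-10)
      delta <- cg_spd(A, r, tol = eta, maxit = 4000L)$x
    }
    # damp on the electrolyte cells only: the ion-free interior is linear and
    # may legitimately take very large (self-energy) potential values
    dnl <- if (any(svol > 0)) max(abs(delta[svol > 0]), 1e-300) else 0
    step <- min(1, dmax / max(dnl, 1e-300))
    # backtracking line search on the residual norm
    for (ls in 1:8) {
      cand <- psi + step * delta
      shc <- .safe_sinh_cosh(cand, svol)
      rc <- as.numeric(L %*% cand) + b0 - shc$s
      if (sqrt(sum(rc^2)) / ref < rn || step == 1) break
      step <- step / 2
    }
    psi <- psi + step * delta
  }
  sh <- .safe_sinh_cosh(psi, svol)
  rn <- sqrt(sum((as.numeric(L %*% psi) + b0 - sh$s)^2)) / ref
  list(psi = psi, residual = rn, iterations = maxit,
       converged = rn <= tol, history = res_hist)
}

# svol * sinh / cosh, with sinh/cosh clamped to avoid overflow while the
# Newton iterate is far from the solution
.safe_sinh_cosh <- function(psi, svol) {
  p <- pmax(pmin(psi, 60), -60)
  list(s = svol * sinh(p), c = svol * cosh(p))
}

# potential_field object ------------------------------------------------------
new_potential_field <- function(geometry, coords, psi, region, residual,
                                elec, meta = list()) {
  structure(c(list(geometry = geometry, coords = coords, psi = psi,
                   region = region, residual = residual, electrolyte = elec),
              meta),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat("<potential_field>", x$geometry, "-", length(x$psi), "cells, residual",
      format(x$residual, digits = 3), "\n  psi range [",
      signif(min(x$psi), 4), ",", signif(max(x$psi), 4), "] kT/e\n")
  invisible(x)
}

#' Tabulate a solved potential field
#'
#' @param x A `potential_field` from one of the PB solvers.
#' @param ... Unused.
#' @return A tibble with one row per finite-volume cell: the cell-center
#'   coordinates (nm), the nondimensional potential `psi` (kT/e), the region
#'   label, and the cell volume.
#' @method as_tibble potential_field
#' @export
as_tibble.potential_field <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$coords),
                   tibble::tibble(psi = x$psi, region = x$region,
                                  volume = x$volume))
}
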
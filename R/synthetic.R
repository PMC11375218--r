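#' Generate synthetic escape-event streams
#'
#' Draws exponential residence times with mean set either directly
#' (`t_esc_ms`) or through the trap model from a true effective charge and
#' surface potential, discretizes them to the camera frame interval, and
#' optionally mixes in a short-lived contaminant component (transiently
#' trapped weakly charged species), the physical reason the shortest lag
#' bins are excluded from fitting.
#'
#' @param n Number of events.
#' @param t_esc_ms True mean escape time (ms); or give `q_eff` + `trap` +
#'   `phi_s`.
#' @param q_eff True effective charge (e, negative).
#' @param trap A [trap_model()] (needed with `q_eff`).
#' @param phi_s Device surface potential (kT/e, needed with `q_eff`).
#' @param frame_ms Frame interval for discretization (0 keeps continuous
#'   times).
#' @param contaminant_frac Fraction of contaminant events.
#' @param contaminant_mean_ms Mean duration of the contaminant component.
#' @param seed Integer seed; stored in the output.
#' @param species,device Labels.
#' @return An [escape_events()] tibble with generation metadata in
#'   attributes (`seed`, `true_t_esc`).
#' @export
generate_escape_events <- function(n, t_esc_ms = NULL, q_eff = NULL,
                                   trap = NULL, phi_s = NULL, frame_ms = 0,
                                   contaminant_frac = 0,
                                   contaminant_mean_ms = 2,
                                   seed = 1, species = "synthetic",
                                   device = "synthetic") {
  if (n < 1) stop("n must be at least 1")
  if (is.null(t_esc_ms)) {
    if (is.null(q_eff) || is.null(trap) || is.null(phi_s))
      stop("give t_esc_ms, or q_eff with trap and phi_s")
    t_esc_ms <- .model_tesc(q_eff, phi_s, trap)
  }
  set.seed(seed)
  n_cont <- rbinom(1, n, contaminant_frac)
  dt <- c(stats::rexp(n - n_cont, 1 / t_esc_ms),
          stats::rexp(n_cont, 1 / contaminant_mean_ms))
  dt <- sample(dt)
  if (frame_ms > 0) dt <- frame_ms * pmax(1, ceiling(dt / frame_ms))
  ev <- escape_events(dt, frame_ms = frame_ms, species = species,
                      device = device)
  attr(ev, "seed") <- seed
  attr(ev, "true_t_esc") <- t_esc_ms
  attr(ev, "contaminant_frac") <- contaminant_frac
  ev
}

#' Generate a discrete worm-like-chain conformational ensemble
#'
#' Stands in for molecular-dynamics conformers of a single-stranded nucleic
#' acid: fixed bond length `b_c` (the contour length per base), bending
#' stiffness set by the persistence length `l_p` (bond-angle distribution
#' \eqn{\propto \exp[(l_p/b_c)\cos\theta]}), one \eqn{-1e} charge site per
#' bead.  The freely jointed limit is `l_p = b_c/2`
#' (\eqn{\langle\cos\theta\rangle \to} small).
#'
#' @param n_conformers Number of chains.
#' @param n_b Number of bases; chains carry `n_b + 1` sites.
#' @param b_c Bond (inter-site contour) length, nm.
#' @param l_p Persistence length, nm.
#' @param seed Integer seed.
#' @return An `ensemble`: list with `conformers` (list of site-coordinate
#'   matrices, nm), the per-conformer `metrics` tibble
#'   ([conformer_metrics()]), and the generation spec.
#' @export
generate_chain_ensemble <- function(n_conformers, n_b, b_c = 0.5, l_p = 2,
                                    seed = 1) {
  if (n_b < 2) stop("n_b must be at least 2")
  if (l_p <= 0 || b_c <= 0) stop("l_p and b_c must be positive")
  if (l_p < b_c / 10) stop("l_p below b_c/10: stiffness numerically meaningless")
  k <- l_p / b_c
  set.seed(seed)
  n_sites <- n_b + 1L
  conformers <- vector("list", n_conformers)
  for (cc in seq_len(n_conformers)) {
    dirs <- matrix(0, n_sites - 1L, 3)
    v <- .rand_unit()
    dirs[1, ] <- v
    if (n_sites > 2) for (i in 2:(n_sites - 1L)) {
      # sample cos(theta) from exp(k cos) on [-1, 1] by inverse CDF
      u <- stats::runif(1)
      ct <- 1 + log(u + (1 - u) * exp(-2 * k)) / k
      st <- sqrt(max(0, 1 - ct^2))
      phi <- stats::runif(1, 0, 2 * pi)
      # orthonormal frame around the previous direction
      e1 <- .perp_unit(v)
      e2 <- c(v[2] * e1[3] - v[3] * e1[2],
              v[3] * e1[1] - v[1] * e1[3],
              v[1] * e1[2] - v[2] * e1[1])
      v <- ct * v + st * (cos(phi) * e1 + sin(phi) * e2)
      v <- v / sqrt(sum(v^2))
      dirs[i, ] <- v
    }
    coords <- rbind(c(0, 0, 0), apply(dirs * b_c, 2, cumsum))
    conformers[[cc]] <- coords
  }
  metrics <- dplyr::bind_rows(lapply(seq_along(conformers), function(i) {
    m <- conformer_metrics(conformers[[i]])
    m$id <- i
    m
  }))
  structure(list(conformers = conformers, metrics = metrics,
                 spec = list(n_conformers = n_conformers, n_b = n_b,
                             b_c = b_c, l_p = l_p, seed = seed)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble>", length(x$conformers), "conformers, n_b =", x$spec$n_b,
      ", b_c =", x$spec$b_c, "nm, l_p =", x$spec$l_p, "nm\n")
  invisible(x)
}

.rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

.perp_unit <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- a - sum(a * v) * v
  p / sqrt(sum(p^2))
}

#' Mean squared end-to-end distance of a discrete worm-like chain
#'
#' Closed form for `N` bonds of length `b` with bond-angle correlation
#' \eqn{c = \langle\cos\theta\rangle = \coth(k) - 1/k}, \eqn{k = l_p/b}:
#' \deqn{\langle R^2\rangle = N b^2\left[\frac{1+c}{1-c} -
#'   \frac{2c(1-c^N)}{N(1-c)^2}\right]}
#' Used as the sampling oracle for [generate_chain_ensemble()].
#'
#' @param n_bonds Number of bonds.
#' @param b Bond length (nm).
#' @param l_p Persistence length (nm).
#' @return \eqn{\langle R^2\rangle} in nm^2.
#' @export
wlc_mean_square_R <- function(n_bonds, b, l_p) {
  k <- l_p / b
  cc <- 1 / tanh(k) - 1 / k
  n_bonds * b^2 * ((1 + cc) / (1 - cc) -
                     2 * cc * (1 - cc^n_bonds) / (n_bonds * (1 - cc)^2))
}

#' Device fixtures used throughout the study conditions
#'
#' Bundled slit-device and electrolyte parameter sets:
#' * `fig1_device`: 2h = 70 nm slit, surface potential -1.91 kT/e,
#'   0.6 mM NaCl (short-fragment measurements).  The printed slit-regime
#'   parameter "kappa h = 5.5" is stored verbatim alongside the geometric
#'   h/kappa^-1 = 2.8; the two are not reconciled.
#' * `fig3_device`: 2h = 75 nm, -2.24 kT/e, 1.2 mM NaCl (30/60-base
#'   measurements).
#' * `fig1c_geometry`: the potential-map cross-section, h = 35 nm, pocket
#'   depth 210 nm, 1.2 mM, walls at an effective -2.2 kT/e.
#'
#' @param name Fixture name.
#' @return A list with `device` ([slit_device()]), `electrolyte`
#'   ([electrolyte()]), `label`, and `kappa_h_printed` (where quoted).
#' @export
generate_device_fixture <- function(name = c("fig1_device", "fig3_device",
                                             "fig1c_geometry")) {
  name <- match.arg(name)
  switch(name,
    fig1_device = list(
      device = slit_device(h = 35, d = 280, pocket_radius = 300,
                           phi_s = -1.91),
      electrolyte = electrolyte(0.6e-3),
      label = "fig1_device", kappa_h_printed = 5.5),
    fig3_device = list(
      device = slit_device(h = 37.5, d = 280, pocket_radius = 300,
                           phi_s = -2.24),
      electrolyte = electrolyte(1.2e-3),
      label = "fig3_device", kappa_h_printed = NA_real_),
    fig1c_geometry = list(
      device = slit_device(h = 35, d = 210, pocket_radius = 300,
                           phi_s = -2.2),
      electrolyte = electrolyte(1.2e-3),
      label = "fig1c_geometry", kappa_h_printed = NA_real_))
}
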
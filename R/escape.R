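#' Residence-time event table
#'
#' Validates a table of trap residence events.  Durations are in ms and must
#' be at least one frame interval.
#'
#' @param dt_ms Event durations (ms).
#' @param frame_ms Camera frame interval (ms).
#' @param species,device Labels.
#' @return A tibble of class `escape_events` with columns
#'   `dt_ms, frame_ms, species, device`.
#' @export
escape_events <- function(dt_ms, frame_ms = 0, species = "unknown",
                          device = "unknown") {
  if (any(!is.finite(dt_ms))) stop("non-finite event durations")
  if (any(dt_ms < frame_ms)) stop("durations below one frame interval")
  out <- tibble::tibble(dt_ms = dt_ms, frame_ms = frame_ms,
                        species = species, device = device)
  class(out) <- c("escape_events", class(out))
  out
}

#' Fit the mean escape time of an exponential residence-time distribution
#'
#' The residence times in an electrostatic fluidic trap are exponential,
#' \eqn{P(\Delta t) \propto (1/t_{esc}) \exp(-\Delta t/t_{esc})}.  The
#' shortest lag bins can contain transiently trapped weakly charged
#' contaminants (free dye, degraded material), so the first
#' `n_excluded_lags` discrete lag values are excluded and the mean is
#' estimated by maximum likelihood for the left-truncated distribution.  For
#' frame-discretized durations the geometric-likelihood estimator is used;
#' it reduces to `mean(dt - truncation)` as the frame interval vanishes.
#'
#' @param events An [escape_events()] table (or data frame with `dt_ms`).
#' @param n_excluded_lags Number of shortest observed lag values to exclude
#'   (default 2).
#' @return An `escape_fit`: one-row tibble with `t_esc_ms`, `se_ms`
#'   (\eqn{t_{esc}/\sqrt{N}}), `n_events`, `n_excluded_lags`, `truncation_ms`.
#' @export
fit_escape_time <- function(events, n_excluded_lags = 2) {
  dt <- events$dt_ms
  frame <- if ("frame_ms" %in% names(events)) max(events$frame_ms) else 0
  if (n_excluded_lags > 0) {
    lags <- sort(unique(round(dt, 9)))
    if (length(lags) <= n_excluded_lags)
      stop("all events fall in the excluded lag bins")
    tau <- lags[n_excluded_lags]
    keep <- dt > tau + 1e-9
  } else {
    tau <- 0
    keep <- rep(TRUE, length(dt))
  }
  dtk <- dt[keep]
  n <- length(dtk)
  if (n < 100) stop("need at least 100 events after lag exclusion")
  if (diff(range(dtk)) == 0) stop("all retained events at a single value")
  if (frame > 0) {
    # durations are multiples of the frame interval: geometric MLE
    k <- round(dtk / frame)
    k0 <- min(k)
    kbar <- mean(k)
    t_esc <- frame / log(1 + 1 / (kbar - k0))
  } else {
    t_esc <- mean(dtk) - min(dtk)
  }
  out <- tibble::tibble(t_esc_ms = t_esc, se_ms = t_esc / sqrt(n),
                        n_events = n, n_excluded_lags = n_excluded_lags,
                        truncation_ms = tau)
  class(out) <- c("escape_fit", class(out))
  out
}

#' Kramers escape-time ratio between two well depths
#'
#' @param W1,W2 Well depths in \eqn{k_B T}.
#' @return \eqn{\exp(W_1 - W_2)}: the ratio of mean escape times.
#' @export
kramers_ratio <- function(W1, W2) exp(W1 - W2)

#' Trap model: escape time versus effective charge
#'
#' The trap depth is \eqn{W = \Delta F_{el} + \Delta F_{trans}} with
#' \eqn{\Delta F_{el} = q_{eff}\,\phi_m} (both negative, so positive) and a
#' confinement-entropy term for a sphere of hydrodynamic radius `r_H`,
#' \eqn{\Delta F_{trans} = \ln[(2h+d-2r_H)/(2h-2r_H)]} (it cancels between
#' species of equal `r_H` measured in one device).  The mean escape time is
#' \eqn{t_{esc} = t_0 e^{W}} with the attempt-time prefactor `t0_ms` fixed
#' by Brownian-dynamics simulation or by the calibration measurement.
#'
#' @param device A [slit_device()].
#' @param elec An [electrolyte()].
#' @param r_H Hydrodynamic radius (nm).
#' @param t0_ms Attempt-time prefactor (ms); default is the flat-trap mean
#'   first-passage time \eqn{a^2/4D} of the pocket.
#' @param dF_trans Override for the entropic term (kT).
#' @return A `trap_model` list.
#' @export
trap_model <- function(device, elec, r_H = 3,
                       t0_ms = NULL, dF_trans = NULL) {
  D <- stokes_einstein_D(r_H, elec$temperature)
  if (is.null(t0_ms)) t0_ms <- device$pocket_radius^2 / (4 * D)
  if (is.null(dF_trans)) {
    h2 <- 2 * device$h
    dF_trans <- log((h2 + device$d - 2 * r_H) / (h2 - 2 * r_H))
  }
  structure(list(device = device, electrolyte = elec, r_H = r_H,
                 D_nm2_ms = D, t0_ms = t0_ms, dF_trans = dF_trans),
            class = "trap_model")
}

#' Stokes-Einstein diffusivity
#'
#' @param r_H Hydrodynamic radius (nm).
#' @param temperature K.
#' @param viscosity Pa s (default water at 25 C).
#' @return Diffusivity in nm^2/ms.
#' @export
stokes_einstein_D <- function(r_H, temperature = 298.15,
                              viscosity = 0.89e-3) {
  D_m2s <- .const$kB * temperature / (6 * pi * viscosity * r_H * 1e-9)
  D_m2s * 1e18 / 1e3
}

# trap depth (kT) for an effective charge at a given surface potential
.trap_depth <- function(q_eff, phi_s, trap) {
  dev <- trap$device
  kap <- trap$electrolyte$kappa_nm1
  phi_m <- 2 * phi_s * exp(-kap * dev$h)
  q_eff * phi_m + trap$dF_trans
}

# model escape time (ms)
.model_tesc <- function(q_eff, phi_s, trap) {
  trap$t0_ms * exp(.trap_depth(q_eff, phi_s, trap))
}

#' Calibrate the device surface potential from a reference molecule
#'
#' The wall surface potential \eqn{\phi_s} is a priori unknown; it is fixed
#' by measuring a calibrator of well-known effective charge (30 or 60 bp
#' double-stranded DNA: \eqn{|q_{eff}|} = 28.2 and 45.6 e) and root-solving
#' \eqn{t_{esc}^{model}(q_{eff}, \phi_s) = t_{esc}^{measured}}.
#'
#' @param calibrator_q_eff Known effective charge of the calibrator (e,
#'   negative).
#' @param calibrator_fit An `escape_fit` for the calibrator.
#' @param trap A [trap_model()] for the device and electrolyte.
#' @return A `calibration`: one-row tibble with `phi_s`, `phi_m`,
#'   `t0_ms`, `dF_trans`, and the calibrator inputs.
#' @export
calibrate_surface_potential <- function(calibrator_q_eff, calibrator_fit,
                                        trap) {
  t_meas <- calibrator_fit$t_esc_ms
  fun <- function(phi_s) .model_tesc(calibrator_q_eff, phi_s, trap) - t_meas
  lohi <- c(-6, -1e-4)
  if (fun(lohi[1]) * fun(lohi[2]) > 0)
    stop("no surface potential in (-6, 0) kT/e reproduces the calibrator")
  phi_s <- stats::uniroot(fun, lohi, tol = 1e-10)$root
  kap <- trap$electrolyte$kappa_nm1
  out <- tibble::tibble(
    phi_s = phi_s,
    phi_m = 2 * phi_s * exp(-kap * trap$device$h),
    t0_ms = trap$t0_ms, dF_trans = trap$dF_trans,
    calibrator_q_eff = calibrator_q_eff, calibrator_t_esc = t_meas)
  class(out) <- c("calibration", class(out))
  out
}

#' Infer a molecular effective charge from its fitted escape time
#'
#' Inverts the Kramers relation: \eqn{W = \ln(t_{esc}/t_0)}, then
#' \eqn{q_{eff} = (W - \Delta F_{trans})/\phi_m}, with the statistical error
#' of the fit propagated through the logarithm.
#'
#' @param fit An `escape_fit` for the species of interest.
#' @param calibration A `calibration` from the same device and conditions.
#' @return A one-row tibble with `q_eff`, `q_eff_se` (e), `W_kT`.
#' @export
infer_qeff <- function(fit, calibration) {
  if (fit$t_esc_ms <= calibration$t0_ms)
    stop("escape time at or below the attempt-time prefactor")
  W <- log(fit$t_esc_ms / calibration$t0_ms)
  q <- (W - calibration$dF_trans) / calibration$phi_m
  q_se <- abs((fit$se_ms / fit$t_esc_ms) / calibration$phi_m)
  tibble::tibble(q_eff = q, q_eff_se = q_se, W_kT = W,
                 t_esc_ms = fit$t_esc_ms)
}

#' Brownian-dynamics simulation of the escape process
#'
#' Simulates overdamped Langevin motion of the molecule (an effective sphere
#' of its hydrodynamic radius) in a radially symmetric in-plane trap of
#' depth `W`: flat well of the pocket radius, linear rim ramp, absorbing at
#' the rim's outer edge.  Validates the Kramers mapping used by
#' [infer_qeff()]: mean escape times scale as \eqn{e^W} and the
#' residence-time distribution is exponential.
#'
#' @param trap A [trap_model()].
#' @param W Well depth (kT).
#' @param n_events Number of escape events.
#' @param seed Integer seed.
#' @param rim_fraction Ramp width as a fraction of the pocket radius.  The
#'   ramp is followed by a field-free run-out of `runout_fraction * a`
#'   before the absorbing radius, so the mean escape time scales as a clean
#'   \eqn{e^W} (a ramp ending directly on the absorber would contribute an
#'   extra 1/W dependence from the barrier top).
#' @param runout_fraction Field-free run-out width fraction.
#' @param dt_ms Time step; default satisfies the stability guard
#'   \eqn{dt \le 0.01\, s^2/D} for ramp width s.
#' @return An [escape_events()] tibble (frame_ms = 0: continuous times).
#' @export
bd_escape_simulate <- function(trap, W, n_events, seed = 1,
                               rim_fraction = 0.05, runout_fraction = 0.2,
                               dt_ms = NULL) {
  a <- trap$device$pocket_radius
  s <- rim_fraction * a
  g <- runout_fraction * a
  D <- trap$D_nm2_ms
  dt_max <- 0.01 * s^2 / D
  if (is.null(dt_ms)) dt_ms <- dt_max
  if (dt_ms > dt_max)
    stop("timestep exceeds the stability guard 0.01 * rim^2 / D")
  set.seed(seed)
  dts <- bd_escape_cpp(as.integer(n_events), W, a, s, g, D, dt_ms,
                       max_steps = as.integer(1e9))
  ev <- escape_events(dts, frame_ms = 0, species = sprintf("BD W=%g", W),
                      device = "BD")
  attr(ev, "seed") <- seed
  attr(ev, "W") <- W
  ev
}
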
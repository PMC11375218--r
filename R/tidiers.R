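#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an escape-time fit
#'
#' @param x An `escape_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated quantity (`term`, `estimate`,
#'   `std.error`).
#' @method tidy escape_fit
#' @export
tidy.escape_fit <- function(x, ...) {
  tibble::tibble(term = "t_esc_ms", estimate = x$t_esc_ms,
                 std.error = x$se_ms)
}

#' @rdname tidy.escape_fit
#' @method glance escape_fit
#' @export
glance.escape_fit <- function(x, ...) {
  tibble::tibble(t_esc_ms = x$t_esc_ms, se_ms = x$se_ms,
                 n_events = x$n_events, truncation_ms = x$truncation_ms)
}

#' Tidy a rod charge curve
#'
#' @param x A `rod_charge_curve`.
#' @param ... Unused.
#' @return The per-spacing points tibble (with fitted values); `glance()`
#'   returns the fit coefficients.
#' @method tidy rod_charge_curve
#' @export
tidy.rod_charge_curve <- function(x, ...) x$points

#' @rdname tidy.rod_charge_curve
#' @method glance rod_charge_curve
#' @export
glance.rod_charge_curve <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, r = x$r, n_b = x$n_b,
                 fit_lo = x$fit_range[1], fit_hi = x$fit_range[2])
}

#' Tidy a calibration
#'
#' @param x A `calibration`.
#' @param ... Unused.
#' @return One row per calibrated quantity.
#' @method tidy calibration
#' @export
tidy.calibration <- function(x, ...) {
  tibble::tibble(term = c("phi_s", "phi_m"),
                 estimate = c(x$phi_s, x$phi_m))
}

#' Plot a rod charge curve
#'
#' @param object A `rod_charge_curve`.
#' @param ... Unused.
#' @return A ggplot: computed \eqn{|q_{calc}|} versus axial spacing with the
#'   fitted line over its window.
#' @method autoplot rod_charge_curve
#' @export
autoplot.rod_charge_curve <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = b, y = q_calc_abs)) +
    ggplot2::geom_line(ggplot2::aes(y = fitted), linetype = 2,
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = in_fit_window), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "axial charge spacing b (nm)",
                  y = expression("|" * q[calc] * "| (e)"),
                  title = sprintf("rod r = %g nm, n_b = %d", object$r,
                                  object$n_b))
}

#' Plot a solved potential field
#'
#' 1D fields are drawn as profiles; 2D (slit-pocket and axisymmetric) fields
#' as filled rasters of \eqn{sign(\psi)\log_{10}(|\psi|)}.
#'
#' @param object A `potential_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot potential_field
#' @export
autoplot.potential_field <- function(object, ...) {
  df <- as_tibble(object)
  if (object$geometry == "planar-1d") {
    return(ggplot2::ggplot(df, ggplot2::aes(x = x, y = psi)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "x (nm)", y = expression(psi ~ (k[B] * T / e))))
  }
  cn <- setdiff(names(df), c("psi", "region", "volume"))[1:2]
  df$logpsi <- sign(df$psi) * log10(pmax(abs(df$psi), 1e-6))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[cn[1]]], y = .data[[cn[2]]],
                                   fill = logpsi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] * "|" * psi * "|")) +
    ggplot2::labs(x = paste(cn[1], "(nm)"), y = paste(cn[2], "(nm)"))
}

#' Plot an ensemble's conformational landscape
#'
#' @param object An `ensemble`.
#' @param ... Unused.
#' @return A ggplot of the \eqn{(R_g, R)} point cloud with density contours.
#' @method autoplot ensemble
#' @export
autoplot.ensemble <- function(object, ...) {
  met <- object$metrics
  ggplot2::ggplot(met, ggplot2::aes(x = R_g, y = R)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_density_2d(colour = "steelblue") +
    ggplot2::labs(x = expression(R[g] ~ "(nm)"), y = "R (nm)")
}

#' Plot residence-time distributions
#'
#' @param object An `escape_events` table.
#' @param ... Unused.
#' @return A ggplot: log-scale histogram of event durations (exponential
#'   distributions appear as straight lines).
#' @method autoplot escape_events
#' @export
autoplot.escape_events <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = dt_ms)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = expression(Delta * t ~ "(ms)"), y = "count")
}
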
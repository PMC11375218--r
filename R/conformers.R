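#' Global geometry metrics of a conformer
#'
#' For a chain of backbone charge sites (phosphate positions): radius of
#' gyration `R_g` (unit weights), end-to-end distance `R`, contour length
#' `l_c` (sum of consecutive inter-site distances), and contour length per
#' base `b_c = l_c/(n_sites - 1)` (the mean inter-phosphate distance).
#'
#' @param coords An `n x 3` matrix of site coordinates (nm), a data frame
#'   with `x, y, z`, or an `atomic_structure`.
#' @return A one-row tibble `R_g, R, l_c, b_c, n_sites`.
#' @export
conformer_metrics <- function(coords) {
  m <- .site_matrix(coords)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 charge sites")
  ctr <- colMeans(m)
  rg <- sqrt(sum((m - matrix(ctr, n, 3, byrow = TRUE))^2) / n)
  R <- sqrt(sum((m[n, ] - m[1, ])^2))
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-n, , drop = FALSE])^2))
  lc <- sum(seg)
  tibble::tibble(R_g = rg, R = R, l_c = lc, b_c = lc / (n - 1), n_sites = n)
}

.site_matrix <- function(coords) {
  if (inherits(coords, "atomic_structure"))
    return(as.matrix(coords$atoms[, c("x", "y", "z")]))
  if (is.data.frame(coords)) return(as.matrix(coords[, c("x", "y", "z")]))
  as.matrix(coords)
}

#' Select representative conformers from an ensemble
#'
#' Mirrors the structure-selection protocol applied to simulated
#' conformational landscapes: a 2D Gaussian kernel density over
#' \eqn{(R_g, R)} identifies (i) the most likely conformation (nearest the
#' density maximum) and, within the highest-density region containing the
#' stated percentile of structures, (ii) the conformers of maximum and
#' minimum end-to-end distance.
#'
#' @param ensemble An `ensemble` from [generate_chain_ensemble()], or a
#'   data frame with columns `id`, `R_g`, `R`.
#' @param percentile Mass fraction (percent) of the highest-density region.
#' @return A tibble with rows `mode`, `max_R`, `min_R` (columns: `role`,
#'   `id`, `R_g`, `R`, `density`).
#' @export
select_representatives <- function(ensemble, percentile = 25) {
  met <- if (inherits(ensemble, "ensemble")) ensemble$metrics
         else tibble::as_tibble(ensemble)
  if (nrow(met) < 3) stop("need at least 3 conformers")
  x <- met$R_g; y <- met$R
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    warning("degenerate ensemble: all conformers identical")
    row <- met[1, c("id", "R_g", "R")]
    out <- dplyr::bind_rows(row, row, row)
    out$role <- c("mode", "max_R", "min_R")
    out$density <- NA_real_
    return(out[, c("role", "id", "R_g", "R", "density")])
  }
  dens <- .kde2d_at_points(x, y)
  met$density <- dens
  mode_row <- met[which.max(dens), ]
  thr <- stats::quantile(dens, 1 - percentile / 100)
  hdr <- met[dens >= thr, , drop = FALSE]
  out <- dplyr::bind_rows(
    mode_row[, c("id", "R_g", "R", "density")],
    hdr[which.max(hdr$R), c("id", "R_g", "R", "density")],
    hdr[which.min(hdr$R), c("id", "R_g", "R", "density")])
  out$role <- c("mode", "max_R", "min_R")
  out[, c("role", "id", "R_g", "R", "density")]
}

# product-Gaussian KDE evaluated at the data points (normal reference
# bandwidths); direct O(n^2) sum
.kde2d_at_points <- function(x, y) {
  n <- length(x)
  hx <- max(stats::bw.nrd(x), 1e-9)
  hy <- max(stats::bw.nrd(y), 1e-9)
  dx <- outer(x, x, `-`) / hx
  dy <- outer(y, y, `-`) / hy
  rowSums(exp(-0.5 * (dx^2 + dy^2))) / (n * 2 * pi * hx * hy)
}

#' Tabulate ensemble metrics
#'
#' @param ensemble An `ensemble`.
#' @return The per-conformer metrics tibble (`id`, `R_g`, `R`, `l_c`,
#'   `b_c`).
#' @export
ensemble_metrics <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  ensemble$metrics[, c("id", "R_g", "R", "l_c", "b_c", "n_sites")]
}
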
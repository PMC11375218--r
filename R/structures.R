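#' Atomic / bead structure container
#'
#' Holds per-site positions (nm), partial charges (e) and radii (nm) for an
#' atomistic or coarse-grained (bead) molecular model, together with the
#' ion-exclusion width `w` used to build the ion-accessible surface and the
#' declared structural charge.
#'
#' @param atoms A data frame with columns `name`, `x`, `y`, `z` (nm),
#'   `charge` (e), `radius` (nm); `resname`/`resid` optional.
#' @param w Ion-exclusion width added to every van der Waals radius (nm).
#' @param seed_radius Radius of the spherical charge seeds (nm).  The seeds
#'   are much smaller than atomic radii; the interior self-energy they carry
#'   cancels in free-energy differences and does not affect effective
#'   charges.
#' @param q_str Declared structural charge (e); defaults to the charge sum.
#' @param n_dyes Number of attached dye labels (bookkeeping only).
#' @param provenance Free-text note on where radii/charges came from.
#' @return An `atomic_structure` object.
#' @export
atomic_structure <- function(atoms, w = 0.2, seed_radius = 0.02,
                             q_str = NULL, n_dyes = 0, provenance = "user") {
  atoms <- tibble::as_tibble(atoms)
  need <- c("name", "x", "y", "z", "charge", "radius")
  if (!all(need %in% names(atoms)))
    stop("atoms needs columns ", paste(need, collapse = ", "))
  if (any(atoms$radius <= 0)) stop("all radii must be positive")
  if (is.null(q_str)) q_str <- sum(atoms$charge)
  structure(list(atoms = atoms, w = w, seed_radius = seed_radius,
                 q_str = q_str, n_dyes = n_dyes, provenance = provenance),
            class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat("<atomic_structure>", nrow(x$atoms), "sites, q_str =",
      signif(x$q_str, 5), "e, w =", x$w, "nm (", x$provenance, ")\n")
  invisible(x)
}

#' Read / write PQR files
#'
#' PQR is the whitespace-separated PDB dialect carrying per-atom charge and
#' radius in the occupancy/B-factor columns; coordinates and radii are in
#' Angstrom on file and converted to nm internally.
#'
#' @param path File path.
#' @param w,n_dyes Passed to [atomic_structure()].
#' @return An `atomic_structure`.
#' @export
read_pqr <- function(path, w = 0.2, n_dyes = 0) {
  lines <- readLines(path)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 10)) stop("malformed PQR record (fewer than 10 fields)")
  m <- t(vapply(fields, function(f) f[(length(f) - 4):length(f)],
                character(5)))
  num <- apply(m, 2, as.numeric)
  if (any(!is.finite(num))) stop("non-numeric coordinate/charge/radius field")
  atoms <- tibble::tibble(
    name = vapply(fields, `[`, character(1), 3),
    resname = vapply(fields, `[`, character(1), 4),
    x = num[, 1] / 10, y = num[, 2] / 10, z = num[, 3] / 10,
    charge = num[, 4], radius = num[, 5] / 10)
  atomic_structure(atoms, w = w, n_dyes = n_dyes,
                   provenance = paste("PQR:", basename(path)))
}

#' @rdname read_pqr
#' @param structure An `atomic_structure` to write.
#' @export
write_pqr <- function(structure, path) {
  a <- structure$atoms
  resname <- if ("resname" %in% names(a)) a$resname else "MOL"
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s %4d    %8.4f %8.4f %8.4f %9.5f %8.5f",
    seq_len(nrow(a)), a$name, resname, seq_len(nrow(a)),
    a$x * 10, a$y * 10, a$z * 10, a$charge, a$radius * 10)
  writeLines(lines, path)
  invisible(path)
}

# Bondi-style van der Waals radii (nm) for PDB inputs without radii
.vdw_table <- c(H = 0.12, C = 0.17, N = 0.155, O = 0.152, P = 0.18,
                S = 0.18)

#' Load a molecular structure from PQR or PDB
#'
#' @param path File path.
#' @param format `"pqr"` (positions, charges and radii on file) or `"pdb"`
#'   (positions only; radii from a bundled element table, charges zero with a
#'   recorded provenance note -- assign charges before solving).
#' @param ... Passed to [atomic_structure()].
#' @return An `atomic_structure` with provenance recorded.
#' @export
load_structure <- function(path, format = c("pqr", "pdb"), ...) {
  format <- match.arg(format)
  if (format == "pqr") return(read_pqr(path, ...))
  lines <- readLines(path)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no ATOM/HETATM records in ", path)
  name <- trimws(substr(lines, 13, 16))
  elem <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  rad <- unname(.vdw_table[elem])
  if (any(is.na(rad))) stop("no fallback radius for element(s): ",
                            paste(unique(elem[is.na(rad)]), collapse = ", "))
  atoms <- tibble::tibble(
    name = name,
    resname = trimws(substr(lines, 18, 20)),
    x = as.numeric(substr(lines, 31, 38)) / 10,
    y = as.numeric(substr(lines, 39, 46)) / 10,
    z = as.numeric(substr(lines, 47, 54)) / 10,
    charge = 0, radius = rad)
  atomic_structure(atoms, provenance = paste("PDB (radii from table):",
                                             basename(path)), ...)
}

#' Adjust terminal hydrogen charges to the integer-charge convention
#'
#' Nucleic-acid forcefields leave an `n_b`-base single strand with total
#' charge \eqn{-(n_b-1)e} because the 5' and 3' terminal residues carry
#' non-integer charge.  Shifting the terminal hydrogen atoms (H5T, H3T) by
#' \eqn{-1e} each restores the \eqn{-(n_b+1)e} structural charge of the
#' fully ionized chain.
#'
#' @param structure An `atomic_structure` containing atoms named H5T and H3T.
#' @return The adjusted structure (total charge changed by exactly -2 e).
#' @export
adjust_terminal_charges <- function(structure) {
  stopifnot(inherits(structure, "atomic_structure"))
  if (isTRUE(structure$terminal_adjusted))
    stop("terminal charges already adjusted; refusing to apply twice")
  a <- structure$atoms
  i5 <- which(a$name == "H5T"); i3 <- which(a$name == "H3T")
  if (length(i5) != 1 || length(i3) != 1)
    stop("expected exactly one H5T and one H3T atom (non-standard naming?)")
  a$charge[c(i5, i3)] <- a$charge[c(i5, i3)] - 1
  out <- structure
  out$atoms <- a
  out$q_str <- sum(a$charge)
  out$terminal_adjusted <- TRUE
  out
}

#' Ideal single-stranded half-helix bead model
#'
#' One strand of a canonical B-form double helix, reduced to its charged
#' phosphate sites: `n_b + 1` beads of -1 e on a helix with rise 0.338 nm and
#' twist 36 degrees per residue at radial distance 0.89 nm, giving the
#' \eqn{-(n_b+1)e} structural charge of a fully ionized `n_b`-base strand.
#'
#' @param n_b Number of bases (1-100).
#' @param sequence_label Species tag stored with the structure.
#' @param rise,twist_deg,radius Helical parameters (nm, degrees, nm).
#' @param bead_radius Bead van der Waals radius (nm).
#' @param w Ion-exclusion width (nm).
#' @return An `atomic_structure` centred at the origin.
#' @export
build_half_helix <- function(n_b, sequence_label = "ssDNA", rise = 0.338,
                             twist_deg = 36, radius = 0.89,
                             bead_radius = 0.2, w = 0.2) {
  if (n_b < 1 || n_b > 100) stop("n_b must be in 1..100")
  i <- 0:n_b
  th <- i * twist_deg * pi / 180
  atoms <- tibble::tibble(
    name = "P", resname = sequence_label,
    x = radius * cos(th), y = radius * sin(th), z = i * rise,
    charge = -1, radius = bead_radius)
  atoms$z <- atoms$z - mean(atoms$z)
  atomic_structure(atoms, w = w,
                   provenance = sprintf("half-helix n_b=%d (%s)", n_b,
                                        sequence_label))
}

#' Label grid nodes inside the ion-accessible surface
#'
#' A node is ion-inaccessible (molecular interior) when it lies within
#' `radius + w` of any atom; crevices narrower than the probe diameter are
#' closed by a one-cell morphological closing when `probe > 0` and the grid
#' is uniform.
#'
#' @param structure An `atomic_structure`.
#' @param x,y,z Grid node coordinate vectors (nm).
#' @param probe Probe radius for crevice smoothing (nm); applied when it is
#'   at least one cell wide.
#' @return A logical array `length(x) * length(y) * length(z)`, TRUE for
#'   molecular interior.
#' @export
ias_voxelize <- function(structure, x, y, z, probe = 0.1) {
  a <- structure$atoms
  w <- structure$w
  rmax <- max(a$radius) + w
  hmin <- min(diff(x), diff(y), diff(z))
  hcoarse <- max(min(diff(x)), min(diff(y)), min(diff(z)))
  if (hcoarse > rmax) stop("grid is coarser than the inflated atomic radii")
  inside <- array(FALSE, c(length(x), length(y), length(z)))
  for (k in seq_len(nrow(a))) {
    rr <- a$radius[k] + w
    ix <- which(x >= a$x[k] - rr & x <= a$x[k] + rr)
    iy <- which(y >= a$y[k] - rr & y <= a$y[k] + rr)
    iz <- which(z >= a$z[k] - rr & z <= a$z[k] + rr)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (x[ix] - a$x[k])^2
    dy2 <- (y[iy] - a$y[k])^2
    dz2 <- (z[iz] - a$z[k])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    inside[ix, iy, iz] <- inside[ix, iy, iz, drop = FALSE] | (d2 <= rr^2)
  }
  if (probe > 0 && probe >= hmin) {
    inside <- .close_voxels(inside)
  }
  inside
}

# one-cell 6-neighbour dilation followed by erosion (morphological closing)
.close_voxels <- function(m) {
  shift <- function(a, dim, by) {
    idx <- lapply(dim(a), seq_len)
    n <- dim(a)[dim]
    idx[[dim]] <- pmin(pmax(seq_len(n) + by, 1L), n)
    do.call(`[`, c(list(a), idx))
  }
  nb <- function(a, f) {
    out <- a
    for (d in 1:3) for (s in c(-1L, 1L)) out <- f(out, shift(a, d, s))
    out
  }
  dil <- nb(m, `|`)
  nb(dil, `&`)
}
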
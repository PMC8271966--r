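#' A single launch fiber
#'
#' Describes one multimode fiber face: position of the face center, emission
#' axis, core diameter and numerical aperture. Photons are launched with a
#' radially Gaussian profile on the face (sigma = core radius / 2, truncated
#' at the core edge) and a Gaussian polar angle about the axis truncated at
#' the in-medium acceptance angle \eqn{\theta_{max} = \arcsin(NA / n)}.
#'
#' @param position 3-vector, mm (fiber face center)
#' @param axis emission direction (3-vector, normalized internally)
#' @param core_diameter fiber core diameter, mm (default 0.1 = 100 um)
#' @param numerical_aperture fiber NA (default 0.22); 0 gives an ideal pencil
#' @param profile beam profile; only `"gaussian"` is supported
#' @return an object of class `fiber_source`
#' @export
fiber_source <- function(position = c(0, 0, 0), axis = c(0, 0, 1),
                         core_diameter = 0.1, numerical_aperture = 0.22,
                         profile = "gaussian") {
  profile <- match.arg(profile, "gaussian")
  stopifnot(length(position) == 3L, length(axis) == 3L)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("fiber axis must be a nonzero vector")
  if (core_diameter <= 0) stop("core_diameter must be > 0")
  if (numerical_aperture < 0 || numerical_aperture >= 1)
    stop("numerical_aperture must lie in [0, 1)")
  structure(
    list(position = as.numeric(position), axis = as.numeric(axis) / nrm,
         core_diameter = core_diameter,
         numerical_aperture = numerical_aperture, profile = profile),
    class = "fiber_source")
}

new_probe_layout <- function(fibers, type, ring_inner_diameter = 2.3,
                             ring_outer_diameter = 3.4, ring_radius = NA_real_) {
  structure(
    list(fibers = fibers, n_fibers = length(fibers), type = type,
         ring_inner_diameter = ring_inner_diameter,
         ring_outer_diameter = ring_outer_diameter,
         ring_radius = ring_radius),
    class = "probe_layout")
}

#' Annular fiber probe layout
#'
#' Places `n_fibers` identical fibers equally spaced in azimuth on a single
#' circle between the inner and outer ferrule of the probe, all emitting
#' parallel to the probe axis. The first fiber sits at azimuth 0 (the +x
#' direction); by rotational symmetry the absolute azimuth is physically
#' irrelevant and is fixed for reproducibility. The default ring radius is the
#' mid-annulus radius (2.3 + 3.4)/4 = 1.425 mm.
#'
#' @param n_fibers number of fibers (>= 1); the physical probe carries 72
#' @param ring_radius radius of the fiber circle, mm
#' @param axis probe axis (emission direction), default +z
#' @param origin center of the fiber ring, mm
#' @param core_diameter,numerical_aperture per-fiber parameters, see
#'   [fiber_source()]
#' @param ring_inner_diameter,ring_outer_diameter ferrule diameters, mm; the
#'   ring radius must lie within the annulus they delimit
#' @return a `probe_layout`
#' @examples
#' annular_layout(72)
#' @export
annular_layout <- function(n_fibers = 72, ring_radius = 1.425,
                           axis = c(0, 0, 1), origin = c(0, 0, 0),
                           core_diameter = 0.1, numerical_aperture = 0.22,
                           ring_inner_diameter = 2.3,
                           ring_outer_diameter = 3.4) {
  if (!is.numeric(n_fibers) || n_fibers < 1)
    stop("n_fibers must be a positive integer")
  n_fibers <- as.integer(n_fibers)
  if (ring_radius < ring_inner_diameter / 2 ||
      ring_radius > ring_outer_diameter / 2)
    stop("ring_radius must lie between the inner and outer ferrule radii")
  axis <- as.numeric(axis) / sqrt(sum(axis^2))
  basis <- .ortho_basis(axis)
  ang <- 2 * pi * (seq_len(n_fibers) - 1L) / n_fibers
  fibers <- lapply(seq_len(n_fibers), function(k) {
    pos <- origin + ring_radius * (cos(ang[k]) * basis$u + sin(ang[k]) * basis$v)
    fiber_source(pos, axis, core_diameter, numerical_aperture)
  })
  new_probe_layout(fibers, "annular", ring_inner_diameter,
                   ring_outer_diameter, ring_radius)
}

#' Surface (extracorporeal) illumination layout
#'
#' An approximate model of surface illumination with a handful of fibers held
#' beside an ultrasound transducer: `n_fibers` collinear fibers along x,
#' equally spaced and centered on the origin, offset by `standoff` in y, all
#' emitting along +z (into the tissue).
#'
#' @param n_fibers number of fibers (>= 1; default 6)
#' @param spacing center-to-center spacing, mm
#' @param standoff lateral offset of the fiber line from the imaging plane, mm
#' @param origin center of the fiber line, mm
#' @param core_diameter,numerical_aperture per-fiber parameters
#' @return a `probe_layout`
#' @export
surface_layout <- function(n_fibers = 6, spacing = 2, standoff = 0,
                           origin = c(0, 0, 0), core_diameter = 0.6,
                           numerical_aperture = 0.22) {
  if (!is.numeric(n_fibers) || n_fibers < 1)
    stop("n_fibers must be a positive integer")
  n_fibers <- as.integer(n_fibers)
  xs <- (seq_len(n_fibers) - (n_fibers + 1) / 2) * spacing
  fibers <- lapply(xs, function(x)
    fiber_source(origin + c(x, standoff, 0), c(0, 0, 1),
                 core_diameter, numerical_aperture))
  new_probe_layout(fibers, "surface",
                   ring_inner_diameter = NA_real_,
                   ring_outer_diameter = NA_real_)
}

.ortho_basis <- function(axis) {
  # u is the in-plane +x-like direction (azimuth 0), v completes the frame
  e <- if (abs(axis[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  u <- e - sum(e * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout: %s> %d fibers", x$type, x$n_fibers))
  if (x$type == "annular")
    cat(sprintf(", ring radius %.3f mm (annulus %.2f-%.2f mm dia.)",
                x$ring_radius, x$ring_inner_diameter, x$ring_outer_diameter))
  cat("\n")
  invisible(x)
}

#' Fiber coordinates of a layout as a table
#'
#' @param layout a `probe_layout`
#' @return data frame with one row per fiber: position, axis, core diameter,
#'   NA and azimuth (annular layouts)
#' @export
layout_table <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  pos <- t(vapply(layout$fibers, `[[`, numeric(3), "position"))
  ax <- t(vapply(layout$fibers, `[[`, numeric(3), "axis"))
  data.frame(
    fiber = seq_len(layout$n_fibers),
    x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
    axis_x = ax[, 1], axis_y = ax[, 2], axis_z = ax[, 3],
    core_diameter_mm = vapply(layout$fibers, `[[`, numeric(1), "core_diameter"),
    numerical_aperture = vapply(layout$fibers, `[[`, numeric(1),
                                "numerical_aperture"))
}

#' Write fiber coordinates to CSV
#'
#' @param layout a `probe_layout`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_layout_csv <- function(layout, path) {
  write.csv(layout_table(layout), path, row.names = FALSE)
  invisible(path)
}

#' Sample photon launch states from a fiber
#'
#' Draws launch positions and directions using the same sampler the transport
#' kernel uses: positions radially Gaussian on the fiber face (sigma = core
#' radius / 2, truncated at the core edge), polar angle Gaussian about the
#' axis (sigma = theta_max / 2, truncated at theta_max = asin(NA / n_medium)),
#' azimuth uniform. All launch weights are 1.
#'
#' @param fiber a [fiber_source()]
#' @param n number of draws
#' @param seed RNG seed (kernel stream; independent of R's RNG)
#' @param n_medium refractive index of the launch medium (narrows the cone)
#' @return list with `position` (n x 3, mm), `direction` (n x 3, unit rows)
#'   and `weight` (all 1)
#' @export
sample_launch <- function(fiber, n = 1L, seed = 1L, n_medium = 1.33) {
  stopifnot(inherits(fiber, "fiber_source"), n >= 1)
  out <- cpp_sample_launch(fiber$position, fiber$axis, fiber$core_diameter,
                           fiber$numerical_aperture, n_medium,
                           as.integer(n), as.numeric(seed))
  out$weight <- rep(1, n)
  out
}
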
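#' Embedded absorber specification
#'
#' Describes a compact optical absorber used as a perturbative probe of the
#' local fluence: the photoacoustic amplitude it generates is proportional to
#' its absorption coefficient times the mean fluence over the voxels it
#' occupies. Geometries: `"line"` (finite cylinder along `orientation`,
#' default the 0.19 mm line target), `"tube"` (blood-filled lumen, modelled
#' as a filled cylinder of the inner diameter), `"slab"` (a z-normal slab of
#' given thickness spanning the lateral extent) and `"inclusion"` (a sphere).
#'
#' @param geometry one of `"line"`, `"slab"`, `"tube"`, `"inclusion"`
#' @param diameter line/tube/inclusion diameter or slab thickness, mm
#' @param position 3-vector, mm (center; grid coordinates)
#' @param orientation axis of a line/tube (3-vector; default +x, i.e.
#'   perpendicular to the probe axis)
#' @param length length of a line/tube, mm (default 1, roughly the
#'   elevational slice thickness of the detecting transducer)
#' @param mu_a_absorber absorption coefficient of the absorber, cm^-1
#' @param label free text
#' @return an object of class `absorber_spec`
#' @export
absorber_spec <- function(geometry = c("line", "slab", "tube", "inclusion"),
                          diameter = 0.19, position = c(0, 0, 5),
                          orientation = c(1, 0, 0), length = 1,
                          mu_a_absorber = 100, label = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(length(position) == 3L, length(orientation) == 3L)
  if (diameter <= 0) stop("diameter/thickness must be > 0")
  if (length <= 0) stop("length must be > 0")
  if (mu_a_absorber < 0) stop("mu_a_absorber must be >= 0")
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("orientation must be a nonzero vector")
  structure(
    list(geometry = geometry, diameter = diameter,
         position = as.numeric(position),
         orientation = as.numeric(orientation) / nrm,
         length = length, mu_a_absorber = mu_a_absorber, label = label),
    class = "absorber_spec")
}

#' Voxels occupied by an absorber
#'
#' @param grid a [voxel_grid()]
#' @param absorber an [absorber_spec()]
#' @return logical array of `dim(grid$region_map)`; `TRUE` for occupied voxels
#' @export
absorber_voxels <- function(grid, absorber) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(absorber, "absorber_spec"))
  cc <- voxel_centers(grid)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  p <- absorber$position
  r <- absorber$diameter / 2
  if (absorber$geometry == "slab") {
    inz <- abs(cc$z - p[3]) <= r
    mask <- array(FALSE, dim = grid$dim)
    mask[, , inz] <- TRUE
    return(mask)
  }
  X <- array(rep(cc$x, times = ny * nz), dim = grid$dim)
  Y <- array(rep(rep(cc$y, each = nx), times = nz), dim = grid$dim)
  Z <- array(rep(cc$z, each = nx * ny), dim = grid$dim)
  dx <- X - p[1]; dy <- Y - p[2]; dz <- Z - p[3]
  if (absorber$geometry == "inclusion") {
    return(dx * dx + dy * dy + dz * dz <= r * r)
  }
  # line / tube: finite cylinder about `orientation`
  o <- absorber$orientation
  t <- dx * o[1] + dy * o[2] + dz * o[3]
  rx <- dx - t * o[1]; ry <- dy - t * o[2]; rz <- dz - t * o[3]
  (abs(t) <= absorber$length / 2) & (rx * rx + ry * ry + rz * rz <= r * r)
}

#' Photoacoustic amplitude of an embedded absorber
#'
#' First-order (perturbative) PA forward model: the absorber does not
#' re-run transport; its relative PA amplitude is
#' \eqn{A = \Gamma \, \mu_a^{abs} \, \langle NFR \rangle} over the voxels it
#' occupies, with \eqn{\Gamma} a Grueneisen-like proportionality constant in
#' relative units.
#'
#' @param fluence a `fluence_volume`
#' @param absorber an [absorber_spec()]
#' @param gamma proportionality constant (default 1)
#' @return relative PA amplitude (scalar)
#' @export
pa_amplitude_at <- function(fluence, absorber, gamma = 1) {
  stopifnot(inherits(fluence, "fluence_volume"))
  mask <- absorber_voxels(fluence$grid, absorber)
  if (!any(mask))
    stop("absorber occupies no voxel of the grid (outside the volume?)")
  gamma * absorber$mu_a_absorber * mean(fluence$nfr[mask])
}

#' Photoacoustic field-of-view map
#'
#' Simulates the absorber-free medium once, then evaluates the perturbative
#' PA amplitude of a template absorber translated over a (lateral x depth)
#' position grid in the y = const plane of the absorber template. The map is
#' normalized to its maximum and expressed in dB as
#' \eqn{20 \log_{10}(A / A_{max})} (pressure-like convention), so the
#' maximum is exactly 0 dB.
#'
#' @param medium a [voxel_grid()] (e.g. from [liquid_phantom()])
#' @param layout a `probe_layout`
#' @param absorber_template an [absorber_spec()]; its x and z are overridden
#'   per evaluation position
#' @param lateral_positions x offsets from the probe axis, mm
#' @param depths z positions, mm
#' @param photons_per_fiber,seed passed to [simulate_fluence()]
#' @param gamma proportionality constant
#' @param fluence optional precomputed `fluence_volume` for `medium`/`layout`
#'   (skips the transport run)
#' @return object of class `pa_field_map`: list with `lateral_positions`,
#'   `depths`, `amplitude_db` (depths x lateral matrix), `amplitude` (linear,
#'   unnormalized), `gamma` and the `fluence` used
#' @export
field_map <- function(medium, layout, absorber_template,
                      lateral_positions, depths,
                      photons_per_fiber = 1e5, seed = 1L, gamma = 1,
                      fluence = NULL) {
  if (is.null(fluence))
    fluence <- simulate_fluence(medium, layout, photons_per_fiber, seed)
  amp <- matrix(NA_real_, nrow = length(depths),
                ncol = length(lateral_positions))
  for (j in seq_along(lateral_positions)) {
    for (i in seq_along(depths)) {
      ab <- absorber_template
      ab$position[1] <- lateral_positions[j]
      ab$position[3] <- depths[i]
      amp[i, j] <- pa_amplitude_at(fluence, ab, gamma = gamma)
    }
  }
  amax <- max(amp)
  if (amax <= 0) stop("field map has no positive amplitude")
  db <- 20 * log10(amp / amax)
  structure(
    list(lateral_positions = lateral_positions, depths = depths,
         amplitude_db = db, amplitude = amp, gamma = gamma,
         fluence = fluence),
    class = "pa_field_map")
}

#' @export
print.pa_field_map <- function(x, ...) {
  cat(sprintf("<pa_field_map> %d depths x %d lateral positions, max 0 dB, floor %.1f dB\n",
              length(x$depths), length(x$lateral_positions),
              min(x$amplitude_db[is.finite(x$amplitude_db)])))
  invisible(x)
}

# last depth at which `prof` (dB) is >= threshold, linearly interpolated;
# attribute "crossed" = FALSE when the profile never drops below threshold
.depth_at_threshold <- function(depths, prof, threshold_db) {
  above <- prof >= threshold_db
  if (!any(above)) {
    out <- depths[1]
    attr(out, "crossed") <- FALSE
    return(out)
  }
  i <- max(which(above))
  if (i == length(prof)) {
    out <- depths[length(depths)]
    attr(out, "crossed") <- FALSE
    return(out)
  }
  # interpolate between the last above-threshold sample and the next one
  p1 <- prof[i]; p2 <- prof[i + 1]
  out <- if (is.finite(p2)) {
    depths[i] + (threshold_db - p1) / (p2 - p1) * (depths[i + 1] - depths[i])
  } else depths[i]
  attr(out, "crossed") <- TRUE
  out
}

#' On-axis penetration depth of the PA field
#'
#' Greatest depth at which the on-axis (lateral position closest to 0)
#' amplitude stays at or above `threshold_db`, linearly interpolated between
#' sampled depths. If the threshold is never crossed the maximum sampled
#' depth is returned with attribute `crossed = FALSE`.
#'
#' @param map a `pa_field_map`
#' @param threshold_db threshold in dB (< 0), e.g. -20
#' @return depth in mm with attribute `crossed`
#' @export
penetration_depth <- function(map, threshold_db = -20) {
  stopifnot(inherits(map, "pa_field_map"))
  if (threshold_db >= 0) stop("threshold_db must be < 0")
  j <- which.min(abs(map$lateral_positions))
  .depth_at_threshold(map$depths, map$amplitude_db[, j], threshold_db)
}

#' Lateral width of the PA field at a depth
#'
#' Lateral extent over which the amplitude at the given (sampled) depth is at
#' or above `threshold_db`, with the two edges linearly interpolated.
#'
#' @param map a `pa_field_map`
#' @param threshold_db threshold in dB (< 0), e.g. -35
#' @param depth one of the sampled depths, mm
#' @return width in mm with attribute `crossed` (FALSE when an edge lies
#'   outside the sampled lateral range)
#' @export
field_width <- function(map, threshold_db = -35, depth) {
  stopifnot(inherits(map, "pa_field_map"))
  if (threshold_db >= 0) stop("threshold_db must be < 0")
  i <- which(abs(map$depths - depth) < 1e-9)
  if (length(i) != 1L) stop("depth is not one of the sampled depths")
  lat <- map$lateral_positions
  prof <- map$amplitude_db[i, ]
  above <- which(prof >= threshold_db)
  if (length(above) == 0L) {
    out <- 0
    attr(out, "crossed") <- FALSE
    return(out)
  }
  l <- min(above); r <- max(above)
  crossed <- TRUE
  left <- if (l > 1L && is.finite(prof[l - 1])) {
    lat[l] + (threshold_db - prof[l]) / (prof[l - 1] - prof[l]) *
      (lat[l - 1] - lat[l])
  } else { if (l == 1L) crossed <- FALSE; lat[l] }
  right <- if (r < length(lat) && is.finite(prof[r + 1])) {
    lat[r] + (threshold_db - prof[r]) / (prof[r + 1] - prof[r]) *
      (lat[r + 1] - lat[r])
  } else { if (r == length(lat)) crossed <- FALSE; lat[r] }
  out <- right - left
  attr(out, "crossed") <- crossed
  out
}

#' Write a PA field map to CSV
#'
#' Long format: one row per (lateral, depth) with the amplitude in dB.
#'
#' @param map a `pa_field_map`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_field_csv <- function(map, path) {
  df <- expand.grid(depth_mm = map$depths,
                    lateral_mm = map$lateral_positions)
  df$amplitude_db <- as.vector(map$amplitude_db)
  write.csv(df[, c("lateral_mm", "depth_mm", "amplitude_db")], path,
            row.names = FALSE)
  invisible(path)
}

#' Plot a PA field map
#'
#' @param x a `pa_field_map`
#' @param floor_db dynamic-range floor for display, dB
#' @param ... passed to [graphics::image()]
#' @return `x`, invisibly
#' @export
plot_field_map <- function(x, floor_db = -40, ...) {
  z <- pmax(t(x$amplitude_db), floor_db)
  graphics::image(x$lateral_positions, x$depths, z,
                  xlab = "lateral (mm)", ylab = "depth (mm)",
                  ylim = rev(range(x$depths)), ...)
  invisible(x)
}
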
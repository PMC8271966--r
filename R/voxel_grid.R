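#' Voxelized tissue volume
#'
#' A rectangular voxel grid with a per-voxel region label and per-region
#' optical properties. Coordinates are in mm: x and y are centered on the
#' probe axis (so x, y span \[-extent/2, extent/2\]) and z runs from 0 at the
#' fiber-face plane into the tissue. Voxels are isotropic.
#'
#' @param extent c(x, y, z) extent in mm; default the 4 x 4 x 5 mm
#'   simulation volume used for probe characterization
#' @param voxel_size isotropic voxel edge, mm; extent/voxel_size must be
#'   integer (within rounding tolerance)
#' @param regions named list of [optical_properties()], one per region label
#' @param region_map integer array of dim `extent/voxel_size` with values
#'   indexing `regions`; default: all voxels belong to the first region
#' @return an object of class `voxel_grid`
#' @examples
#' g <- voxel_grid(regions = list(liver = liver_optical_properties("native", 650)))
#' @export
voxel_grid <- function(extent = c(4, 4, 5), voxel_size = 0.05,
                       regions, region_map = NULL) {
  stopifnot(length(extent) == 3L, all(extent > 0), voxel_size > 0)
  dims <- extent / voxel_size
  if (any(abs(dims - round(dims)) > 1e-6))
    stop("extent must be an integer multiple of voxel_size on every axis")
  dims <- as.integer(round(dims))
  if (!is.list(regions) || length(regions) == 0L)
    stop("regions must be a non-empty named list of optical_properties")
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("every region must be named")
  for (nm in names(regions))
    if (!inherits(regions[[nm]], "optical_properties"))
      stop(sprintf("region '%s' is not an optical_properties object", nm))
  if (is.null(region_map)) {
    region_map <- array(1L, dim = dims)
  } else {
    region_map <- array(as.integer(region_map), dim = dims)
    rng <- range(region_map)
    if (rng[1] < 1L || rng[2] > length(regions))
      stop("region_map values must index the regions list")
  }
  structure(
    list(extent = as.numeric(extent), voxel_size = voxel_size, dim = dims,
         regions = regions, region_map = region_map),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %g x %g x %g mm @ %g mm (%d x %d x %d voxels), %d region(s): %s\n",
              x$extent[1], x$extent[2], x$extent[3], x$voxel_size,
              x$dim[1], x$dim[2], x$dim[3], length(x$regions),
              paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

#' Voxel-center coordinates of a grid
#'
#' @param grid a `voxel_grid`
#' @return list of vectors `x`, `y`, `z` (mm); x and y centered on the axis,
#'   z from the launch plane
#' @export
voxel_centers <- function(grid) {
  h <- grid$voxel_size
  list(x = (seq_len(grid$dim[1]) - 0.5) * h - grid$extent[1] / 2,
       y = (seq_len(grid$dim[2]) - 0.5) * h - grid$extent[2] / 2,
       z = (seq_len(grid$dim[3]) - 0.5) * h)
}
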
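#' Depth-resolved fluence homogeneity statistic NFR_rel
#'
#' For every transverse slice of a fluence volume, computes
#' \eqn{NFR_{rel} = 100 \cdot NFR_{ROI} / NFR_{max}} where \eqn{NFR_{ROI}}
#' is the mean normalized fluence rate over an axis-centered square region of
#' interest and \eqn{NFR_{max}} the maximum over the whole slice. The ROI is
#' centered on the probe axis (the lateral center of the grid); when
#' `roi_side` is not an integer number of voxels it snaps to the nearest
#' voxel-aligned square and the effective side is recorded as an attribute.
#' Slices whose maximum is zero are dropped with a warning.
#'
#' @param fluence a `fluence_volume` from [simulate_fluence()]
#' @param roi_side side of the square ROI, mm (default 1.96)
#' @param config_label free-text label stored with the profile
#' @return a data frame of class `depth_profile` with columns `depth_mm`
#'   (voxel-center depth) and `nfr_rel_pct`, plus attributes
#'   `roi_side_effective` (mm) and `config_label`
#' @export
nfr_rel_profile <- function(fluence, roi_side = 1.96, config_label = NULL) {
  stopifnot(inherits(fluence, "fluence_volume"))
  grid <- fluence$grid
  h <- grid$voxel_size
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  if (roi_side > min(grid$extent[1:2]))
    stop("roi_side exceeds the lateral extent of the grid")
  if (all(fluence$nfr == 0)) stop("fluence volume is identically zero")

  nroi_x <- max(1L, min(nx, as.integer(round(roi_side / h))))
  nroi_y <- max(1L, min(ny, as.integer(round(roi_side / h))))
  x0 <- floor((nx - nroi_x) / 2) + 1L
  y0 <- floor((ny - nroi_y) / 2) + 1L
  xs <- x0:(x0 + nroi_x - 1L)
  ys <- y0:(y0 + nroi_y - 1L)

  depth <- (seq_len(nz) - 0.5) * h
  rel <- numeric(nz)
  keep <- logical(nz)
  for (k in seq_len(nz)) {
    slice <- fluence$nfr[, , k]
    m <- max(slice)
    if (m <= 0) next
    keep[k] <- TRUE
    rel[k] <- 100 * mean(slice[xs, ys]) / m
  }
  if (!all(keep))
    warning(sprintf("%d slice(s) with zero maximum dropped", sum(!keep)))
  out <- data.frame(depth_mm = depth[keep], nfr_rel_pct = rel[keep])
  if (nrow(out) == 0L) stop("no slice carries fluence: empty profile")
  attr(out, "roi_side_effective") <- nroi_x * h
  attr(out, "config_label") <- config_label %||%
    sprintf("%d fibers", fluence$layout$n_fibers)
  attr(out, "seed") <- fluence$seed
  class(out) <- c("depth_profile", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate a depth profile into depth bins
#'
#' Averages `nfr_rel_pct` within depth bins centered on integer multiples of
#' `bin_width`, after discarding depths shallower than `z_min` (the first
#' voxel layers contain launch-position artifacts).
#'
#' @param profile a `depth_profile`
#' @param bin_width bin width, mm (default 0.25)
#' @param z_min minimum depth retained, mm (default 0.1)
#' @return data frame with `depth_mm` (bin centers) and `nfr_rel_pct`
#' @export
bin_profile <- function(profile, bin_width = 0.25, z_min = 0.1) {
  stopifnot(inherits(profile, "depth_profile"), bin_width > 0)
  p <- profile[profile$depth_mm >= z_min, , drop = FALSE]
  if (nrow(p) == 0L) stop("no depths at or beyond z_min")
  # round-half-up so bins get an even slice count (round() is half-to-even)
  bins <- floor(p$depth_mm / bin_width + 0.5) * bin_width
  agg <- aggregate(list(nfr_rel_pct = p$nfr_rel_pct),
                   by = list(depth_mm = bins), FUN = mean)
  agg[order(agg$depth_mm), , drop = FALSE]
}

#' Optimal (most homogeneous) illumination depth
#'
#' Returns the depth-bin center at which the binned \eqn{NFR_{rel}} profile
#' is maximal, with ties broken toward the shallower depth. Depths shallower
#' than `z_min` are excluded.
#'
#' @inheritParams bin_profile
#' @return optimal depth, mm (a bin center)
#' @export
optimal_depth <- function(profile, z_min = 0.1, bin_width = 0.25) {
  b <- bin_profile(profile, bin_width = bin_width, z_min = z_min)
  b$depth_mm[which.max(b$nfr_rel_pct)]
}

#' NFR_rel profiles for a sweep of fiber counts
#'
#' Runs one simulation per fiber configuration on the same grid and returns
#' the per-slice profiles as one tidy table (columns `depth_mm`,
#' `nfr_rel_pct`, `config_label`, `seed`).
#'
#' @param grid a [voxel_grid()]
#' @param fiber_counts vector of fiber counts, e.g. `c(4, 16, 36, 72)`
#' @param photons_per_fiber photons per fiber for every configuration
#' @param seed RNG seed shared by the runs
#' @param ring_radius fiber ring radius, mm
#' @param roi_side ROI side for [nfr_rel_profile()], mm
#' @return tidy data frame; the individual `depth_profile` objects are
#'   attached as attribute `profiles` (named by fiber count)
#' @export
profile_sweep <- function(grid, fiber_counts = c(4, 16, 36, 72),
                          photons_per_fiber = 1000, seed = 1L,
                          ring_radius = 1.425, roi_side = 1.96) {
  if (any(fiber_counts < 1)) stop("fiber counts must be positive")
  profiles <- lapply(fiber_counts, function(nf) {
    fl <- simulate_fluence(grid, annular_layout(nf, ring_radius = ring_radius),
                           photons_per_fiber, seed)
    nfr_rel_profile(fl, roi_side = roi_side,
                    config_label = sprintf("%d fibers", nf))
  })
  names(profiles) <- as.character(fiber_counts)
  tidy <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(depth_mm = p$depth_mm, nfr_rel_pct = p$nfr_rel_pct,
               config_label = attr(p, "config_label"),
               seed = attr(p, "seed"))
  }))
  rownames(tidy) <- NULL
  attr(tidy, "profiles") <- profiles
  tidy
}

#' Write a depth profile (or sweep table) to CSV
#'
#' @param profile a `depth_profile` or the tidy table from [profile_sweep()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  if (is.null(df$config_label))
    df$config_label <- attr(profile, "config_label") %||% NA_character_
  if (is.null(df$seed)) df$seed <- attr(profile, "seed") %||% NA_integer_
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot NFR_rel depth profiles
#'
#' Base-graphics rendering of one or more profiles (homogeneity vs depth).
#'
#' @param x a `depth_profile` or tidy sweep table with a `config_label` column
#' @param bin_width,z_min binning passed to [bin_profile()] when `x` is a
#'   single profile; set `bin_width = NA` to plot raw slices
#' @param ... passed to [graphics::matplot()]
#' @return invisibly, the plotted data
#' @export
plot_depth_profile <- function(x, bin_width = 0.25, z_min = 0.1, ...) {
  if (inherits(x, "depth_profile")) {
    d <- if (is.na(bin_width)) x else bin_profile(x, bin_width, z_min)
    graphics::plot(d$depth_mm, d$nfr_rel_pct, type = "l",
                   xlab = "depth (mm)", ylab = "NFR_rel (%)", ...)
    return(invisible(d))
  }
  labs <- unique(x$config_label)
  graphics::plot(range(x$depth_mm), range(x$nfr_rel_pct), type = "n",
                 xlab = "depth (mm)", ylab = "NFR_rel (%)", ...)
  for (i in seq_along(labs)) {
    d <- x[x$config_label == labs[i], ]
    graphics::lines(d$depth_mm, d$nfr_rel_pct, col = i)
  }
  graphics::legend("bottomright", legend = labs, col = seq_along(labs),
                   lty = 1, cex = 0.8)
  invisible(x)
}
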
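#' Write a fluence volume to NIfTI with a JSON sidecar
#'
#' The NFR array is written as a NIfTI volume with mm voxel spacing; run
#' metadata (seed, photon count, layout, region properties, weight ledger and
#' a config hash) goes to a JSON sidecar next to it, so the volume can be
#' re-loaded for analysis without re-running the simulation.
#'
#' @param fluence a `fluence_volume`
#' @param path output path ending in `.nii` or `.nii.gz`
#' @return `path`, invisibly
#' @export
write_fluence <- function(fluence, path) {
  stopifnot(inherits(fluence, "fluence_volume"))
  img <- RNifti::asNifti(fluence$nfr,
                         pixdim = rep(fluence$grid$voxel_size, 3))
  RNifti::writeNifti(img, path)
  meta <- list(
    extent = fluence$grid$extent,
    voxel_size = fluence$grid$voxel_size,
    dim = fluence$grid$dim,
    regions = lapply(fluence$grid$regions, function(p)
      p[c("mu_a", "mu_s_prime", "g", "n", "wavelength")]),
    uniform_region_map = length(unique(as.vector(fluence$grid$region_map))) == 1L,
    layout = layout_table(fluence$layout),
    layout_type = fluence$layout$type,
    photons_per_fiber = fluence$photons_per_fiber,
    seed = fluence$seed,
    launched_weight = fluence$launched_weight,
    deposited_weight = fluence$deposited_weight,
    escaped_weight = fluence$escaped_weight,
    roulette_net = fluence$roulette_net,
    conservation_residual = fluence$conservation_residual,
    config_hash = config_hash(list(
      dim = fluence$grid$dim, voxel = fluence$grid$voxel_size,
      layout = layout_table(fluence$layout),
      photons = fluence$photons_per_fiber, seed = fluence$seed)))
  jsonlite::write_json(meta, .sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a fluence volume written by [write_fluence()]
#'
#' @param path the `.nii` / `.nii.gz` path
#' @return a `fluence_volume` (the region map is reconstructed as uniform;
#'   heterogeneous region maps are analysis inputs only and are not
#'   round-tripped)
#' @export
read_fluence <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  regs <- meta$regions
  regions <- lapply(names(regs), function(nm) {
    p <- regs[[nm]]
    optical_properties(p$mu_a, p$mu_s_prime, g = p$g, n = p$n,
                       wavelength = p$wavelength %||% NA_real_, label = nm)
  })
  names(regions) <- names(regs)
  grid <- voxel_grid(unlist(meta$extent), meta$voxel_size, regions = regions)
  lay <- meta$layout
  fibers <- lapply(seq_len(nrow(lay)), function(i)
    fiber_source(c(lay$x_mm[i], lay$y_mm[i], lay$z_mm[i]),
                 c(lay$axis_x[i], lay$axis_y[i], lay$axis_z[i]),
                 lay$core_diameter_mm[i], lay$numerical_aperture[i]))
  layout <- new_probe_layout(fibers, meta$layout_type %||% "annular")
  structure(
    list(nfr = array(as.vector(img), dim = unlist(meta$dim)),
         grid = grid, layout = layout,
         photons_per_fiber = meta$photons_per_fiber,
         seed = meta$seed,
         launched_weight = meta$launched_weight,
         deposited_weight = meta$deposited_weight,
         escaped_weight = meta$escaped_weight,
         roulette_net = meta$roulette_net,
         truncated_photons = 0,
         conservation_residual = meta$conservation_residual),
    class = "fluence_volume")
}

#' Hash of a configuration object
#'
#' Deterministic short hash of any serializable R object, used to stamp
#' outputs so a run can be matched to its configuration.
#'
#' @param x an R object
#' @return character scalar (16 hex digits)
#' @export
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  # two polynomial rolling hashes over the serialized payload; products stay
  # below 2^53 so double arithmetic is exact
  h1 <- 17; h2 <- 40389
  for (b in raw) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

#' Read a run configuration from YAML
#'
#' The configuration drives the pipeline commands: a `grid` block (either a
#' liver preset: `{preset: liver, tissue_state, wavelength, extent,
#' voxel_size}`, or a liquid phantom: `{preset: liquid, mu_a, mu_s_prime,
#' ...}`), a `layout` block (`{type: annular|surface, n_fibers, ...}`),
#' `photons_per_fiber`, `seed`, an optional `analysis` block (`roi_side`,
#' `bin_width`, `z_min`, `thresholds`) and an `output` directory.
#'
#' @param path YAML file path
#' @return a list of class `run_config` with resolved `grid` and `layout`
#'   objects and analysis defaults filled in
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$grid)) stop("config is missing the 'grid' block")
  if (is.null(cfg$layout)) stop("config is missing the 'layout' block")
  g <- cfg$grid
  grid <- if (identical(g$preset, "liver")) {
    voxel_grid(unlist(g$extent %||% c(4, 4, 5)), g$voxel_size %||% 0.05,
               regions = list(liver = liver_optical_properties(
                 g$tissue_state %||% "native", g$wavelength %||% 650)))
  } else if (identical(g$preset, "liquid")) {
    liquid_phantom(g$mu_a %||% 0.1, g$mu_s_prime %||% 10,
                   extent = unlist(g$extent %||% c(30, 30, 20)),
                   voxel_size = g$voxel_size %||% 0.2,
                   g = g$g %||% 0.7, n = g$n %||% 1.33)
  } else if (!is.null(g$regions)) {
    regions <- lapply(names(g$regions), function(nm) {
      p <- g$regions[[nm]]
      if (is.null(p$mu_a) || is.null(p$mu_s_prime))
        stop(sprintf("region '%s' is missing mu_a or mu_s_prime", nm))
      optical_properties(p$mu_a, p$mu_s_prime, g = p$g %||% 0.9,
                         n = p$n %||% 1.33,
                         wavelength = p$wavelength %||% NA_real_, label = nm)
    })
    names(regions) <- names(g$regions)
    voxel_grid(unlist(g$extent), g$voxel_size, regions = regions)
  } else stop("grid block needs a preset or a regions map")

  l <- cfg$layout
  layout <- switch(l$type %||% "annular",
    annular = annular_layout(l$n_fibers %||% 72,
                             ring_radius = l$ring_radius %||% 1.425,
                             core_diameter = l$core_diameter %||% 0.1,
                             numerical_aperture = l$numerical_aperture %||% 0.22),
    surface = surface_layout(l$n_fibers %||% 6, spacing = l$spacing %||% 2,
                             standoff = l$standoff %||% 0),
    stop(sprintf("unknown layout type '%s'", l$type)))

  analysis <- modifyList(
    list(roi_side = 1.96, bin_width = 0.25, z_min = 0.1,
         penetration_db = -20, width_db = -35), cfg$analysis %||% list())
  structure(
    list(grid = grid, layout = layout,
         photons_per_fiber = cfg$photons_per_fiber %||% 1e5,
         seed = cfg$seed %||% 1L, analysis = analysis,
         output = cfg$output %||% ".", raw = cfg),
    class = "run_config")
}
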
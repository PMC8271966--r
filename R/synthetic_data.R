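#' Homogeneous liquid optical phantom
#'
#' An intralipid/India-ink style liquid phantom: a homogeneous grid with
#' tunable absorption and reduced scattering. Defaults mimic the field-of-view
#' experiments: \eqn{\mu_s' = 10} cm^-1 with \eqn{\mu_a = 0.1} cm^-1
#' (chicken-like) or 0.5 cm^-1 (liver-like). The anisotropy defaults to an
#' intralipid-like g = 0.7 and n = 1.33.
#'
#' @param mu_a absorption coefficient, cm^-1
#' @param mu_s_prime reduced scattering coefficient, cm^-1
#' @param extent grid extent c(x, y, z), mm; field-of-view scale by default
#' @param voxel_size voxel edge, mm
#' @param g anisotropy factor
#' @param n refractive index
#' @return a [voxel_grid()] with a single region `"phantom"`
#' @export
liquid_phantom <- function(mu_a = 0.1, mu_s_prime = 10,
                           extent = c(30, 30, 20), voxel_size = 0.2,
                           g = 0.7, n = 1.33) {
  voxel_grid(extent, voxel_size,
             regions = list(phantom = optical_properties(
               mu_a, mu_s_prime, g = g, n = n, label = "liquid phantom")))
}

#' Layered scene specification
#'
#' Describes a stack of tissue layers (top to bottom along z) with optional
#' embedded inclusions, for building ex vivo style scenes: chicken over
#' liver with a blood-filled tube, a tumor-mimicking inclusion, an ablation
#' lesion, or an absorbing slab at a chosen depth.
#'
#' @param name scene name
#' @param layers list of `list(label =, thickness =, props =)` entries,
#'   ordered from the surface (z = 0) downward; `props` are
#'   [optical_properties()]
#' @param inclusions list of `list(absorber =, props =)` entries: an
#'   [absorber_spec()] giving the geometry plus the optical properties of the
#'   material filling it
#' @param extent_lateral lateral extent c(x, y), mm
#' @param voxel_size voxel edge, mm
#' @param image_noise c(background mean, multiplicative speckle sigma) used
#'   by [synthetic_pa_image()] fixtures derived from the scene
#' @return an object of class `scene_spec`
#' @export
scene_spec <- function(name, layers, inclusions = list(),
                       extent_lateral = c(30, 30), voxel_size = 0.2,
                       image_noise = c(0.05, 0.1)) {
  for (l in layers) {
    if (is.null(l$label) || is.null(l$thickness) || is.null(l$props))
      stop("each layer needs label, thickness and props")
    if (l$thickness <= 0) stop("layer thicknesses must be positive")
    stopifnot(inherits(l$props, "optical_properties"))
  }
  for (inc in inclusions) {
    if (is.null(inc$absorber) || is.null(inc$props))
      stop("each inclusion needs an absorber spec and optical properties")
    stopifnot(inherits(inc$absorber, "absorber_spec"),
              inherits(inc$props, "optical_properties"))
  }
  structure(
    list(name = name, layers = layers, inclusions = inclusions,
         extent_lateral = extent_lateral, voxel_size = voxel_size,
         image_noise = image_noise),
    class = "scene_spec")
}

#' Build a voxel grid from a layered scene
#'
#' Stacks the layers along z and carves each inclusion into the region map.
#' Inclusions that fall entirely outside the volume raise an error.
#'
#' @param spec a [scene_spec()]
#' @return list with `grid` (a [voxel_grid()]) and `absorbers` (the
#'   [absorber_spec()] list of the inclusions, for perturbative PA
#'   evaluation)
#' @export
layered_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  thick <- vapply(spec$layers, `[[`, numeric(1), "thickness")
  ztot <- sum(thick)
  extent <- c(spec$extent_lateral, ztot)
  h <- spec$voxel_size
  dims <- round(extent / h)
  if (any(abs(extent / h - dims) > 1e-6))
    stop("layer thicknesses and lateral extent must be multiples of voxel_size")

  regions <- lapply(spec$layers, `[[`, "props")
  names(regions) <- vapply(spec$layers, `[[`, character(1), "label")
  # assign layer index per z voxel
  zc <- (seq_len(dims[3]) - 0.5) * h
  zedges <- cumsum(thick)
  layer_of_z <- findInterval(zc, c(0, zedges), rightmost.closed = TRUE)
  region_map <- array(rep(layer_of_z, each = dims[1] * dims[2]), dim = dims)

  grid <- voxel_grid(extent, h, regions = regions, region_map = region_map)
  absorbers <- list()
  for (inc in spec$inclusions) {
    idx <- length(grid$regions) + 1L
    lab <- inc$absorber$label %||% sprintf("inclusion_%d", length(absorbers) + 1L)
    mask <- absorber_voxels(grid, inc$absorber)
    if (!any(mask))
      stop(sprintf("inclusion '%s' lies outside the volume", lab))
    grid$regions[[lab]] <- inc$props
    grid$region_map[mask] <- idx
    absorbers[[lab]] <- inc$absorber
  }
  list(grid = grid, absorbers = absorbers)
}

#' Synthetic PA-image-like fixture with known ground truth
#'
#' Draws simple structures (discs, rectangles, lines) at specified dB
#' contrasts over a noisy background, returning the image together with the
#' exact signal masks so the construction contrast is known for SNR testing.
#' Pixel model: background pixels have mean `background_mean` (exponentially
#' distributed when `noise_sigma > 0`, constant otherwise); structure pixels
#' are `background_mean * 10^(contrast_db/20)` with multiplicative Gaussian
#' speckle of relative sigma `noise_sigma`, clipped at 0.
#'
#' @param structures list of `list(shape =, contrast_db =, label =, ...)`:
#'   shape `"disc"` needs `center` (row, col) and `radius`; `"rect"` needs
#'   `rows` and `cols` (index ranges); `"line"` needs `rows`, `cols` of equal
#'   length (pixel path, drawn with `width` >= 1)
#' @param dims image dimensions c(rows, cols)
#' @param background_mean mean background level
#' @param noise_sigma relative noise level (0 for a noise-free fixture)
#' @param seed RNG seed
#' @return list with `image`, `masks` (named list of logical matrices),
#'   `background_mask` (complement of all structures) and `contrasts_db`
#' @export
synthetic_pa_image <- function(structures, dims = c(128, 128),
                               background_mean = 0.05, noise_sigma = 0.1,
                               seed = 1L) {
  for (s in structures)
    if (is.null(s$shape) || is.null(s$contrast_db))
      stop("each structure needs a shape and a contrast_db")
  .with_seed(seed, {
    img <- if (noise_sigma > 0) {
      matrix(background_mean * stats::rexp(prod(dims)), dims[1], dims[2])
    } else matrix(background_mean, dims[1], dims[2])
    masks <- list()
    contrasts <- numeric(0)
    for (i in seq_along(structures)) {
      s <- structures[[i]]
      mask <- matrix(FALSE, dims[1], dims[2])
      if (s$shape == "disc") {
        rr <- row(mask) - s$center[1]
        cc <- col(mask) - s$center[2]
        mask <- rr^2 + cc^2 <= s$radius^2
      } else if (s$shape == "rect") {
        mask[s$rows, s$cols] <- TRUE
      } else if (s$shape == "line") {
        w <- max(1L, s$width %||% 1L)
        for (k in seq_along(s$rows)) {
          r0 <- max(1L, s$rows[k] - w %/% 2L)
          r1 <- min(dims[1], s$rows[k] + w %/% 2L)
          c0 <- max(1L, s$cols[k] - w %/% 2L)
          c1 <- min(dims[2], s$cols[k] + w %/% 2L)
          mask[r0:r1, c0:c1] <- TRUE
        }
      } else stop(sprintf("unknown shape '%s'", s$shape))
      level <- background_mean * 10^(s$contrast_db / 20)
      vals <- if (noise_sigma > 0)
        level * (1 + noise_sigma * stats::rnorm(sum(mask)))
      else rep(level, sum(mask))
      img[mask] <- pmax(vals, 0)
      lab <- s$label %||% sprintf("structure_%d", i)
      masks[[lab]] <- mask
      contrasts[lab] <- s$contrast_db
    }
    background <- !Reduce(`|`, masks)
    list(image = img, masks = masks, background_mask = background,
         contrasts_db = contrasts)
  })
}

#' Canned scene library
#'
#' One builder per experimental configuration the pipeline emulates:
#' \describe{
#'   \item{liquid_line}{liquid phantom (chicken- or liver-mimicking) with the
#'     0.19 mm line absorber for field-of-view mapping}
#'   \item{slab_depth}{chicken volume with an absorbing slab at 15 or 32 mm
#'     below the surface (surface vs interstitial comparison)}
#'   \item{tines}{chicken volume plus thin metallic-rod stand-ins for the RFA
#'     tines, drawn as absorptive line inclusions (no specular model)}
#'   \item{blood_tube}{chicken-over-liver scene with a 1 mm inner-diameter
#'     blood-filled tube}
#'   \item{tumor}{chicken-over-liver scene with a blood-soaked
#'     tumor-mimicking inclusion}
#'   \item{ablation}{chicken over native liver with an ablated-liver lesion
#'     region}
#' }
#'
#' @param name one of the scene names above
#' @param ... overrides: `slab_depth_mm` (15 or 32), `mu_a_blood` (default 4,
#'   within the 2-7 cm^-1 whole-blood range), `mu_a_tumor` (default 4; the
#'   true post-soak value is unknown and exposed as a free parameter),
#'   `wavelength` (default 650 for the liver presets), `voxel_size`
#' @return list with `grid` and `absorbers` as in [layered_scene()]
#' @export
scene_library <- function(name = c("liquid_line", "slab_depth", "tines",
                                   "blood_tube", "tumor", "ablation"), ...) {
  name <- match.arg(name)
  opt <- list(...)
  slab_depth_mm <- opt$slab_depth_mm %||% 15
  mu_a_blood <- opt$mu_a_blood %||% 4
  mu_a_tumor <- opt$mu_a_tumor %||% 4
  wavelength <- opt$wavelength %||% 650
  chicken <- optical_properties(0.1, 10, g = 0.9, n = 1.33,
                                wavelength = wavelength, label = "chicken")
  liver <- liver_optical_properties("native", wavelength)
  ablated <- liver_optical_properties("ablated_70C", wavelength)
  blood <- optical_properties(mu_a_blood, 10, g = 0.95, n = 1.33,
                              wavelength = wavelength, label = "blood")

  switch(name,
    liquid_line = {
      grid <- liquid_phantom(opt$mu_a %||% 0.1, opt$mu_s_prime %||% 10,
                             voxel_size = opt$voxel_size %||% 0.2)
      ab <- absorber_spec("line", diameter = 0.19,
                          position = c(0, 0, 5), orientation = c(0, 1, 0),
                          label = "line_absorber")
      list(grid = grid, absorbers = list(line_absorber = ab))
    },
    slab_depth = {
      if (!slab_depth_mm %in% c(15, 32))
        stop("slab_depth_mm must be 15 or 32")
      h <- opt$voxel_size %||% 0.25
      spec <- scene_spec("slab_depth",
        layers = list(list(label = "chicken", thickness = 40, props = chicken)),
        extent_lateral = c(25, 25), voxel_size = h)
      out <- layered_scene(spec)
      out$absorbers <- list(slab = absorber_spec(
        "slab", diameter = 1, position = c(0, 0, slab_depth_mm),
        mu_a_absorber = 20, label = "slab"))
      out
    },
    tines = {
      h <- opt$voxel_size %||% 0.2
      spec <- scene_spec("tines",
        layers = list(list(label = "chicken", thickness = 20, props = chicken)),
        inclusions = lapply(c(-25, 0, 25), function(ang) {
          a <- ang * pi / 180
          list(absorber = absorber_spec("line", diameter = 0.4,
                 position = c(5 * sin(a), 0, 5 + 5 * cos(a)) ,
                 orientation = c(sin(a), 0, cos(a)), length = 10,
                 mu_a_absorber = 50,
                 label = sprintf("tine_%+d", ang)),
               props = optical_properties(50, 5, g = 0.9))
        }),
        extent_lateral = c(24, 24), voxel_size = h)
      layered_scene(spec)
    },
    blood_tube = {
      h <- opt$voxel_size %||% 0.2
      spec <- scene_spec("blood_tube",
        layers = list(list(label = "chicken", thickness = 10, props = chicken),
                      list(label = "liver", thickness = 10, props = liver)),
        inclusions = list(list(
          absorber = absorber_spec("tube", diameter = 1,
            position = c(0, 0, 14), orientation = c(0, 1, 0), length = 20,
            mu_a_absorber = mu_a_blood, label = "blood_tube"),
          props = blood)),
        extent_lateral = c(24, 24), voxel_size = h)
      layered_scene(spec)
    },
    tumor = {
      h <- opt$voxel_size %||% 0.2
      tumor_props <- optical_properties(mu_a_tumor, 10, g = 0.9, n = 1.33,
                                        wavelength = wavelength,
                                        label = "tumor_mimic")
      spec <- scene_spec("tumor",
        layers = list(list(label = "chicken", thickness = 10, props = chicken),
                      list(label = "liver", thickness = 10, props = liver)),
        inclusions = list(list(
          absorber = absorber_spec("inclusion", diameter = 8,
            position = c(0, 0, 12), mu_a_absorber = mu_a_tumor,
            label = "tumor"),
          props = tumor_props)),
        extent_lateral = c(24, 24), voxel_size = h)
      layered_scene(spec)
    },
    ablation = {
      h <- opt$voxel_size %||% 0.2
      spec <- scene_spec("ablation",
        layers = list(list(label = "chicken", thickness = 8, props = chicken),
                      list(label = "liver", thickness = 12, props = liver)),
        inclusions = list(list(
          absorber = absorber_spec("inclusion", diameter = 10,
            position = c(0, 0, 14), mu_a_absorber = ablated$mu_a,
            label = "lesion"),
          props = ablated)),
        extent_lateral = c(24, 24), voxel_size = h)
      layered_scene(spec)
    })
}
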
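# Shared fixtures for the test suite. Heavier Monte Carlo runs used by the
# acceptance checks are memoized so several test blocks can share one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# wrap a hand-made nfr array as a fluence_volume, bypassing transport
fake_fluence <- function(nfr, voxel = 1) {
  d <- dim(nfr)
  g <- voxel_grid(d * voxel, voxel,
                  regions = list(m = optical_properties(1, 10)))
  structure(
    list(nfr = nfr, grid = g, layout = annular_layout(4),
         photons_per_fiber = 1L, seed = 1L,
         launched_weight = 1, deposited_weight = 1, escaped_weight = 0,
         roulette_net = 0, truncated_photons = 0,
         conservation_residual = 0),
    class = "fluence_volume")
}

liver_grid <- function(state, wavelength, voxel = 0.05) {
  voxel_grid(c(4, 4, 5), voxel,
             regions = list(liver = liver_optical_properties(state, wavelength)))
}

# one pencil-beam layout (NA -> 0, tiny core) aimed down the +z axis
pencil_layout <- function(origin = c(0, 0, 0)) {
  f <- fiber_source(origin, c(0, 0, 1), core_diameter = 1e-4,
                    numerical_aperture = 0)
  afpsim:::new_probe_layout(list(f), "annular")
}

# liver characterization run at the resolution used for the homogeneity
# analysis; ppf chosen so the binned depth-of-optimum is stable to one
# 0.25 mm bin across seeds (see the methods vignette)
liver_run <- function(state, wavelength, ppf = 20000, seed = 11L) {
  cached(sprintf("liver_%s_%d_%d_%d", state, wavelength, ppf, seed), {
    simulate_fluence(liver_grid(state, wavelength), annular_layout(72),
                     photons_per_fiber = ppf, seed = seed)
  })
}

liver_optimum <- function(state, wavelength, ppf = 20000, seed = 11L) {
  optimal_depth(nfr_rel_profile(liver_run(state, wavelength, ppf, seed)))
}
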
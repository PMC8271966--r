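# afpsim

Monte Carlo fluence and photoacoustic (PA) field modelling for annular-fiber
interstitial illumination probes.

## The problem

Photoacoustic imaging can guide radiofrequency ablation (RFA) of liver
tumors — the RFA needle, blood vessels, tumor tissue and ablated tissue all
differ in optical absorption — but light launched from the skin surface
barely penetrates a few millimetres into liver. An annular fiber probe
(AFP) solves this by delivering light interstitially: 72 multimode fibers
(100 µm core, NA 0.22) sit in a ring between two ferrules (2.3 / 3.4 mm
diameter) on a cannula whose lumen passes the RFA device.

Designing and interpreting such a probe raises questions this package
answers computationally:

* **Fluence homogeneity.** Directly in front of the fiber ring the fluence
  is annular with a dark center; only beyond some depth does it merge into a
  usable, centered illumination spot. For each tissue and wavelength the
  package computes the depth-resolved homogeneity statistic
  `NFR_rel(z) = 100 · mean(NFR over a centered 1.96 mm ROI) / max(NFR in the slice)`
  and its argmax, the **optimal illumination depth**.
* **PA field of view.** A perturbative forward model
  (`amplitude ∝ μₐ × fluence`) maps the relative PA amplitude of a small
  absorber around the probe tip in dB, from which the −20 dB penetration
  depth and −35 dB lateral width follow.
* **Image quantification.** The ROI signal-to-noise statistic
  `SNR = 20·log10(S_R/S_n)` with sub-ROI resampling uncertainty, as used on
  PA/US images.

The transport kernel (C++ via Rcpp) follows the standard voxelized MCML
scheme: exponential step sampling with the local `μt = μa + μs`,
`μs = μs′/(1−g)`, partial weight deposition `w·μa/μt`, Henyey–Greenstein
scattering, Russian roulette, escape at the grid boundary, and per-fiber
deterministic RNG streams. Energy conservation
(`launched = deposited + escaped`) is enforced to 1e-6 relative on every
run. Tabulated optical properties of native and thermally ablated (70 °C)
liver at 650/900/1050 nm ship with the package; synthetic phantom and scene
generators (liquid phantom, layered chicken-over-liver scenes with blood
tube / tumor mimic / ablation lesion, PA-image fixtures with known
contrast) make the whole pipeline testable without experimental data.

## Worked example

A desk-scale characterization of the 72-fiber probe in native liver at
650 nm (coarse 0.1 mm voxels for speed; the analysis default is 0.05 mm):

```r
library(afpsim)

grid  <- voxel_grid(extent = c(4, 4, 5), voxel_size = 0.1,
                    regions = list(liver = liver_optical_properties("native", 650)))
probe <- annular_layout(n_fibers = 72)
probe
#> <probe_layout: annular> 72 fibers, ring radius 1.425 mm (annulus 2.30-3.40 mm dia.)

fl <- simulate_fluence(grid, probe, photons_per_fiber = 3000, seed = 42)
fl
#> <fluence_volume> 40 x 40 x 50 voxels @ 0.1 mm, 72 fibers x 3000 photons (seed 42)
#>   weights: launched 216000 = deposited 73184.1 + escaped 142816 (residual 2.5e-12)

prof <- nfr_rel_profile(fl)        # NFR_rel per slice, 1.96 mm ROI
head(bin_profile(prof), 10)        # averaged into 0.25 mm depth bins
#>    depth_mm nfr_rel_pct
#> 1      0.25    5.657301
#> 2      0.50   14.073272
#> 3      0.75   27.567787
#> 4      1.00   44.463807
#> 5      1.25   57.038072
#> 6      1.50   65.689948
#> 7      1.75   71.515546
#> 8      2.00   72.031629
#> 9      2.25   71.652352
#> 10     2.50   65.303776
optimal_depth(prof)
#> [1] 2
```

Reading the output: close to the probe the ROI mean is a small fraction of
the slice maximum (the fluence is a bright ring with a dark center —
`NFR_rel` ≈ 6% at 0.25 mm), the distribution merges into its most
homogeneous state around 2 mm depth (`NFR_rel` ≈ 72%), and beyond that a
centered Gaussian-like spot remains. The weight ledger in the printout is
the per-run energy-conservation check.

The same machinery drives fiber-count sweeps
(`profile_sweep(grid, c(4, 16, 36, 72), ...)`), PA field maps
(`field_map()`, `penetration_depth()`, `field_width()`), surface-versus-
interstitial comparisons (`surface_layout()` + `pa_amplitude_at()`), and
image SNR (`image_roi()`, `snr_db()`, `frame_average()`). A thin CLI with
`simulate` / `homogeneity` / `pa-field` / `snr` / `fixtures` / `sweep`
subcommands is installed at `inst/cli/afpsim`; volumes are written as NIfTI
with a JSON metadata sidecar, and all tabular output is CSV.

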
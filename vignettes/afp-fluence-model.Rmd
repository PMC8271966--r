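---
title: "Modelling interstitial annular-fiber illumination: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interstitial annular-fiber illumination: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Photoacoustic (PA) imaging of the liver during radiofrequency ablation is
limited by the shallow penetration of light: in liver the optical penetration
depth is only a few millimetres, so illumination from the skin surface cannot
reach a deep target. An annular fiber probe (AFP) — a cannula carrying 72
multimode fibers (100 µm core, NA 0.22) in a ring between an inner ferrule of
2.3 mm and an outer ferrule of 3.4 mm diameter — delivers light
interstitially: the probe is inserted into tissue and an RFA device slides
through its lumen. Two questions determine whether such a probe is useful:

1. **How far in front of the probe does the fluence become homogeneous?**
   Directly in front of the fiber ring the light forms an annulus with a dark
   center; imaging inside that region is unreliable. Beyond some depth the
   ring diffuses into a centered, Gaussian-like spot.
2. **How large is the usable PA field of view** around the probe tip, and how
   does it depend on the absorption of the surrounding medium?

`afpsim` answers both with a voxelized Monte Carlo (MC) photon-transport
model, plus the image metrics (ROI SNR) used to quantify PA/US image quality.

## Transport model

The kernel implements the standard MCML-style voxel scheme:

- step lengths are sampled from the local attenuation,
  $s = -\ln \xi / \mu_t$ with $\mu_t = \mu_a + \mu_s$ and
  $\mu_s = \mu_s'/(1-g)$;
- at each interaction a fraction $\mu_a/\mu_t$ of the photon weight is
  deposited and the direction is redrawn from the Henyey–Greenstein phase
  function with the local anisotropy $g$;
- photons are tracked voxel-by-voxel (a DDA traversal), so layered and
  heterogeneous media are handled exactly;
- Russian roulette terminates photons below a weight of $10^{-4}$ with
  survival probability $1/10$;
- photons leaving the grid are terminated and booked as escaped. The
  refractive index is uniform ($n = 1.33$ for both native and ablated
  liver), so no internal Fresnel reflection or refraction is modelled; the
  index enters only through the in-tissue launch cone
  $\theta_{max} = \arcsin(\mathrm{NA}/n)$.

The normalized fluence rate (NFR, 1/cm² per unit incident power) is scored
with the deposited-energy estimator, $\Phi_v = E_v /(\mu_a V N)$, matching
the output quantity of the standard MC toolboxes; voxels with $\mu_a = 0$
fall back to a track-length estimator so the fluence remains defined there.

**Energy bookkeeping.** The ledger `launched = deposited + escaped` is
enforced to $10^{-6}$ relative on every run — not just in expectation — by
folding the net weight retired and created by Russian roulette into
`escaped_weight` (reported separately as `roulette_net`).

**Reproducibility.** Each fiber owns an independent counter-seeded
xoshiro256++ stream derived from `(seed, fiber index)`, so runs are
bit-reproducible, independent of fiber order, and do not touch R's RNG.

### Launch model

The source description gives the NA and a "Gaussian beam profile" but not
the exact in-tissue distributions, so the package fixes them as follows and
exposes them as parameters:

- launch position: radially Gaussian on the fiber face with
  $\sigma = r_{core}/2$, truncated at the core edge (the 2σ contour matches
  the physical 100 µm core);
- polar angle: Gaussian with $\sigma = \theta_{max}/2$ truncated at
  $\theta_{max}$, azimuth uniform;
- the fiber ring radius is not documented; the mid-annulus radius
  $(2.3 + 3.4)/4 = 1.425$ mm is the symmetric default and is configurable.
  The first fiber sits at azimuth 0 (the +x axis); the absolute azimuth is
  physically irrelevant by symmetry and fixed for reproducibility. All 72
  fibers are assumed to sit on a single circle.

### Optical properties

`liver_optical_properties()` carries the tabulated absorption and reduced
scattering of native and thermally ablated (70 °C) liver at 650, 900 and
1050 nm, with $g = 0.93$ (native) / $0.90$ (ablated) and $n = 1.33$ for
both states. $\mu_s'$ and $g$ are stored as primary and $\mu_s$ derived on
demand: the tabulated $\mu_s$ values were evidently printed from rounded
inputs (e.g. $8.26/0.07 = 118.00$ vs a printed 118.01), so the derived value
is authoritative and agrees with the printed one within 0.1 cm⁻¹ everywhere.
No spectral interpolation is offered — only three wavelengths were ever
simulated, and interpolating would invent data.

## The homogeneity statistic

For each transverse slice at depth $z$,

$$ NFR_{rel}(z) = 100 \cdot \frac{\overline{NFR}_{ROI}(z)}{NFR_{max}(z)} $$

with the ROI a 1.96 × 1.96 mm square centered on the probe axis and
$NFR_{max}$ the slice maximum. The optimal illumination depth is the argmax
of this profile. Numerical choices:

- **Depth binning (0.25 mm, configurable).** At desk-scale photon counts the
  single-slice argmax is noise-dominated (the slice maximum is a biased,
  noisy statistic); profiles are averaged within 0.25 mm bins centered on
  multiples of 0.25 mm before the argmax. Binning uses round-half-up so
  every bin holds the same number of slices. Reported optima are therefore
  bin centers, consistent with the 0.5 mm granularity at which such optima
  are usually quoted.
- **z_min = 0.1 mm.** The first voxel layers contain launch-position
  artifacts (the discrete fiber spots themselves) and are excluded.
- **ROI snapping.** When the ROI side is not an integer number of voxels it
  snaps to the nearest voxel-aligned square; the effective side is recorded
  in the profile's attributes.
- **Ties** in the binned argmax break toward the shallower depth.
- Slices with zero maximum (no fluence reached them) are dropped with a
  warning rather than producing 0/0.

## Problem sizes (desk scale)

The original study ran 820³ voxels with 3×10⁶ photons per fiber — about six
hours and 7 GB per configuration. The package defaults are chosen so a full
characterization runs on a laptop while preserving the binned depth
statistics: a 4 × 4 × 5 mm volume at 0.05 mm voxels (80 × 80 × 100) and
50,000 photons per fiber (3.6 M photons for the 72-fiber ring, about one to
two minutes per run). This photon budget was selected by a precision
analysis: across independent seeds the binned optimum must be stable to one
0.25 mm bin; 5,000 photons/fiber is visibly under-resolved (the noisy slice
maximum biases $NFR_{rel}$ downward at depth and the optimum shallow), while
at 50,000 the native-650 nm optimum is reproducibly 2.0 mm. Everything is
overridable up to the full published scale.

With these settings the model reproduces the study's findings: native liver
at 650 nm is most homogeneously illuminated near 2 mm depth; ablated liver
(higher $\mu_s'$, shorter transport mean free path) near 1.5 mm at all three
wavelengths; the native optimum deepens by about 0.5 mm at 900 nm and about
1 mm at 1050 nm; and more fibers give a higher $NFR_{rel}$ at an unchanged
optimal depth.

## PA forward model

PA amplitude is modelled perturbatively: the initial pressure is
proportional to the local absorbed energy, so a small absorber's relative
amplitude is $A = \Gamma\, \mu_a^{abs}\, \langle NFR \rangle$ over the
voxels it occupies, with the fluence computed **without** the absorber.
This first-order approximation is appropriate because the characterization
target (a 0.19 mm line) is tiny compared to the field and all reported maps
are relative; it would bias results for large or very dark inclusions, where
the absorber's own shadow matters. Field maps are normalized to their
maximum and expressed as $20\log_{10}(A/A_{max})$ (a pressure-like dB
convention, matching the −20/−35 dB display thresholds); penetration depth
and lateral width are read off the dB map with linear interpolation between
samples. Acoustic propagation, transducer bandwidth and image reconstruction
are deliberately out of scope, so measured dB maps are matched in shape and
trend, not absolute value: higher background absorption must narrow the
−35 dB width and shorten the −20 dB penetration, and the liver-mimicking
phantom ($\mu_a = 0.5$ cm⁻¹, $\mu_s' = 10$ cm⁻¹) lands in the same 4–12 mm
penetration decade as the measured 7 mm.

The **line absorber's evaluation length** defaults to 1 mm: the physical
line target spans the tank, but the detected in-plane signal comes from
roughly the elevational slice thickness of the transducer; averaging the
fluence over the full line would wash lateral structure out of the map.

**Interstitial vs surface illumination.** With the annular layout advanced
to a fixed probe–target standoff, the modelled target amplitude is
insensitive to how deep the target lies beneath the outer surface (the light
always travels the same standoff), whereas a surface layout decays roughly
as $e^{-\mu_{eff} z}$. This is the modelled counterpart of the experimental
observation that interstitial SNR was depth-independent while surface SNR
collapsed between 15 mm and 32 mm target depth.

## Image metrics

The SNR statistic is $20\log_{10}(S_R/S_n)$, with $S_R$ the mean normalized
pixel value over the signal ROI and $S_n$ over the background. Design
choices:

- **Normalization is by the per-frame maximum** (configurable: `"max"`,
  `"minmax"`, `"none"`). A min–max normalization would send a constant
  background to zero and make the ratio undefined; dividing by the maximum
  preserves the defining property that a constant 0.5 signal over a constant
  0.05 background is exactly 20 dB, and leaves the ratio statistic invariant
  to overall gain.
- **Uncertainty by sub-ROI resampling**: $S_R$ is recomputed over 10
  (configurable) random sub-ROIs of half the signal-region area, and the
  mean ± SD of the resulting SNRs is reported — mirroring the practice of
  estimating the ROI mean "several times per object".
- `frame_average()` is a plain pixelwise mean; averaging 20 signed frames
  before envelope detection improves SNR by $20\log_{10}\sqrt{20} \approx
  13$ dB on i.i.d. noise, which the test suite verifies on a constructed
  fixture.

## Synthetic data

The generator modules produce every input the pipeline needs:

- `liquid_phantom()` — the intralipid/India-ink tank with tunable
  $\mu_a/\mu_s'$; $g = 0.7$ is a standard intralipid-like value (the
  experiments never state it) and is recorded in output metadata.
- `layered_scene()` / `scene_library()` — chicken-over-liver stacks with a
  1 mm blood tube ($\mu_a$ defaulting to 4 cm⁻¹, inside the quoted 2–7 cm⁻¹
  whole-blood range), a tumor-mimicking inclusion (its true post-blood-soak
  absorption is unknown and exposed as a free parameter), an ablated-liver
  lesion, an absorbing slab at 15 or 32 mm, and rod stand-ins for the RFA
  tines (drawn as absorptive structures; no specular metal model is in
  scope). Chicken defaults to $\mu_a = 0.1$ cm⁻¹, $\mu_s' = 10$ cm⁻¹ — the
  same values the liquid phantom uses to mimic it.
- `synthetic_pa_image()` — PA-image-like 2D fixtures with structures drawn
  at known dB contrast over exponential background noise and multiplicative
  speckle, returning exact masks so the SNR ground truth is known by
  construction.

**What passing tests do and do not show.** The synthetic scenes share the
geometry and optical contrasts of the experiments but none of the acoustic
physics: no beamforming, no bandwidth filtering (which in reality reduces a
filled tube to its walls), no reconstruction artifacts, no system gain.
Agreement on these fixtures validates the optics, the statistics and the
bookkeeping — not the full imaging chain.

## Known limitations

- The deposited-energy estimator is noisy in voxels that absorb little;
  very low-absorption media are better served by the track-length fallback,
  which the kernel applies only at exactly $\mu_a = 0$.
- The steel ferrules, epoxy and Pebax sheath are not optical boundaries; any
  reflectivity of the probe face is unmodelled.
- Lateral escape at the 4 × 4 mm volume boundary slightly depresses deep
  fluence compared to an unbounded medium; the lateral extent is
  configurable for sensitivity checks.
- Fibers are modelled as identical and lossless; coupling variation across
  the physical bundle is not represented.
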
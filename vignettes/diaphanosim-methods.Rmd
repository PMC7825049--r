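---
title: "Modelling transillumination of the maxillary sinus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transillumination of the maxillary sinus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diaphanosim)
```

# The measurement being modelled

Digital diaphanoscopy probes the maxillary sinuses with low-intensity red
(650 nm) and near-infrared (850 nm) light delivered from inside the oral
cavity; a camera facing the cheek records the light that survives the
trip through mucosa, bone, the sinus cavity and the facial soft tissue.
A healthy sinus is an air pocket and transmits comparatively well; cystic
fluid or tumor tissue filling the cavity absorbs and scatters the probe
light and dims the emerging pattern, preferentially in the near infrared.
`diaphanosim` implements a forward model of this measurement — geometry,
photon transport, camera — plus the image quantification applied to the
recorded patterns.

# Tissue geometry

The transillumination path is modelled as a planar multilayer, laterally
infinite (the standard slab-geometry convention for layered-tissue Monte
Carlo), with the z axis running from the source face (z = 0, oral cavity
side) to the detector face (outer skin). The stack has eight layers in
fixed order: palatine mucosa, palatine bone, inner sinus mucosa, sinus
cavity, outer sinus mucosa, zygomatic bone, hypodermis, epidermis+dermis.
Layer thicknesses are sex-specific presets and μ_a, μ_s are
per-wavelength presets, shipped as a human-readable YAML file
(`inst/extdata/tissue_presets.yaml`) and loaded by `build_stack()`.

Several aspects of this parameterisation were genuinely open and were
settled as follows:

* **Mucosa on both sides of the cavity.** The published thickness table
  lists one 0.5 mm "sinus mucosa" entry, while the model description
  counts eight layers. Anatomically the mucosa lines the whole cavity, so
  the 0.5 mm mucosa is applied on both the inner and the outer cavity
  wall; this also reconciles the layer count.
* **Epidermis+dermis thickness.** The source anatomy gives ranges
  (1.5–3 mm male, 1–2 mm female); the presets use the midpoints (2.25 and
  1.5 mm), overridable per call.
* **Anisotropy and refractive index.** The coefficient table provides
  only μ_a and μ_s. Defaults g = 0.9 and n = 1.4 for all condensed
  tissues (air: g = 0, n = 1) are the standard soft-tissue/bone values;
  both are per-layer configurable. Because the tabulated μ_s magnitudes
  (0.8–3.7 mm⁻¹) are closer to typical *reduced* scattering coefficients
  than to full ones, `build_stack(..., scattering = "reduced")` offers the
  alternative reading: μ_s treated as μ_s′ with isotropic (g = 0)
  transport. The default is the literal reading. Which reading the
  original tabulation intended is unknowable from the numbers alone; both
  are first-class.
* **Pathology geometry.** A cyst or tumor replaces the entire air cavity
  by default. A `fill_fraction` parameter places a partial pathological
  layer adjacent to the inner mucosa (with residual air above it, giving
  a ninth layer) for partially filled sinuses.

`total_interaction_depth()` and `ballistic_transmission()` expose the
closed-form optical thickness Σ(μ_a + μ_s)d and its exponential — the
main analytic oracles used by the tests.

# Photon transport

`run_simulation()` drives a weighted-packet (implicit capture) Monte
Carlo engine written in C++:

1. **Hop** — dimensionless step −ln(u) consumed against the local
   μ_t = μ_a + μ_s, segment by segment across boundaries. Layers with
   μ_t = 0 (the air cavity) are crossed ballistically in one flight.
2. **Drop** — at each interaction the packet deposits the fraction
   μ_a/μ_t of its weight into the local layer's absorption tally and
   keeps the rest.
3. **Spin** — the new direction follows the Henyey–Greenstein phase
   function, the one-parameter standard for tissue scattering; g = 0
   reduces to an isotropic deflection cosine.
4. **Boundaries** — unpolarized Fresnel reflectance decides specular
   reflection versus Snell refraction stochastically, including total
   internal reflection; the entry face (ambient n = 1 by default) is
   treated the same way.
5. **Termination** — packets leave through the front face (reflected
   tally), the back face (transmitted; binned into the detector grid by
   exit position, with out-of-aperture weight tallied separately), or are
   terminated by Russian roulette once their weight falls below 10⁻⁴
   (survival probability 0.1, survivors boosted ×10 — unbiased in
   expectation). With roulette disabled, energy conservation is exact to
   floating point; with it enabled the relative error stays below 10⁻³
   at 10⁴+ packets.

**Randomness and determinism.** Each packet draws from its own
counter-based substream (splitmix64) seeded from the run seed and the
packet index. Two consequences: identical configurations are
bit-identical across runs, and enlarging the packet count does not
reshuffle the draws of earlier packets. The R-level samplers
(`sample_free_path()`, `sample_scatter()`, `fresnel_interaction()`)
mirror the C++ physics and take their uniform draws as arguments, so the
tests can check each primitive against closed forms independently of any
generator.

**Degenerate inputs.** Zero-thickness layers are dropped before
simulation (a zero-thickness hypodermis is a no-op interface); a stack of
total thickness zero transmits every packet at its entry point through a
single ambient-to-ambient interface. Non-finite packet states or a packet
exceeding the per-packet event budget abort with a diagnostic rather than
being dropped silently.

**Source model.** The default source is an on-axis pencil beam at 8 mW —
collimated entry is what the validation oracles (Beer–Lambert, benchmark
reflectance) require. A cone beam and an array of offset emitters
(mimicking the multi-LED applicator, cycled packet-by-packet) are
available. The detector is a 64 × 64-bin grid over 40 × 40 mm at the
outer skin surface; scoring happens at the tissue surface, not after
free-space propagation to a lens.

# Validation anchors

Three independent anchors pin the engine down, all exercised by the test
suite and the acceptance script:

* **Beer–Lambert**: with scattering disabled and matched indices the
  transmitted fraction must equal exp(−Σμ_a d), with the exponent summed
  layer-by-layer from an independently transcribed coefficient table.
* **Semi-infinite diffuse reflectance**: an isotropically scattering
  half-space with single-scattering albedo 0.9 and a matched boundary
  reflects 0.41497 of a normally incident pencil beam. This reference was
  regenerated independently before the engine was built, two ways: the
  exact Chandrasekhar H-function identity A(μ₀) = 1 − H(μ₀)√(1−ω)
  (H obtained by fixed-point iteration, verified against the zeroth
  moment identity to 13 digits) and a separate vectorized long-run
  simulation; the two agree to ~2 × 10⁻⁴.
* **Sampling closed forms**: free-path mean 1/μ_t; Henyey–Greenstein mean
  deflection cosine g, with the variance for the test band obtained by
  numerically integrating the phase function.

On the similarity relation: replacing (μ_s, g) by (μ_s(1−g), 0) preserves
slab transmission only approximately. For a pure-scattering 20 mm slab
the two agree to under a percent, and the test asserts that form (3%
band); with absorption present, transmission is exponentially sensitive
to the effective attenuation coefficient, which similarity preserves only
to first order, and relative deviations of several percent are expected
and observed. The equivalence switch is therefore a modelling choice, not
a numerical identity.

# The simulation campaign

`run_condition_grid()` crosses sex × pathology × wavelength (12 cells),
`hypodermis_sweep()` varies the hypodermis over 1–5 mm (bracketing the
3 mm preset — the subcutaneous fat is the strongest absorber in the
stack and the key anatomical covariate), and `source_power_response()`
maps flux over the applicator's 0–750 mW range by exact linear rescaling
of one run, since Monte Carlo weights are relative. Each cell's seed is
derived by hashing the condition label into the run seed, so results are
invariant to execution order and to subsetting the grid. Per-cell
standard errors come from the per-packet transmitted-weight variance;
they are what turns the campaign's ordering claims (healthy > cyst,
healthy > tumor at 850 nm; female > male for matched conditions;
monotone decay with hypodermis thickness) into statistical tests. No
absolute flux values are asserted anywhere: the campaign's published
counterpart is a figure without printed numbers, so orderings and
closed-form ratios are the testable content.

# Synthetic images

The camera model is deliberately minimal: counts = gain × irradiance ×
exposure + offset, rounded and clipped to the bit depth (8-bit default),
with optional Gaussian read noise and Poisson shot noise. The true
radiometric calibration of the clinical camera is unknown; `auto_gain()`
places a given map's peak at a target fraction (default 80%) of full
scale at the 20.7 ms working exposure. The exposure-series generator
defaults to 1–40 ms in 1 ms steps — forty values; the acquisition
protocol's "0 to 40 ms" range description does not fix whether the grid
starts at 0 or 1, and a zero-exposure frame (pure offset) remains
available explicitly.

The two-sinus face phantom gives the image metrics a ground truth:
flat-topped elliptical bright regions on a dim background, optionally
with a darker inclusion mimicking a cyst, whose continuous (pre-
quantization) region means are known by construction. What the phantom
does **not** emulate: smooth intensity falloff at region edges, facial
structure and texture, lens effects (PSF, vignetting), stray light, or
patient-to-patient anatomical variation. Passing metric tests on the
phantom therefore demonstrates correctness of the arithmetic and its
quantization behaviour, not clinical robustness on real faces.

# Image quantification

The clinical software reports "the percentage of light passed through
the sinus" without a published formula. The package's primary definition
is the mean offset-corrected ROI intensity as a percentage of the
offset-corrected full scale. Because that definition scales with
exposure, an alternative form — the ROI mean relative to the
contralateral ROI — is available via `reference = "contralateral"`; the
left/right *ratio* (and hence the asymmetry index
|p_L − p_R|/(p_L + p_R)) is invariant under any common intensity scaling,
which is what makes the observed insensitivity of the diagnostic result
to exposure time expressible as a testable property. The residual
variation of the ratio across an exposure series is bounded by count
quantization (±0.5 counts per flat region), and the tests assert exactly
that bound rather than an arbitrary tolerance.

Pseudo-color segmentation quantizes intensities into n equal-width bands
(default 8) over either the full scale or the image's own range; labels
are stable (0 = darkest) and color lookup happens only at PNG export. A
constant image under image-range normalization degenerates to a single
band and is flagged rather than erroring.

ROIs can be parametric ellipses (reproducible tests) or manual polygon
outlines (the clinical workflow); polygon membership uses the even-odd
rule via `mgcv::in.out`.

# Problem sizes and budgets

The shipped tests use 10³–2×10⁴ packets for unit-level checks, 10⁵ per
cell for the campaign-level ordering tests (where the smallest asserted
difference exceeds three combined standard errors) and 10⁶ for the
semi-infinite benchmark (1% band). These sizes were chosen so the full
suite settles each assertion with comfortable statistical margin while
completing in about a minute; all of them scale up without code changes.

# Command-line interface

The package's functions are the primary interface; a thin Rscript wrapper
(`inst/scripts/diaphanosim`) exposes `simulate`, `grid`, `sweep` and
`pipeline` subcommands over YAML configurations for shell use. The
`pipeline` subcommand chains simulate → render → analyze → report and
writes an examination-report JSON bundling the metrics with patient-free
metadata. Validation of a configuration happens before any computation,
and every run writes its resolved configuration next to its outputs.

# Known limitations

* Planar slabs: no sinus-wall curvature, no voxelized anatomy, no lateral
  heterogeneity; the lateral spread of the transmitted spot is therefore
  broader than a curved bony frame would allow.
* No polarization, fluorescence or time-resolved transport.
* The zygomatic-bone preset thicknesses (26/23 mm) are used exactly as
  tabulated, although they are large for an anterior sinus wall; they
  dominate the optical thickness of the stack.
* Camera calibration, lens optics and stray light are out of scope; the
  synthetic images are radiometrically idealized.
* No diagnostic classifier is included — the package quantifies images
  but does not decide between pathologies.
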
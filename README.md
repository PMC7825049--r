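# diaphanosim

Monte Carlo simulation and image quantification for **digital
diaphanoscopy** (transillumination) of the human maxillary sinuses.

Digital diaphanoscopy shines low-intensity red (650 nm) and near-infrared
(850 nm) light through the maxillary sinuses from inside the oral cavity
and records the scattering pattern emerging through the cheek with a
camera. Pathology — mucosal swelling, cystic fluid, tumor tissue — replaces
the air in the sinus cavity with an absorbing, scattering medium and dims
the transmitted pattern; anatomy (bone thickness, subcutaneous fat, sinus
size, sex differences) modulates it. `diaphanosim` is for researchers
developing or evaluating this modality who need a forward model of the
measurement and a reproducible test bed for the image analysis.

The package provides:

* **Tissue model** — an eight-layer planar stack of the transillumination
  path (palatine mucosa, palatine bone, inner sinus mucosa, sinus cavity,
  outer sinus mucosa, zygomatic bone, hypodermis, epidermis+dermis) with
  sex-specific thicknesses and per-wavelength absorption/scattering
  coefficients μ_a, μ_s (mm⁻¹); healthy, cystic and tumor cavity variants.
* **Monte Carlo transport** — a weighted-photon (implicit-capture)
  radiative transport engine in C++: exponential free paths against
  μ_t = μ_a + μ_s, Henyey–Greenstein scattering with anisotropy g,
  unpolarized Fresnel/Snell boundaries with per-layer refractive index,
  Russian roulette, and detector-plane irradiance scoring. Runs are
  bit-reproducible for a fixed seed.
* **Simulation campaign** — the sex × pathology × wavelength condition
  grid, hypodermis-thickness sweeps and the (exactly linear) source-power
  response, with per-cell Monte Carlo standard errors.
* **Synthetic camera** — renders detector irradiance maps or a parametric
  two-sinus face phantom through a linear exposure/gain/offset model with
  configurable bit depth and optional Poisson+Gaussian noise.
* **Image metrics** — transmitted-light percentage over sinus regions of
  interest, pseudo-color intensity segmentation, a left–right asymmetry
  index |p_L − p_R| / (p_L + p_R), and exposure-robustness analysis.

## Worked example

Build the healthy female stack at 850 nm, push 50 000 photon packets of an
8 mW source through it, and sweep the hypodermis thickness:

```r
library(diaphanosim)

st <- build_stack("female", "none", 850)
st
#> <tissue_stack> female, pathology=none, 850 nm (literal scattering)
#>   8 layers, total thickness 40.80 mm, interaction depth 74.68
#>                name           tissue thickness  mu_a  mu_s   g   n
#>     palatine_mucosa           mucosa       3.0 0.075 1.200 0.9 1.4
#>       palatine_bone             bone       3.1 0.007 2.113 0.9 1.4
#>  sinus_mucosa_inner           mucosa       0.5 0.075 1.200 0.9 1.4
#>        sinus_cavity              air       6.2 0.000 0.000 0.0 1.0
#>  sinus_mucosa_outer           mucosa       0.5 0.075 1.200 0.9 1.4
#>      zygomatic_bone             bone      23.0 0.007 2.113 0.9 1.4
#>          hypodermis       hypodermis       3.0 0.100 2.700 0.9 1.4
#>    epidermis_dermis epidermis_dermis       1.5 0.200 3.700 0.9 1.4

res <- run_simulation(st, source_spec(850, power_mW = 8),
                      n_photons = 50000, seed = 1)
res
#> <transport_result> 50000 packets, seed 1, 8 mW launched
#>   reflected   1.537 mW
#>   absorbed    6.405 mW
#>   transmitted 0.05757 mW (aperture flux 0.03002 +/- 0.00089 mW)
#>   conservation error 4.36e-07
```

Of the 8 mW launched, ~1.5 mW backscatters into the oral cavity, ~6.4 mW
is absorbed along the path (mostly in bone and hypodermis), and ~0.06 mW
emerges through the cheek, of which ~0.03 mW lands inside the 40 × 40 mm
detector aperture; the tallies close to the launched power to within
5 × 10⁻⁷ relative. The absorbing hypodermis drives the detected flux
down steeply as it thickens:

```r
sw <- hypodermis_sweep(condition_spec("female", "none", 850),
                       thicknesses = 1:5, n_photons = 20000, seed = 1)
sw[, c("hypodermis_mm", "flux_mW", "flux_se_mW")]
#>  hypodermis_mm    flux_mW   flux_se_mW
#>              1 0.05219501 0.0020918435
#>              2 0.03710457 0.0016239927
#>              3 0.02924357 0.0014047595
#>              4 0.02152437 0.0010846300
#>              5 0.01434317 0.0007912152
```

Synthetic images and their quantification:

```r
ph  <- render_phantom(phantom_spec())        # two-sinus face phantom
roi <- roi_ellipse(ph$image, c(48, 60), c(22, 16), "left")
percent_transmitted(ph$image, roi)           # % of full scale
seg <- pseudocolor_segmentation(ph$image, n_bands = 8)
```

A thin command-line wrapper ships in `inst/scripts/diaphanosim` with
`simulate`, `pipeline`, `grid` and `sweep` subcommands driven by YAML
configuration files.

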
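# Shared fixtures and independent oracle tables.

# Independently transcribed optical coefficients (mm^-1) and per-sex layer
# thicknesses (mm), used for spreadsheet-style oracle sums so the tests do
# not route the expected values through the package's own preset loader.
oracle_mu <- list(
  mucosa          = list(`650` = c(mu_a = 0.05,   mu_s = 0.8),
                         `850` = c(mu_a = 0.075,  mu_s = 1.2)),
  bone            = list(`650` = c(mu_a = 0.011,  mu_s = 1.873),
                         `850` = c(mu_a = 0.007,  mu_s = 2.113)),
  cystic_fluid    = list(`650` = c(mu_a = 0.022,  mu_s = 1.34),
                         `850` = c(mu_a = 0.027,  mu_s = 0.95)),
  tumor           = list(`650` = c(mu_a = 0.0391, mu_s = 2.17),
                         `850` = c(mu_a = 0.0522, mu_s = 2.67)),
  hypodermis      = list(`650` = c(mu_a = 0.18,   mu_s = 2.0),
                         `850` = c(mu_a = 0.1,    mu_s = 2.7)),
  epidermis_dermis = list(`650` = c(mu_a = 0.17,  mu_s = 3.0),
                          `850` = c(mu_a = 0.2,   mu_s = 3.7)))

oracle_thickness <- list(
  male = c(palatine_mucosa = 2, palatine_bone = 3.1,
           sinus_mucosa_inner = 0.5, sinus_cavity = 6.7,
           sinus_mucosa_outer = 0.5, zygomatic_bone = 26,
           hypodermis = 3, epidermis_dermis = 2.25),
  female = c(palatine_mucosa = 3, palatine_bone = 3.1,
             sinus_mucosa_inner = 0.5, sinus_cavity = 6.2,
             sinus_mucosa_outer = 0.5, zygomatic_bone = 23,
             hypodermis = 3, epidermis_dermis = 1.5))

oracle_layer_tissue <- c(
  palatine_mucosa = "mucosa", palatine_bone = "bone",
  sinus_mucosa_inner = "mucosa", sinus_cavity = "air",
  sinus_mucosa_outer = "mucosa", zygomatic_bone = "bone",
  hypodermis = "hypodermis", epidermis_dermis = "epidermis_dermis")

# Sum of coef * thickness over the healthy stack, computed from the oracle
# tables alone (air contributes 0).
oracle_sum <- function(sex, wavelength, coef = "mu_a") {
  th <- oracle_thickness[[sex]]
  s <- 0
  for (nm in names(th)) {
    tis <- oracle_layer_tissue[[nm]]
    if (tis == "air") next
    s <- s + oracle_mu[[tis]][[as.character(wavelength)]][[coef]] * th[[nm]]
  }
  s
}

all_layer_names <- names(oracle_thickness$male)

# overrides disabling scattering and matching all indices to air
no_scatter_overrides <- function() {
  ov <- lapply(all_layer_names, function(x) list(mu_s = 0, n = 1))
  names(ov) <- all_layer_names
  ov
}

# a single homogeneous slab masquerading as a stack: every other layer has
# zero thickness
single_slab <- function(mu_a, mu_s, g = 0, n = 1, thickness = 10,
                        wavelength = 650) {
  zero <- setNames(rep(0, length(all_layer_names)), all_layer_names)
  zero["zygomatic_bone"] <- thickness
  build_stack("male", "none", wavelength, thickness_overrides = zero,
              prop_overrides = list(zygomatic_bone =
                list(mu_a = mu_a, mu_s = mu_s, g = g, n = n)))
}

# wide-open single-bin detector catching every transmitted packet
open_detector <- function() detector_config(1, 1, 1e6, 1e6)

# a small asymmetric two-sinus phantom used across image tests
demo_phantom <- function(left_peak = 0.8, right_peak = 0.4,
                         inclusion = NULL) {
  phantom_spec(width = 120, height = 90,
               left = list(center = c(35, 45), axes = c(16, 12),
                           peak = left_peak),
               right = list(center = c(85, 45), axes = c(16, 12),
                            peak = right_peak),
               background = 0.05, inclusion = inclusion)
}
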
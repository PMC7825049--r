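# Layered maxillary-sinus tissue presets for digital diaphanoscopy simulation.
#
# Schema:
#   optical_properties: <tissue>:
#     g: scattering anisotropy (dimensionless, -1..1)
#     n: refractive index (dimensionless, >= 1)
#     wavelengths: "<nm>": {mu_a: absorption mm^-1, mu_s: scattering mm^-1}
#   layers: ordered source -> detector; thickness_mm per sex.
#
# mu_a / mu_s are literature values for each tissue at 650 and 850 nm.
# g and n are not part of the published coefficient table; 0.9 / 1.4 are
# standard soft-tissue and bone defaults, overridable per layer.
optical_properties:
  mucosa:
    g: 0.9
    "n": 1.4
    wavelengths:
      "650": {mu_a: 0.05,  mu_s: 0.8}
      "850": {mu_a: 0.075, mu_s: 1.2}
  bone:
    g: 0.9
    "n": 1.4
    wavelengths:
      "650": {mu_a: 0.011, mu_s: 1.873}
      "850": {mu_a: 0.007, mu_s: 2.113}
  cystic_fluid:
    g: 0.9
    "n": 1.4
    wavelengths:
      "650": {mu_a: 0.022, mu_s: 1.34}
      "850": {mu_a: 0.027, mu_s: 0.95}
  tumor:
    g: 0.9
    "n": 1.4
    wavelengths:
      "650": {mu_a: 0.0391, mu_s: 2.17}
      "850": {mu_a: 0.0522, mu_s: 2.67}
  hypodermis:
    g: 0.9
    "n": 1.4
    wavelengths:
      "650": {mu_a: 0.18, mu_s: 2.0}
      "850": {mu_a: 0.1,  mu_s: 2.7}
  epidermis_dermis:
    g: 0.9
    "n": 1.4
    wavelengths:
      "650": {mu_a: 0.17, mu_s: 3.0}
      "850": {mu_a: 0.2,  mu_s: 3.7}
  air:
    g: 0.0
    "n": 1.0
    wavelengths:
      "650": {mu_a: 0.0, mu_s: 0.0}
      "850": {mu_a: 0.0, mu_s: 0.0}

# Epidermis+dermis is published as a range (1.5-3 mm male, 1-2 mm female);
# the midpoint is used as the preset default.
layers:
  - name: palatine_mucosa
    tissue: mucosa
    thickness_mm: {male: 2.0, female: 3.0}
  - name: palatine_bone
    tissue: bone
    thickness_mm: {male: 3.1, female: 3.1}
  - name: sinus_mucosa_inner
    tissue: mucosa
    thickness_mm: {male: 0.5, female: 0.5}
  - name: sinus_cavity
    tissue: air
    thickness_mm: {male: 6.7, female: 6.2}
  - name: sinus_mucosa_outer
    tissue: mucosa
    thickness_mm: {male: 0.5, female: 0.5}
  - name: zygomatic_bone
    tissue: bone
    thickness_mm: {male: 26.0, female: 23.0}
  - name: hypodermis
    tissue: hypodermis
    thickness_mm: {male: 3.0, female: 3.0}
  - name: epidermis_dermis
    tissue: epidermis_dermis
    thickness_mm: {male: 2.25, female: 1.5}
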
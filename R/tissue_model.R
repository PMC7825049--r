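#' Optical properties of one tissue at one wavelength
#'
#' Bundles the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index of a homogeneous tissue.
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param mu_s Scattering coefficient, mm^-1 (>= 0).
#' @param g Scattering anisotropy, the mean cosine of the single-scattering
#'   deflection angle, in \[-1, 1\]. 0.9 is the usual soft-tissue default.
#' @param n Refractive index (>= 1).
#' @return An object of class `optical_properties` (a named list).
#' @export
optical_properties <- function(mu_a, mu_s, g = 0.9, n = 1.4) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(mu_s), length(mu_s) == 1L, is.finite(mu_s),
            is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (g < -1 || g > 1) stop("g must lie in [-1, 1]")
  if (n < 1) stop("n must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' Load the packaged tissue presets
#'
#' Reads (and caches) the YAML file shipping the layer order, per-sex layer
#' thicknesses and per-wavelength optical coefficients of the
#' maxillary-sinus model.
#'
#' @param path Optional path to an alternative preset file with the same
#'   schema.
#' @return A list with elements `optical_properties` and `layers`.
#' @export
tissue_presets <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.diaphanosim_env$presets)) return(.diaphanosim_env$presets)
    path <- system.file("extdata", "tissue_presets.yaml",
                        package = "diaphanosim", mustWork = TRUE)
    .diaphanosim_env$presets <- yaml::read_yaml(path)
    return(.diaphanosim_env$presets)
  }
  yaml::read_yaml(path)
}

.tissue_props <- function(presets, tissue, wavelength) {
  op <- presets$optical_properties[[tissue]]
  if (is.null(op)) stop("unknown tissue: ", tissue)
  wl <- op$wavelengths[[as.character(wavelength)]]
  if (is.null(wl)) stop("tissue '", tissue, "' has no coefficients at ",
                        wavelength, " nm")
  optical_properties(wl$mu_a, wl$mu_s, op$g, op$n)
}

#' Build the layered maxillary-sinus tissue stack
#'
#' Constructs the eight-layer planar model of the transillumination path
#' through the maxillary sinus, from the light-source (oral cavity) side to
#' the detector (cheek skin) side: palatine-bone mucosa, palatine bone,
#' inner sinus mucosa, sinus cavity (air when healthy, otherwise filled by
#' the pathological medium), outer sinus mucosa, zygomatic bone, hypodermis
#' and epidermis+dermis. Layer thicknesses are sex-specific presets;
#' absorption and scattering coefficients are wavelength-specific presets.
#'
#' Two readings of the preset scattering coefficients are supported.
#' `scattering = "literal"` treats them as full scattering coefficients
#' with anisotropic (g = 0.9) deflection. `scattering = "reduced"` treats
#' them as reduced coefficients mu_s' and runs the equivalent isotropic
#' (g = 0) transport.
#'
#' @param sex `"male"` or `"female"`.
#' @param pathology `"none"`, `"cyst"` or `"tumor"`. A pathology replaces
#'   the air in the sinus cavity with the corresponding medium; see
#'   `fill_fraction`.
#' @param wavelength Probing wavelength in nm; presets cover 650 and 850.
#' @param thickness_overrides Optional named numeric vector of layer
#'   thickness replacements in mm, e.g. `c(hypodermis = 5)`.
#' @param prop_overrides Optional named list of per-layer optical-property
#'   replacements; each element is a list with any of `mu_a`, `mu_s`, `g`,
#'   `n`, e.g. `list(zygomatic_bone = list(mu_s = 0))`.
#' @param scattering `"literal"` or `"reduced"` (see Details).
#' @param fill_fraction Fraction (0..1) of the sinus-cavity depth occupied
#'   by the pathological medium, adjacent to the inner mucosa; the rest
#'   stays air. Default 1 (whole cavity). Values in (0, 1) add a ninth,
#'   residual-air layer.
#' @param presets Preset list as returned by [tissue_presets()].
#' @return A `tissue_stack`: a list with a `layers` data frame (columns
#'   `name`, `tissue`, `thickness`, `mu_a`, `mu_s`, `g`, `n`) plus the
#'   construction parameters.
#' @examples
#' st <- build_stack("male", "none", 850)
#' subset(st$layers, name == "hypodermis")
#' @export
build_stack <- function(sex, pathology = "none", wavelength,
                        thickness_overrides = NULL, prop_overrides = NULL,
                        scattering = c("literal", "reduced"),
                        fill_fraction = 1, presets = tissue_presets()) {
  sex <- match.arg(sex, c("male", "female"))
  pathology <- match.arg(pathology, c("none", "cyst", "tumor"))
  scattering <- match.arg(scattering)
  if (!wavelength %in% c(650, 850))
    stop("wavelength must be 650 or 850 nm")
  if (!is.numeric(fill_fraction) || fill_fraction < 0 || fill_fraction > 1)
    stop("fill_fraction must lie in [0, 1]")

  rows <- lapply(presets$layers, function(ly) {
    tissue <- ly$tissue
    data.frame(name = ly$name, tissue = tissue,
               thickness = ly$thickness_mm[[sex]],
               stringsAsFactors = FALSE)
  })
  layers <- do.call(rbind, rows)

  # pathology fills the cavity from the inner-mucosa side
  if (pathology != "none") {
    medium <- c(cyst = "cystic_fluid", tumor = "tumor")[[pathology]]
    i <- which(layers$name == "sinus_cavity")
    depth <- layers$thickness[i]
    if (fill_fraction >= 1) {
      layers$tissue[i] <- medium
    } else if (fill_fraction > 0) {
      filled <- layers[i, ]
      filled$name <- "sinus_pathology"
      filled$tissue <- medium
      filled$thickness <- depth * fill_fraction
      air <- layers[i, ]
      air$thickness <- depth * (1 - fill_fraction)
      layers <- rbind(layers[seq_len(i - 1L), ], filled, air,
                      layers[seq(i + 1L, nrow(layers)), ])
      rownames(layers) <- NULL
    }
  }

  props <- lapply(layers$tissue, .tissue_props,
                  presets = presets, wavelength = wavelength)
  layers$mu_a <- vapply(props, `[[`, numeric(1), "mu_a")
  layers$mu_s <- vapply(props, `[[`, numeric(1), "mu_s")
  layers$g <- vapply(props, `[[`, numeric(1), "g")
  layers$n <- vapply(props, `[[`, numeric(1), "n")
  if (scattering == "reduced") layers$g <- 0

  if (!is.null(thickness_overrides)) {
    if (is.null(names(thickness_overrides)) ||
        any(names(thickness_overrides) == ""))
      stop("thickness_overrides must be a named vector")
    for (nm in names(thickness_overrides)) {
      i <- which(layers$name == nm)
      if (length(i) != 1L) stop("unknown layer in thickness_overrides: ", nm)
      t_mm <- thickness_overrides[[nm]]
      if (!is.finite(t_mm) || t_mm < 0)
        stop("override thickness for '", nm, "' must be >= 0")
      layers$thickness[i] <- t_mm
    }
  }
  if (!is.null(prop_overrides)) {
    for (nm in names(prop_overrides)) {
      i <- which(layers$name == nm)
      if (length(i) != 1L) stop("unknown layer in prop_overrides: ", nm)
      ov <- prop_overrides[[nm]]
      cur <- optical_properties(
        if (is.null(ov$mu_a)) layers$mu_a[i] else ov$mu_a,
        if (is.null(ov$mu_s)) layers$mu_s[i] else ov$mu_s,
        if (is.null(ov$g)) layers$g[i] else ov$g,
        if (is.null(ov$n)) layers$n[i] else ov$n)
      layers$mu_a[i] <- cur$mu_a; layers$mu_s[i] <- cur$mu_s
      layers$g[i] <- cur$g; layers$n[i] <- cur$n
    }
  }

  structure(list(layers = layers, sex = sex, pathology = pathology,
                 wavelength = wavelength, scattering = scattering,
                 fill_fraction = fill_fraction),
            class = "tissue_stack")
}

#' Replace the hypodermis thickness of a stack
#'
#' The hypodermis (subcutaneous fat) is the model's key anatomical
#' covariate: its strong absorption makes the detected flux sensitive to
#' its thickness. All other layers are untouched. A zero thickness keeps
#' the layer entry but the transport engine treats it as a no-op interface.
#'
#' @param stack A `tissue_stack`.
#' @param t_mm New hypodermis thickness in mm (>= 0).
#' @return The modified `tissue_stack`.
#' @export
set_hypodermis_thickness <- function(stack, t_mm) {
  set_layer_thickness(stack, "hypodermis", t_mm)
}

#' Replace the thickness of a named layer
#'
#' @param stack A `tissue_stack`.
#' @param layer Layer name (see `stack$layers$name`).
#' @param t_mm New thickness in mm (>= 0).
#' @return The modified `tissue_stack`.
#' @export
set_layer_thickness <- function(stack, layer, t_mm) {
  stopifnot(inherits(stack, "tissue_stack"))
  if (!is.numeric(t_mm) || length(t_mm) != 1L || !is.finite(t_mm) || t_mm < 0)
    stop("thickness must be a single number >= 0")
  i <- which(stack$layers$name == layer)
  if (length(i) != 1L) stop("unknown layer: ", layer)
  stack$layers$thickness[i] <- t_mm
  stack
}

#' Total interaction depth of a stack
#'
#' The dimensionless optical thickness for interaction of any kind:
#' sum over layers of (mu_a + mu_s) x thickness. Air contributes zero.
#' `exp(-total_interaction_depth(stack))` is the ballistic (unscattered,
#' unabsorbed) transmission, see [ballistic_transmission()].
#'
#' @param stack A `tissue_stack`.
#' @return A single non-negative number.
#' @export
total_interaction_depth <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  ly <- stack$layers
  if (nrow(ly) == 0L) return(0)
  sum((ly$mu_a + ly$mu_s) * ly$thickness)
}

#' @export
print.tissue_stack <- function(x, ...) {
  cat(sprintf("<tissue_stack> %s, pathology=%s, %d nm (%s scattering)\n",
              x$sex, x$pathology, x$wavelength, x$scattering))
  cat(sprintf("  %d layers, total thickness %.2f mm, interaction depth %.2f\n",
              nrow(x$layers), sum(x$layers$thickness),
              total_interaction_depth(x)))
  print(x$layers, row.names = FALSE)
  invisible(x)
}
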
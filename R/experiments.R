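#' Simulation condition
#'
#' @param sex `"male"` or `"female"`.
#' @param pathology `"none"`, `"cyst"` or `"tumor"`.
#' @param wavelength 650 or 850 (nm).
#' @param hypodermis_mm Optional hypodermis-thickness override in mm;
#'   `NULL` keeps the preset (3 mm).
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(sex, pathology = "none", wavelength,
                           hypodermis_mm = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  pathology <- match.arg(pathology, c("none", "cyst", "tumor"))
  if (!wavelength %in% c(650, 850)) stop("wavelength must be 650 or 850 nm")
  if (!is.null(hypodermis_mm) && (!is.numeric(hypodermis_mm) ||
                                  hypodermis_mm < 0))
    stop("hypodermis_mm must be >= 0")
  structure(list(sex = sex, pathology = pathology, wavelength = wavelength,
                 hypodermis_mm = hypodermis_mm),
            class = "condition_spec")
}

# Deterministic, order-independent sub-seed for one condition: a small
# polynomial hash of the condition label folded into the run seed, kept
# below 2^31 so it stays a valid integer seed.
.condition_seed <- function(seed, cond) {
  label <- paste(cond$sex, cond$pathology, cond$wavelength,
                 if (is.null(cond$hypodermis_mm)) "preset"
                 else format(cond$hypodermis_mm), sep = "|")
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 2147483647
  (as.double(seed) * 2654435761 + h) %% 2147483647
}

.stack_for <- function(cond, ...) {
  ov <- if (is.null(cond$hypodermis_mm)) NULL else
    c(hypodermis = cond$hypodermis_mm)
  build_stack(cond$sex, cond$pathology, cond$wavelength,
              thickness_overrides = ov, ...)
}

.run_condition <- function(cond, n_photons, seed, power_mW, detector,
                           options, stack_args = list()) {
  st <- do.call(.stack_for, c(list(cond), stack_args))
  sub <- .condition_seed(seed, cond)
  res <- run_simulation(st, source_spec(cond$wavelength, power_mW),
                        n_photons = n_photons, seed = sub,
                        detector = detector, options = options)
  data.frame(sex = cond$sex, pathology = cond$pathology,
             wavelength = cond$wavelength,
             hypodermis_mm = if (is.null(cond$hypodermis_mm))
               st$layers$thickness[st$layers$name == "hypodermis"]
               else cond$hypodermis_mm,
             flux_mW = res$flux_mW, flux_se_mW = res$flux_se_mW,
             transmitted_mW = res$transmitted_mW,
             reflected_mW = res$reflected_mW, seed = sub,
             n_photons = n_photons, stringsAsFactors = FALSE)
}

#' Run the sex x pathology x wavelength condition grid
#'
#' One simulation per factor combination, each with a sub-seed derived
#' from the condition itself (not from execution order), so the grid is
#' invariant to row ordering and to subsetting of factors.
#'
#' @param sexes,pathologies,wavelengths Factor levels to cross.
#' @param n_photons Packets per cell.
#' @param seed Run seed.
#' @param power_mW Source power per cell, mW.
#' @param detector,options Passed to [run_simulation()].
#' @param stack_args Extra arguments forwarded to [build_stack()] (e.g.
#'   `scattering = "reduced"`).
#' @return Data frame with one row per condition: the condition factors,
#'   the detector-aperture flux (`flux_mW`), its Monte Carlo standard
#'   error, total transmitted and reflected power, and the sub-seed used.
#' @export
run_condition_grid <- function(sexes = c("male", "female"),
                               pathologies = c("none", "cyst", "tumor"),
                               wavelengths = c(650, 850),
                               n_photons = 10000, seed = 1, power_mW = 8,
                               detector = detector_config(),
                               options = transport_options(),
                               stack_args = list()) {
  if (!length(sexes) || !length(pathologies) || !length(wavelengths))
    stop("factor lists must be nonempty")
  grid <- expand.grid(sex = sexes, pathology = pathologies,
                      wavelength = wavelengths, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cond <- condition_spec(grid$sex[i], grid$pathology[i],
                           grid$wavelength[i])
    tryCatch(
      .run_condition(cond, n_photons, seed, power_mW, detector, options,
                     stack_args),
      error = function(e) stop("condition [", grid$sex[i], ", ",
                               grid$pathology[i], ", ", grid$wavelength[i],
                               " nm] failed: ", conditionMessage(e),
                               call. = FALSE))
  })
  do.call(rbind, out)
}

#' Sweep the hypodermis thickness
#'
#' Re-runs one condition over a list of hypodermis thicknesses, all else
#' fixed; the default grid 1-5 mm brackets the 3 mm preset.
#'
#' @param condition A `condition_spec` (its `hypodermis_mm` is ignored).
#' @param thicknesses Thicknesses in mm (>= 0, at least 2 values).
#' @inheritParams run_condition_grid
#' @return Data frame as in [run_condition_grid()], one row per thickness.
#' @export
hypodermis_sweep <- function(condition, thicknesses = 1:5,
                             n_photons = 10000, seed = 1, power_mW = 8,
                             detector = detector_config(),
                             options = transport_options(),
                             stack_args = list()) {
  stopifnot(inherits(condition, "condition_spec"))
  if (length(thicknesses) < 2 || any(thicknesses < 0))
    stop("thicknesses must be >= 0 and supply at least 2 values")
  out <- lapply(thicknesses, function(t_mm) {
    cond <- condition_spec(condition$sex, condition$pathology,
                           condition$wavelength, hypodermis_mm = t_mm)
    .run_condition(cond, n_photons, seed, power_mW, detector, options,
                   stack_args)
  })
  do.call(rbind, out)
}

#' Detected flux as a function of source power
#'
#' Monte Carlo weights are relative, so flux responds exactly linearly to
#' the source power: one 8 mW baseline simulation is rescaled to each
#' requested power. The default power list mirrors the applicator's
#' 0-750 mW range in 50 mW increments.
#'
#' @param condition A `condition_spec`.
#' @param powers_mW Source powers in mW (>= 0).
#' @inheritParams run_condition_grid
#' @return Data frame with `power_mW`, `flux_mW`, `flux_se_mW`.
#' @export
source_power_response <- function(condition, powers_mW = seq(0, 750, 50),
                                  n_photons = 10000, seed = 1,
                                  detector = detector_config(),
                                  options = transport_options(),
                                  stack_args = list()) {
  stopifnot(inherits(condition, "condition_spec"))
  if (any(powers_mW < 0)) stop("powers must be >= 0")
  base <- .run_condition(condition, n_photons, seed, power_mW = 8,
                         detector = detector, options = options,
                         stack_args = stack_args)
  data.frame(power_mW = powers_mW,
             flux_mW = base$flux_mW * powers_mW / 8,
             flux_se_mW = base$flux_se_mW * powers_mW / 8)
}

#' Write a sweep/grid result as tidy CSV plus a JSON summary
#'
#' @param result Data frame from [run_condition_grid()] or
#'   [hypodermis_sweep()].
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(result, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(result, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
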
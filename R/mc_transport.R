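#' Light-source specification
#'
#' @param wavelength Wavelength in nm (informational; the optical
#'   coefficients come from the tissue stack).
#' @param power_mW Source radiant power in mW (> 0). The simulation default
#'   of 8 mW matches the modelled probing source.
#' @param beam `"pencil"` (collimated, the validation default), `"cone"`
#'   (uniform within `half_angle_deg`), or `"array"` (several offset
#'   emitters, cycled packet-by-packet, emulating the multi-LED
#'   applicator).
#' @param half_angle_deg Cone half-angle in degrees, `0 <= x < 90`.
#' @param entry_points Two-column matrix of (x, y) entry points in mm on
#'   the source face; one row per emitter (one row for pencil/cone).
#' @return A `source_spec` object.
#' @export
source_spec <- function(wavelength, power_mW = 8,
                        beam = c("pencil", "cone", "array"),
                        half_angle_deg = 0,
                        entry_points = matrix(0, 1, 2)) {
  beam <- match.arg(beam)
  stopifnot(is.numeric(power_mW), length(power_mW) == 1L)
  if (!is.finite(power_mW) || power_mW <= 0) stop("power_mW must be > 0")
  if (half_angle_deg < 0 || half_angle_deg >= 90)
    stop("half_angle_deg must lie in [0, 90)")
  entry_points <- as.matrix(entry_points)
  if (ncol(entry_points) != 2L) stop("entry_points needs two columns (x, y)")
  if (beam != "cone") half_angle_deg <- if (beam == "pencil") 0 else half_angle_deg
  structure(list(wavelength = wavelength, power_mW = power_mW, beam = beam,
                 half_angle_deg = half_angle_deg,
                 entry_points = entry_points),
            class = "source_spec")
}

#' Detector-plane binning configuration
#'
#' The detector plane sits at the outer skin surface; transmitted packets
#' are binned on a regular grid centred on the beam axis. Weight exiting
#' outside the aperture is tallied separately so energy bookkeeping stays
#' closed.
#'
#' @param nx,ny Bin counts.
#' @param width_mm,height_mm Aperture extent in mm.
#' @return A `detector_config` object.
#' @export
detector_config <- function(nx = 64, ny = 64, width_mm = 40,
                            height_mm = 40) {
  stopifnot(nx >= 1, ny >= 1, width_mm > 0, height_mm > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 width_mm = width_mm, height_mm = height_mm),
            class = "detector_config")
}

#' Transport engine options
#'
#' @param roulette Use Russian roulette for low-weight packets (unbiased
#'   termination). Disabling it makes energy conservation exact to
#'   floating-point accuracy.
#' @param roulette_threshold Weight below which roulette is played.
#' @param roulette_survival Survival probability; survivors are boosted by
#'   its inverse.
#' @param n_ambient_front,n_ambient_back Refractive index of the media
#'   outside the stack on the source and detector sides.
#' @param n_paths Record full trajectories for the first `n_paths` packets
#'   (for path visualisation); 0 disables recording.
#' @param max_events Per-packet event budget guarding against non-physical
#'   configurations; exceeding it is a hard error, never silent.
#' @return A `transport_options` object.
#' @export
transport_options <- function(roulette = TRUE, roulette_threshold = 1e-4,
                              roulette_survival = 0.1,
                              n_ambient_front = 1.0, n_ambient_back = 1.0,
                              n_paths = 0, max_events = 5e6) {
  stopifnot(roulette_threshold > 0, roulette_survival > 0,
            roulette_survival <= 1, n_ambient_front >= 1,
            n_ambient_back >= 1, n_paths >= 0, max_events > 0)
  structure(list(roulette = isTRUE(roulette),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 n_ambient_front = n_ambient_front,
                 n_ambient_back = n_ambient_back,
                 n_paths = as.integer(n_paths),
                 max_events = as.integer(max_events)),
            class = "transport_options")
}

#' Sample an exponential free path
#'
#' Inverse-CDF sampling of the photon free path between interactions,
#' `-log(u)/mu_t`. A zero interaction coefficient means an infinite free
#' path: the packet propagates straight to the next boundary.
#'
#' @param mu_t Interaction coefficient mu_a + mu_s, mm^-1 (>= 0).
#' @param u Uniform(0, 1) draw(s).
#' @return Path length(s) in mm (`Inf` when `mu_t` is 0).
#' @export
sample_free_path <- function(mu_t, u) {
  stopifnot(all(mu_t >= 0), all(u > 0), all(u < 1))
  out <- -log(u) / mu_t  # recycles mu_t against u
  out[is.infinite(out) | rep_len(mu_t == 0, length(out))] <- Inf
  out
}

#' Sample a scattered direction (Henyey-Greenstein)
#'
#' Deflects `incoming` by a polar angle whose cosine follows the
#' Henyey-Greenstein distribution with anisotropy `g` (uniform on
#' \[-1, 1\] when g = 0) and a uniform azimuth.
#'
#' @param g Anisotropy in \[-1, 1\].
#' @param u1,u2 Uniform(0, 1) draws for the polar and azimuthal angles.
#' @param incoming Unit 3-vector.
#' @return New unit 3-vector.
#' @export
sample_scatter <- function(g, u1, u2, incoming) {
  stopifnot(g >= -1, g <= 1, length(incoming) == 3)
  if (abs(sum(incoming^2) - 1) > 1e-8) stop("incoming must be a unit vector")
  ct <- if (abs(g) < 1e-6) {
    2 * u1 - 1
  } else {
    tmp <- (1 - g^2) / (1 - g + 2 * g * u1)
    min(1, max(-1, (1 + g^2 - tmp^2) / (2 * g)))
  }
  st <- sqrt(max(0, 1 - ct^2))
  phi <- 2 * pi * u2
  ux <- incoming[1]; uy <- incoming[2]; uz <- incoming[3]
  if (abs(uz) > 0.99999) {
    out <- c(st * cos(phi), st * sin(phi), sign(uz) * ct)
  } else {
    den <- sqrt(1 - uz^2)
    out <- c(st * (ux * uz * cos(phi) - uy * sin(phi)) / den + ux * ct,
             st * (uy * uz * cos(phi) + ux * sin(phi)) / den + uy * ct,
             -den * st * cos(phi) + uz * ct)
  }
  out / sqrt(sum(out^2))
}

#' Unpolarized Fresnel reflectance of a planar interface
#'
#' @param n1,n2 Refractive indices on the incidence and transmission sides.
#' @param cos_i Cosine of the incidence angle (>= 0).
#' @return Reflectance in \[0, 1\]; 1 under total internal reflection.
#' @export
fresnel_reflectance <- function(n1, n2, cos_i) {
  stopifnot(n1 >= 1, n2 >= 1, cos_i >= 0, cos_i <= 1)
  if (n1 == n2) return(0)
  sin_t <- n1 / n2 * sqrt(1 - cos_i^2)
  if (sin_t >= 1) return(1)
  cos_t <- sqrt(1 - sin_t^2)
  rs <- (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
  rp <- (n1 * cos_t - n2 * cos_i) / (n1 * cos_t + n2 * cos_i)
  (rs^2 + rp^2) / 2
}

#' Stochastic Fresnel interaction at a planar interface
#'
#' With probability equal to the unpolarized Fresnel reflectance the packet
#' is specularly reflected; otherwise it is refracted by Snell's law.
#' Total internal reflection reflects with probability 1.
#'
#' @param n1,n2 Refractive indices (incidence / transmission side).
#' @param direction Unit 3-vector of propagation.
#' @param surface_normal Unit 3-vector normal to the interface.
#' @param u Uniform(0, 1) draw deciding reflection vs refraction.
#' @return List with `type` (`"reflected"` or `"refracted"`) and the new
#'   unit `direction`.
#' @export
fresnel_interaction <- function(n1, n2, direction, surface_normal, u) {
  stopifnot(length(direction) == 3, length(surface_normal) == 3,
            u >= 0, u <= 1)
  if (abs(sum(direction^2) - 1) > 1e-8 ||
      abs(sum(surface_normal^2) - 1) > 1e-8)
    stop("direction and surface_normal must be unit vectors")
  cos_i <- abs(sum(direction * surface_normal))
  R <- fresnel_reflectance(n1, n2, cos_i)
  sgn <- sign(sum(direction * surface_normal))
  if (u < R) {
    d <- direction - 2 * sgn * cos_i * surface_normal
    return(list(type = "reflected", direction = d / sqrt(sum(d^2))))
  }
  if (n1 == n2) return(list(type = "refracted", direction = direction))
  sin_t <- n1 / n2 * sqrt(max(0, 1 - cos_i^2))
  cos_t <- sqrt(max(0, 1 - sin_t^2))
  tangent <- direction - sgn * cos_i * surface_normal
  d <- n1 / n2 * tangent + sgn * cos_t * surface_normal
  list(type = "refracted", direction = d / sqrt(sum(d^2)))
}

# engine-facing view of a stack: drop zero-thickness layers, keep mapping
.engine_layers <- function(stack) {
  ly <- stack$layers
  keep <- which(ly$thickness > 0)
  list(thickness = ly$thickness[keep], mu_a = ly$mu_a[keep],
       mu_s = ly$mu_s[keep], g = ly$g[keep], n = ly$n[keep], keep = keep)
}

#' Run a Monte Carlo transport simulation
#'
#' Launches `n_photons` weighted packets through the stack and scores
#' reflected, per-layer absorbed and transmitted power, plus a
#' detector-plane irradiance map built from transmitted exit positions.
#' All tallies are scaled so the launched power equals `source$power_mW`.
#' Runs are reproducible: identical arguments give bit-identical results.
#'
#' @param stack A `tissue_stack` from [build_stack()].
#' @param source A `source_spec`.
#' @param n_photons Number of packets (>= 1).
#' @param seed Integer seed for the run's random stream.
#' @param detector A `detector_config`.
#' @param options A `transport_options`.
#' @return A `transport_result` with power tallies in mW, the detector
#'   irradiance map in mW/mm^2, the aperture flux and its Monte Carlo
#'   standard error, and (optionally) recorded photon paths.
#' @examples
#' st <- build_stack("female", "none", 650)
#' res <- run_simulation(st, source_spec(650), n_photons = 2000, seed = 1)
#' res$flux_mW
#' @export
run_simulation <- function(stack, source, n_photons, seed,
                           detector = detector_config(),
                           options = transport_options()) {
  stopifnot(inherits(stack, "tissue_stack"), inherits(source, "source_spec"),
            inherits(detector, "detector_config"),
            inherits(options, "transport_options"))
  if (!is.numeric(n_photons) || length(n_photons) != 1L || n_photons < 1)
    stop("n_photons must be >= 1")
  n_photons <- as.integer(n_photons)
  seed <- as.integer(seed) %% .Machine$integer.max

  eng <- .engine_layers(stack)
  half_angle <- if (source$beam == "cone") source$half_angle_deg * pi / 180 else 0
  raw <- cpp_run_transport(
    eng$thickness, eng$mu_a, eng$mu_s, eng$g, eng$n,
    options$n_ambient_front, options$n_ambient_back,
    source$entry_points, half_angle, n_photons, as.double(seed),
    detector$nx, detector$ny, detector$width_mm, detector$height_mm,
    options$roulette, options$roulette_threshold, options$roulette_survival,
    options$n_paths, options$max_events)

  p_per <- source$power_mW / n_photons
  absorbed <- numeric(nrow(stack$layers))
  if (length(eng$keep) > 0) absorbed[eng$keep] <- raw$absorbed * p_per
  names(absorbed) <- stack$layers$name
  bin_area <- (detector$width_mm / detector$nx) *
              (detector$height_mm / detector$ny)
  flux <- raw$transmitted_in * p_per
  # SE of the aperture flux from the per-packet transmitted-weight variance
  m1 <- raw$transmitted_in / n_photons
  m2 <- raw$transmitted_in_sq / n_photons
  flux_se <- source$power_mW * sqrt(max(0, m2 - m1^2) / n_photons)

  paths <- NULL
  if (options$n_paths > 0 && length(raw$path_id) > 0) {
    xyz <- matrix(raw$path_xyz, ncol = 3, byrow = TRUE)
    idx <- rep(seq_along(raw$path_len), raw$path_len)
    paths <- lapply(seq_along(raw$path_len), function(k) {
      m <- xyz[idx == k, , drop = FALSE]
      colnames(m) <- c("x", "y", "z")
      m
    })
  }

  structure(list(
    source_power_mW = source$power_mW, n_photons = n_photons, seed = seed,
    reflected_mW = raw$reflected * p_per,
    absorbed_mW = absorbed,
    transmitted_mW = (raw$transmitted_in + raw$transmitted_out) * p_per,
    flux_mW = flux, flux_se_mW = flux_se,
    out_of_aperture_mW = raw$transmitted_out * p_per,
    detector = list(
      irradiance = raw$detector * p_per / bin_area,
      x_centers = seq(-detector$width_mm / 2 +
                        detector$width_mm / detector$nx / 2,
                      detector$width_mm / 2 -
                        detector$width_mm / detector$nx / 2,
                      length.out = detector$nx),
      y_centers = seq(-detector$height_mm / 2 +
                        detector$height_mm / detector$ny / 2,
                      detector$height_mm / 2 -
                        detector$height_mm / detector$ny / 2,
                      length.out = detector$ny),
      bin_area_mm2 = bin_area),
    paths = paths,
    stack = stack, options = options),
    class = "transport_result")
}

#' Launch and follow a single photon packet
#'
#' Convenience wrapper around the engine for one packet, returning its
#' terminal fate and (always) its trajectory.
#'
#' @inheritParams run_simulation
#' @return List with `status` (`"reflected"`, `"transmitted"` or
#'   `"absorbed"`), the weight delivered to each tally (summing to 1),
#'   exit `x`/`y` in mm for transmitted packets, and the `path` matrix.
#' @export
propagate_packet <- function(stack, source, seed,
                             options = transport_options()) {
  options$n_paths <- 1L
  res <- run_simulation(stack, source, n_photons = 1L, seed = seed,
                        detector = detector_config(1, 1, 1e6, 1e6),
                        options = options)
  w <- function(p) p / res$source_power_mW
  status <- if (res$transmitted_mW > 0) "transmitted"
            else if (res$reflected_mW > 0) "reflected" else "absorbed"
  path <- res$paths[[1]]
  out <- list(status = status,
              reflected_weight = w(res$reflected_mW),
              absorbed_weight = sum(w(res$absorbed_mW)),
              transmitted_weight = w(res$transmitted_mW),
              path = path)
  if (status == "transmitted") {
    out$x <- path[nrow(path), "x"]; out$y <- path[nrow(path), "y"]
  }
  out
}

#' Ballistic (unscattered) transmission of a stack
#'
#' The fraction of collimated light that crosses the whole stack without a
#' single interaction: `exp(-sum((mu_a + mu_s) * thickness))`. Used as an
#' analytic oracle against collimated-detection tallies.
#'
#' @param stack A `tissue_stack`.
#' @return A number in (0, 1\].
#' @export
ballistic_transmission <- function(stack) {
  exp(-total_interaction_depth(stack))
}

#' Relative energy-conservation error of a run
#'
#' `|launched - (reflected + absorbed + transmitted)| / launched`; zero to
#' floating-point accuracy when roulette is off, and below ~1e-3 at 1e4+
#' packets with roulette on.
#'
#' @param result A `transport_result`.
#' @return A single non-negative number.
#' @export
conservation_error <- function(result) {
  stopifnot(inherits(result, "transport_result"))
  got <- result$reflected_mW + sum(result$absorbed_mW) + result$transmitted_mW
  abs(result$source_power_mW - got) / result$source_power_mW
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("<transport_result> %d packets, seed %d, %.3g mW launched\n",
              x$n_photons, x$seed, x$source_power_mW))
  cat(sprintf("  reflected   %.4g mW\n  absorbed    %.4g mW\n", x$reflected_mW,
              sum(x$absorbed_mW)))
  cat(sprintf("  transmitted %.4g mW (aperture flux %.4g +/- %.2g mW)\n",
              x$transmitted_mW, x$flux_mW, x$flux_se_mW))
  cat(sprintf("  conservation error %.3g\n", conservation_error(x)))
  invisible(x)
}
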
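#' Camera configuration for synthetic image rendering
#'
#' Linear radiometric model: `counts = gain * irradiance * exposure +
#' offset (+ noise)`, rounded and clipped to the bit depth. The 20.7 ms
#' default exposure is the working point used for image analysis; the
#' camera's true calibration is unknown, so `gain` and `offset` are free
#' parameters (see [auto_gain()]).
#'
#' @param exposure_ms Exposure time in ms (>= 0); images were acquired in
#'   the 0-40 ms range.
#' @param gain Counts per (mW/mm^2 x ms) (> 0).
#' @param offset Dark offset in counts.
#' @param bit_depth 8, 10, 12 or 16.
#' @param noise `"none"` (default, deterministic), `"gaussian"` (additive
#'   read noise) or `"poisson_gaussian"` (shot noise on the signal counts
#'   plus read noise).
#' @param noise_sd Gaussian read-noise standard deviation in counts.
#' @return A `camera_config` object.
#' @export
camera_config <- function(exposure_ms = 20.7, gain = 1, offset = 0,
                          bit_depth = 8,
                          noise = c("none", "gaussian", "poisson_gaussian"),
                          noise_sd = 1) {
  noise <- match.arg(noise)
  if (!is.numeric(exposure_ms) || exposure_ms < 0)
    stop("exposure_ms must be >= 0")
  if (!is.numeric(gain) || gain <= 0) stop("gain must be > 0")
  if (!bit_depth %in% c(8, 10, 12, 16))
    stop("bit_depth must be one of 8, 10, 12, 16")
  structure(list(exposure_ms = exposure_ms, gain = gain, offset = offset,
                 bit_depth = as.integer(bit_depth), noise = noise,
                 noise_sd = noise_sd),
            class = "camera_config")
}

#' Full-scale count of a camera
#' @param camera A `camera_config`.
#' @return `2^bit_depth - 1`.
#' @export
full_scale <- function(camera) 2^camera$bit_depth - 1

#' Gain mapping a given irradiance map to a target fraction of full scale
#'
#' Chooses the gain so the peak of `irradiance` lands at
#' `target * full_scale` at the camera's exposure; the shipped default
#' target (0.8) keeps the simulated peak well below saturation.
#'
#' @param irradiance Non-negative matrix, mW/mm^2.
#' @param camera A `camera_config`.
#' @param target Fraction of full scale for the peak (0..1).
#' @return The gain (counts per mW/mm^2/ms).
#' @export
auto_gain <- function(irradiance, camera, target = 0.8) {
  pk <- max(irradiance)
  if (pk <= 0 || camera$exposure_ms <= 0)
    stop("auto_gain needs a positive peak irradiance and exposure")
  target * (full_scale(camera) - camera$offset) / (pk * camera$exposure_ms)
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.quantize <- function(counts, camera) {
  px <- round(counts)
  px[px < 0] <- 0
  fs <- full_scale(camera)
  px[px > fs] <- fs
  storage.mode(px) <- "integer"
  px
}

.apply_noise <- function(counts, camera) {
  if (camera$noise == "none") return(counts)
  if (camera$noise == "gaussian")
    return(counts + rnorm(length(counts), 0, camera$noise_sd))
  signal <- pmax(0, counts - camera$offset)
  camera$offset + rpois(length(signal), signal) +
    rnorm(length(signal), 0, camera$noise_sd)
}

#' Render a camera image from a detector irradiance map
#'
#' @param irradiance Non-negative matrix of irradiance, mW/mm^2 (e.g.
#'   `result$detector$irradiance` from [run_simulation()]).
#' @param camera A `camera_config`.
#' @param seed Seed for the noise draws; required when noise is on.
#' @return A `sinus_image`: integer pixel matrix in
#'   `[0, 2^bit_depth - 1]` with the camera attached as an attribute.
#' @export
render_image <- function(irradiance, camera = camera_config(),
                         seed = NULL) {
  irradiance <- as.matrix(irradiance)
  if (any(!is.finite(irradiance)) || any(irradiance < 0))
    stop("irradiance must be finite and non-negative")
  counts <- camera$gain * irradiance * camera$exposure_ms + camera$offset
  if (camera$noise != "none") {
    if (is.null(seed)) stop("seed is required when noise is enabled")
    counts <- .with_seed(seed, {
      matrix(.apply_noise(counts, camera), nrow(counts), ncol(counts))
    })
  }
  structure(.quantize(counts, camera),
            camera = camera, provenance = "simulated",
            class = c("sinus_image", "matrix", "array"))
}

#' Two-sinus face phantom specification
#'
#' A parametric stand-in for a registered transillumination image: a dim
#' background with two elliptical bright regions (the transilluminated
#' left and right sinuses), optionally containing a darker elliptical
#' inclusion mimicking a cyst. Intensities are fractions of full scale in
#' the continuous (pre-quantization) image.
#'
#' @param width,height Image size in pixels.
#' @param left,right Lists with `center` (x, y pixels), `axes` (semi-axes
#'   in pixels) and `peak` (intensity fraction in \[0, 1\]).
#' @param background Background intensity fraction.
#' @param inclusion Optional list with `side` (`"left"`/`"right"`),
#'   `center`, `axes` and `level` (intensity fraction within the
#'   inclusion).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(width = 160, height = 120,
                         left = list(center = c(48, 60), axes = c(22, 16),
                                     peak = 0.6),
                         right = list(center = c(112, 60), axes = c(22, 16),
                                      peak = 0.6),
                         background = 0.05, inclusion = NULL) {
  chk <- function(r, nm) {
    if (r$peak < 0 || r$peak > 1) stop(nm, " peak must lie in [0, 1]")
    if (r$center[1] - r$axes[1] < 1 || r$center[1] + r$axes[1] > width ||
        r$center[2] - r$axes[2] < 1 || r$center[2] + r$axes[2] > height)
      stop(nm, " region must lie within the image bounds")
  }
  chk(left, "left"); chk(right, "right")
  if (background < 0 || background > 1)
    stop("background must lie in [0, 1]")
  spec <- structure(list(width = as.integer(width),
                         height = as.integer(height), left = left,
                         right = right, background = background,
                         inclusion = inclusion),
                    class = "phantom_spec")
  m <- .phantom_masks(spec)
  if (any(m$left & m$right))
    stop("left and right regions must not overlap")
  spec
}

.ellipse_mask <- function(width, height, center, axes) {
  x <- matrix(seq_len(width), width, height)
  y <- matrix(seq_len(height), width, height, byrow = TRUE)
  ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 <= 1
}

.phantom_masks <- function(spec) {
  list(left = .ellipse_mask(spec$width, spec$height, spec$left$center,
                            spec$left$axes),
       right = .ellipse_mask(spec$width, spec$height, spec$right$center,
                             spec$right$axes))
}

# continuous intensity-fraction field of a phantom, plus region masks
.phantom_field <- function(spec) {
  m <- .phantom_masks(spec)
  f <- matrix(spec$background, spec$width, spec$height)
  f[m$left] <- spec$left$peak
  f[m$right] <- spec$right$peak
  if (!is.null(inc <- spec$inclusion)) {
    mi <- .ellipse_mask(spec$width, spec$height, inc$center, inc$axes)
    mi <- mi & m[[inc$side]]  # clip the inclusion to its host sinus
    f[mi] <- inc$level
  }
  list(field = f, masks = m)
}

#' Render a phantom image with analytic ground truth
#'
#' Renders the phantom's continuous intensity field through the camera
#' model and returns, alongside the image, the mean intensity fraction of
#' each sinus region computed from the continuous field - the ground
#' truth the image metrics should recover up to quantization (and noise).
#'
#' @param spec A `phantom_spec`.
#' @param camera A `camera_config`; the continuous field maps to counts as
#'   `offset + fraction * (full_scale - offset)` at the camera's own
#'   exposure, scaling linearly with exposure.
#' @param seed Noise seed (required when noise is on).
#' @return List with `image` (a `sinus_image`), `truth` (list `left`,
#'   `right`: mean intensity fractions) and `masks` (logical matrices).
#' @export
render_phantom <- function(spec, camera = camera_config(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  ph <- .phantom_field(spec)
  fs <- full_scale(camera)
  counts <- camera$offset + ph$field * (fs - camera$offset)
  if (camera$noise != "none") {
    if (is.null(seed)) stop("seed is required when noise is enabled")
    counts <- .with_seed(seed, {
      matrix(.apply_noise(counts, camera), nrow(counts), ncol(counts))
    })
  }
  img <- structure(.quantize(counts, camera),
                   camera = camera, provenance = "phantom",
                   class = c("sinus_image", "matrix", "array"))
  truth <- list(left = mean(ph$field[ph$masks$left]),
                right = mean(ph$field[ph$masks$right]))
  list(image = img, truth = truth, masks = ph$masks)
}

#' Render an exposure series
#'
#' One image per exposure time, emulating the acquisition protocol of
#' recording the same scene at stepped exposures (default 1-40 ms in 1 ms
#' increments). For a phantom, the camera's own `exposure_ms` acts as the
#' reference exposure at which the phantom intensities equal their
#' specified fractions of full scale; other exposures scale linearly.
#' The same `seed` is reused for every exposure, so with noise on the
#' series shares one noise realisation policy (stated in the result's
#' `seed_policy` attribute).
#'
#' @param x A `phantom_spec` or an irradiance matrix.
#' @param camera A `camera_config`.
#' @param exposures_ms Exposure times in ms (>= 0).
#' @param seed Noise seed (required when noise is on).
#' @return List of `sinus_image`s, one per exposure, with the exposure
#'   recorded in each image's camera attribute.
#' @export
exposure_series <- function(x, camera = camera_config(),
                            exposures_ms = 1:40, seed = NULL) {
  if (!length(exposures_ms) || any(exposures_ms < 0))
    stop("exposures_ms must be nonempty and >= 0")
  if (inherits(x, "phantom_spec")) {
    if (camera$exposure_ms <= 0)
      stop("camera exposure must be > 0 to act as the phantom reference")
    ph <- .phantom_field(x)
    fs <- full_scale(camera)
    # pseudo-irradiance reproducing the phantom at the reference exposure
    irr <- ph$field * (fs - camera$offset) / (camera$gain * camera$exposure_ms)
  } else {
    irr <- as.matrix(x)
  }
  out <- lapply(exposures_ms, function(t_ms) {
    cam_t <- camera
    cam_t$exposure_ms <- t_ms
    img <- render_image(irr, cam_t, seed = seed)
    attr(img, "provenance") <- if (inherits(x, "phantom_spec"))
      "phantom" else "simulated"
    img
  })
  attr(out, "exposures_ms") <- exposures_ms
  attr(out, "seed_policy") <- "shared seed across exposures"
  out
}

#' @export
print.sinus_image <- function(x, ...) {
  cam <- attr(x, "camera")
  cat(sprintf("<sinus_image> %dx%d px, %d-bit, exposure %.3g ms, %s\n",
              nrow(x), ncol(x), cam$bit_depth, cam$exposure_ms,
              attr(x, "provenance")))
  cat(sprintf("  counts: min %d, max %d (full scale %d)\n", min(x), max(x),
              full_scale(cam)))
  invisible(x)
}

#' Write a sinus image as PNG
#'
#' Pixel counts are normalised by the camera's full scale before writing,
#' so the PNG renders the image's dynamic range regardless of bit depth.
#'
#' @param image A `sinus_image`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sinus_image <- function(image, path) {
  cam <- attr(image, "camera")
  # png arrays are row-major top-left; transpose our (x, y) layout
  arr <- t(unclass(image))[seq(ncol(image), 1), , drop = FALSE]
  png::writePNG(arr / full_scale(cam), path)
  invisible(path)
}
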
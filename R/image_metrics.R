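#' Elliptical region of interest
#'
#' Parametric ROI over a sinus region, for reproducible analyses (the
#' clinical workflow outlines the region by hand; see [roi_polygon()]).
#'
#' @param image A `sinus_image` or a matrix giving the target geometry.
#' @param center Ellipse centre (x, y) in pixels.
#' @param axes Semi-axes in pixels.
#' @param side `"left"` or `"right"`.
#' @return An `roi` object: a logical mask with `side` and `provenance`
#'   attributes.
#' @export
roi_ellipse <- function(image, center, axes, side = c("left", "right")) {
  side <- match.arg(side)
  mask <- .ellipse_mask(nrow(image), ncol(image), center, axes)
  .roi(mask, side, "parametric ellipse")
}

#' Polygonal region of interest
#'
#' Builds an ROI from manually drawn polygon vertices (the on-image
#' outline of the analysis area).
#'
#' @param image A `sinus_image` or matrix giving the target geometry.
#' @param vertices Two-column matrix of (x, y) vertex coordinates in
#'   pixels.
#' @param side `"left"` or `"right"`.
#' @return An `roi` object.
#' @export
roi_polygon <- function(image, vertices, side = c("left", "right")) {
  side <- match.arg(side)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("vertices must be an n x 2 matrix with n >= 3")
  px <- cbind(rep(seq_len(nrow(image)), ncol(image)),
              rep(seq_len(ncol(image)), each = nrow(image)))
  inside <- mgcv::in.out(rbind(vertices, vertices[1, ]), px)
  mask <- matrix(inside, nrow(image), ncol(image))
  .roi(mask, side, "manual polygon")
}

.roi <- function(mask, side, provenance) {
  if (!any(mask)) stop("ROI is empty")
  structure(mask, side = side, provenance = provenance,
            class = c("roi", "matrix", "array"))
}

.image_offset <- function(image) {
  cam <- attr(image, "camera")
  if (is.null(cam)) 0 else cam$offset
}

.image_full_scale <- function(image) {
  cam <- attr(image, "camera")
  if (is.null(cam)) max(2^8 - 1, max(image)) else full_scale(cam)
}

#' Percentage of light transmitted through a sinus region
#'
#' The quantitative diaphanoscopy readout: the mean offset-corrected pixel
#' value over the ROI as a percentage of the offset-corrected full scale,
#' clipped to \[0, 100\]. With `reference = "contralateral"` the value is
#' instead expressed relative to a second ROI's mean (x 100), which makes
#' the readout invariant to common intensity scalings such as exposure
#' changes.
#'
#' @param image A `sinus_image` (or plain matrix; offset then defaults
#'   to 0 and full scale to 255).
#' @param roi An `roi` mask.
#' @param reference `"full_scale"` (default) or `"contralateral"`.
#' @param reference_roi The contralateral ROI (required for the
#'   contralateral reference).
#' @return A single percentage.
#' @export
percent_transmitted <- function(image, roi,
                                reference = c("full_scale",
                                              "contralateral"),
                                reference_roi = NULL) {
  reference <- match.arg(reference)
  if (!all(dim(roi) == dim(image))) stop("ROI does not match the image")
  if (!any(roi)) stop("ROI is empty")
  off <- .image_offset(image)
  m <- mean(image[roi]) - off
  if (reference == "contralateral") {
    if (is.null(reference_roi)) stop("reference_roi is required")
    ref <- mean(image[reference_roi]) - off
    if (ref <= 0) return(0)
    return(max(0, 100 * m / ref))
  }
  denom <- .image_full_scale(image) - off
  min(100, max(0, 100 * m / denom))
}

#' Pseudo-color intensity segmentation
#'
#' Quantizes the image into `n_bands` equal-width intensity bands (the
#' qualitative processing step of diaphanoscopic images), labelled 0
#' (darkest) to `n_bands - 1`. Colors are applied only at export
#' ([export_pseudocolor_png()]).
#'
#' @param image A `sinus_image` or matrix.
#' @param n_bands Number of bands (>= 2).
#' @param normalization `"full_scale"` bins over `[0, full_scale]`;
#'   `"image_max"` bins over `[min(image), max(image)]`.
#' @return List with `labels` (integer matrix), `edges` (band boundaries,
#'   length `n_bands + 1`) and `constant` (flag: degenerate constant image
#'   under image_max normalization, single band).
#' @export
pseudocolor_segmentation <- function(image, n_bands = 8,
                                     normalization = c("full_scale",
                                                       "image_max")) {
  normalization <- match.arg(normalization)
  if (n_bands < 2) stop("n_bands must be >= 2")
  px <- unclass(image)
  if (normalization == "full_scale") {
    lo <- 0; hi <- .image_full_scale(image)
  } else {
    lo <- min(px); hi <- max(px)
    if (hi == lo) {
      warning("constant image under image_max normalization; single band")
      return(list(labels = matrix(0L, nrow(px), ncol(px)),
                  edges = c(lo, hi), constant = TRUE))
    }
  }
  edges <- seq(lo, hi, length.out = n_bands + 1)
  lab <- pmin(n_bands - 1L, pmax(0L, floor((px - lo) / (hi - lo) * n_bands)))
  storage.mode(lab) <- "integer"
  list(labels = matrix(lab, nrow(px), ncol(px)), edges = edges,
       constant = FALSE)
}

#' Left-right asymmetry index
#'
#' `|p_left - p_right| / (p_left + p_right)`: 0 for perfect symmetry, 1
#' when one side transmits nothing. Defined as 0 when both sides are 0.
#' The index is symmetric in its arguments and invariant to a common
#' positive scaling (hence to exposure changes in the linear range).
#'
#' @param p_left,p_right Transmitted-light percentages in \[0, 100\].
#' @return A number in \[0, 1\].
#' @export
asymmetry_index <- function(p_left, p_right) {
  stopifnot(p_left >= 0, p_right >= 0)
  if (p_left + p_right == 0) return(0)
  abs(p_left - p_right) / (p_left + p_right)
}

#' Transmitted-light metrics across an exposure series
#'
#' Applies a fixed left/right ROI pair to every image of an exposure
#' series and reports the per-exposure percentages, their ratio and the
#' asymmetry index, flagging saturated images (any ROI pixel at full
#' scale). The spread statistics (attributes `ratio_spread` and
#' `asymmetry_spread`: max minus min) are computed over non-saturated,
#' non-zero exposures only.
#'
#' @param series List of `sinus_image`s from [exposure_series()].
#' @param roi_left,roi_right `roi` masks shared by the whole series.
#' @return Data frame with columns `exposure_ms`, `percent_left`,
#'   `percent_right`, `ratio`, `asymmetry`, `saturated`.
#' @export
exposure_robustness <- function(series, roi_left, roi_right) {
  rows <- lapply(series, function(img) {
    fs <- .image_full_scale(img)
    pl <- percent_transmitted(img, roi_left)
    pr <- percent_transmitted(img, roi_right)
    data.frame(exposure_ms = attr(img, "camera")$exposure_ms,
               percent_left = pl, percent_right = pr,
               ratio = if (pr > 0) pl / pr else NA_real_,
               asymmetry = asymmetry_index(pl, pr),
               saturated = any(img[roi_left | roi_right] >= fs))
  })
  out <- do.call(rbind, rows)
  ok <- !out$saturated & out$exposure_ms > 0 & is.finite(out$ratio)
  attr(out, "ratio_spread") <-
    if (any(ok)) diff(range(out$ratio[ok])) else NA_real_
  attr(out, "asymmetry_spread") <-
    if (any(ok)) diff(range(out$asymmetry[ok])) else NA_real_
  out
}

#' Export a segmentation as a pseudo-colored PNG
#'
#' @param segmentation Result of [pseudocolor_segmentation()].
#' @param path Output path.
#' @param palette A `grDevices::hcl.colors` palette name.
#' @return Invisibly, `path`.
#' @export
export_pseudocolor_png <- function(segmentation, path,
                                   palette = "Inferno") {
  lab <- segmentation$labels
  n <- max(lab) + 1L
  cols <- grDevices::col2rgb(grDevices::hcl.colors(max(n, 2), palette)) / 255
  arr <- array(0, dim = c(ncol(lab), nrow(lab), 3))
  for (ch in 1:3) {
    m <- matrix(cols[ch, lab + 1L], nrow(lab), ncol(lab))
    arr[, , ch] <- t(m)[seq(ncol(lab), 1), , drop = FALSE]
  }
  png::writePNG(arr, path)
  invisible(path)
}

#' Bundle metrics into an examination-report JSON
#'
#' Writes a patient-free report: run metadata, the per-side
#' transmitted-light percentages, asymmetry index and any image file
#' paths.
#'
#' @param metrics Named list (e.g. percentages, asymmetry, exposure
#'   table).
#' @param path Output JSON path.
#' @param metadata Optional named list (seed, wavelength, package
#'   version...).
#' @param images Optional character vector of image paths.
#' @return Invisibly, `path`.
#' @export
examination_report <- function(metrics, path, metadata = list(),
                               images = character()) {
  report <- list(
    generated = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package = as.character(utils::packageVersion("diaphanosim")),
    metadata = metadata, metrics = metrics, images = images)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
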
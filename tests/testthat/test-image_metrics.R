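test_that("percent transmitted reproduces closed-form cases", {
  cam <- camera_config(offset = 10)
  img <- structure(matrix(255L, 20, 20), camera = cam,
                   class = c("sinus_image", "matrix", "array"))
  roi <- roi_ellipse(img, c(10, 10), c(6, 6), "left")
  expect_equal(percent_transmitted(img, roi), 100)

  img[] <- 10L
  expect_equal(percent_transmitted(img, roi), 0)

  # plain matrices default to offset 0 / full scale 255
  m <- matrix(51, 10, 10)
  r <- roi_ellipse(m, c(5, 5), c(3, 3), "left")
  expect_equal(percent_transmitted(m, r), 20)
  expect_error(percent_transmitted(img, roi[1:5, 1:5]), "match")
})

test_that("phantom percentages recover the ground truth to quantization", {
  spec <- demo_phantom(0.25, 0.8)
  ph <- render_phantom(spec)
  roi_l <- roi_ellipse(ph$image, spec$left$center, spec$left$axes, "left")
  roi_r <- roi_ellipse(ph$image, spec$right$center, spec$right$axes,
                       "right")
  pl <- percent_transmitted(ph$image, roi_l)
  pr <- percent_transmitted(ph$image, roi_r)
  expect_equal(pl, 100 * ph$truth$left, tolerance = 0.3)
  expect_equal(pr, 100 * ph$truth$right, tolerance = 0.3)
  # contralateral reference form
  expect_equal(percent_transmitted(ph$image, roi_l,
                                   reference = "contralateral",
                                   reference_roi = roi_r),
               100 * 0.25 / 0.8, tolerance = 0.5)
})

test_that("percent is monotone under uniform intensity shifts", {
  m <- matrix(100, 12, 12)
  r <- roi_ellipse(m, c(6, 6), c(4, 4), "left")
  vals <- vapply(c(-40, 0, 40, 80), function(s)
    percent_transmitted(m + s, r), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("asymmetry index: closed forms, symmetry, scale invariance", {
  expect_identical(asymmetry_index(50, 50), 0)
  expect_identical(asymmetry_index(60, 20), 0.5)
  expect_identical(asymmetry_index(37, 0), 1)
  expect_identical(asymmetry_index(0, 0), 0)
  for (i in 1:20) {
    p <- runif(2, 0, 100); a <- runif(1, 0.1, 10)
    expect_equal(asymmetry_index(p[1], p[2]), asymmetry_index(p[2], p[1]))
    expect_equal(asymmetry_index(a * p[1], a * p[2]),
                 asymmetry_index(p[1], p[2]))
  }
  expect_error(asymmetry_index(-1, 5), ">= 0")
})

test_that("pseudo-color segmentation bins intensities into stable bands", {
  bin <- matrix(c(0, 255), 8, 8)
  seg <- pseudocolor_segmentation(bin, n_bands = 2)
  expect_setequal(unique(as.vector(seg$labels)), c(0L, 1L))

  ramp <- matrix(rep(seq(0, 255, length.out = 80), each = 10), 10, 80)
  seg8 <- pseudocolor_segmentation(ramp, n_bands = 8)
  counts <- table(seg8$labels)
  expect_length(counts, 8)
  expect_true(all(counts == 100))  # eight equal contiguous stripes
  expect_length(seg8$edges, 9)
  # labels are non-decreasing along the ramp
  expect_true(all(diff(seg8$labels[1, ]) >= 0))

  expect_warning(
    flat <- pseudocolor_segmentation(matrix(7, 4, 4),
                                     normalization = "image_max"),
    "constant")
  expect_true(flat$constant)
  expect_true(all(flat$labels == 0))
  expect_error(pseudocolor_segmentation(bin, n_bands = 1), "n_bands")
})

test_that("a cyst-mimic inclusion takes the lowest label within its sinus", {
  inc <- list(side = "left", center = c(35, 45), axes = c(6, 5),
              level = 0.08)
  spec <- demo_phantom(0.8, 0.6, inclusion = inc)
  ph <- render_phantom(spec)
  seg <- pseudocolor_segmentation(ph$image, n_bands = 8)
  f <- diaphanosim:::.phantom_field(spec)
  left_labels <- seg$labels[f$masks$left]
  inc_mask <- diaphanosim:::.ellipse_mask(spec$width, spec$height,
                                          inc$center, inc$axes)
  expect_equal(unique(as.vector(seg$labels[inc_mask])),
               min(left_labels))
})

test_that("segmentation labels are invariant under affine remaps (image_max)", {
  img <- matrix(sample(20:120, 60, replace = TRUE), 6, 10)
  base <- pseudocolor_segmentation(img, n_bands = 6,
                                   normalization = "image_max")
  remap <- pseudocolor_segmentation(2 * img + 13, n_bands = 6,
                                    normalization = "image_max")
  expect_identical(base$labels, remap$labels)
})

test_that("polygon and ellipse ROIs agree on simple shapes", {
  m <- matrix(0, 30, 30)
  sq <- roi_polygon(m, rbind(c(5, 5), c(5, 25), c(25, 25), c(25, 5)),
                    side = "left")
  expect_true(sq[15, 15] && !sq[2, 2] && !sq[28, 28])
  expect_equal(attr(sq, "provenance"), "manual polygon")
  expect_error(roi_polygon(m, rbind(c(1, 1), c(2, 2)), "left"), "n >= 3")
  expect_error(roi_ellipse(m, c(200, 200), c(2, 2), "left"), "empty")
})

test_that("exposure robustness: ratio invariance and saturation flags", {
  spec <- demo_phantom(0.8, 0.4)
  cam <- camera_config(exposure_ms = 20.7)
  series <- exposure_series(spec, cam, exposures_ms = c(0, 5, 10, 20, 35))
  img <- series[[2]]
  roi_l <- roi_ellipse(img, spec$left$center, spec$left$axes, "left")
  roi_r <- roi_ellipse(img, spec$right$center, spec$right$axes, "right")
  tab <- exposure_robustness(series, roi_l, roi_r)
  expect_equal(nrow(tab), 5)
  # the 35 ms frame saturates the 0.8 peak (0.8 * 35 / 20.7 > 1)
  expect_true(tab$saturated[5])
  expect_false(any(tab$saturated[1:4]))
  # the left/right ratio is exposure-invariant up to quantization: the
  # regions are flat, so the only error is rounding the counts, giving a
  # first-order bound |ratio - 2| <= 2 (0.5/cL + 0.5/cR)
  ok <- tab$exposure_ms > 0 & !tab$saturated
  cL <- 0.8 * 255 * tab$exposure_ms / 20.7
  cR <- 0.4 * 255 * tab$exposure_ms / 20.7
  bound <- 2 * (0.5 / cL + 0.5 / cR)
  expect_true(all(abs(tab$ratio[ok] - 2) <= bound[ok] + 1e-9))
  expect_equal(attr(tab, "ratio_spread"), diff(range(tab$ratio[ok])))
})

test_that("pseudocolor export and examination report write valid files", {
  ph <- render_phantom(demo_phantom())
  seg <- pseudocolor_segmentation(ph$image)
  png_path <- tempfile(fileext = ".png")
  export_pseudocolor_png(seg, png_path)
  arr <- png::readPNG(png_path)
  expect_equal(dim(arr)[3], 3)

  rep_path <- tempfile(fileext = ".json")
  examination_report(list(percent_left = 40.2, percent_right = 39.8,
                          asymmetry_index = 0.005),
                     rep_path, metadata = list(wavelength = 850),
                     images = png_path)
  parsed <- jsonlite::read_json(rep_path)
  expect_equal(parsed$metrics$percent_left, 40.2)
  expect_equal(parsed$metadata$wavelength, 850)
  expect_true(nzchar(parsed$package))
})
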
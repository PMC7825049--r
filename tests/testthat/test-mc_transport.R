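test_that("free-path sampling matches the exponential closed form", {
  expect_equal(sample_free_path(1, exp(-1)), 1)
  expect_equal(sample_free_path(2, 0.5), log(2) / 2)
  expect_identical(sample_free_path(0, 0.5), Inf)
  expect_error(sample_free_path(1, 0), "u > 0")
})

test_that("Henyey-Greenstein sampling has the right mean and limits", {
  set.seed(101)
  n <- 2e4
  cs0 <- vapply(seq_len(n), function(i)
    sample_scatter(0, runif(1), runif(1), c(0, 0, 1))[3], 0)
  # isotropic: mean 0, variance 1/3
  expect_lt(abs(mean(cs0)), 3 * sqrt(1 / 3 / n))

  g <- 0.9
  cs <- vapply(seq_len(n), function(i)
    sample_scatter(g, runif(1), runif(1), c(0, 0, 1))[3], 0)
  # HG variance from independent numerical integration of the phase function
  pdf_hg <- function(mu) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * mu)^1.5
  e2 <- stats::integrate(function(m) m^2 * pdf_hg(m), -1, 1)$value
  expect_lt(abs(mean(cs) - g), 3 * sqrt((e2 - g^2) / n))

  # forward-peaked limit
  fwd <- sample_scatter(1 - 1e-12, 0.3, 0.7, c(0, 0, 1))
  expect_equal(fwd[3], 1, tolerance = 1e-4)
  # output is always a unit vector, along any incoming direction
  for (i in 1:25) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    out <- sample_scatter(0.5, runif(1), runif(1), d)
    expect_equal(sum(out^2), 1, tolerance = 1e-12)
  }
})

test_that("Fresnel interaction reproduces the closed forms", {
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.3), 0)
  expect_equal(fresnel_reflectance(1, 1.4, 1), ((1 - 1.4) / (1 + 1.4))^2)
  # total internal reflection beyond the critical angle
  cos_crit <- sqrt(1 - (1 / 1.4)^2)
  expect_equal(fresnel_reflectance(1.4, 1, cos_crit * 0.9), 1)

  same <- fresnel_interaction(1.4, 1.4, c(0, 0, 1), c(0, 0, 1), u = 0.99)
  expect_equal(same$type, "refracted")
  expect_equal(same$direction, c(0, 0, 1))

  tir <- fresnel_interaction(1.4, 1, c(sqrt(1 - 0.5^2), 0, 0.5),
                             c(0, 0, 1), u = 0.999999)
  expect_equal(tir$type, "reflected")
  expect_equal(tir$direction[3], -0.5)

  # Snell's law at 45 degrees into a denser medium
  d <- c(sin(pi / 4), 0, cos(pi / 4))
  out <- fresnel_interaction(1, 1.5, d, c(0, 0, 1), u = 0.999999)
  expect_equal(out$type, "refracted")
  expect_equal(out$direction[1], sin(pi / 4) / 1.5, tolerance = 1e-12)
})

test_that("absorption-only slab follows Beer-Lambert", {
  st <- single_slab(mu_a = 0.2, mu_s = 0, thickness = 10)
  n <- 5e4
  res <- run_simulation(st, source_spec(650, 1), n, seed = 9,
                        detector = open_detector())
  p <- exp(-2)
  expect_lt(abs(res$transmitted_mW - p), 3 * sqrt(p * (1 - p) / n))
  expect_equal(res$reflected_mW, 0)
})

test_that("energy is conserved: exactly without roulette, closely with", {
  st <- build_stack("female", "none", 650)
  res <- run_simulation(st, source_spec(650), 5e3, seed = 3,
                        options = transport_options(roulette = FALSE))
  expect_equal(conservation_error(res), 0, tolerance = 1e-12)

  res2 <- run_simulation(st, source_spec(650), 2e4, seed = 3)
  expect_lt(conservation_error(res2), 1e-3)

  # no absorption: everything is reflected or transmitted
  pure <- single_slab(0, 1.5, g = 0.8, thickness = 15)
  res3 <- run_simulation(pure, source_spec(650, 1), 5e3, seed = 5,
                         detector = open_detector(),
                         options = transport_options(roulette = FALSE))
  expect_equal(res3$reflected_mW + res3$transmitted_mW, 1,
               tolerance = 1e-12)
  expect_equal(sum(res3$absorbed_mW), 0)
})

test_that("zero-thickness stack transmits at the entry point", {
  zero_all <- setNames(rep(0, 8), all_layer_names)
  st <- build_stack("male", "none", 650, thickness_overrides = zero_all)
  res <- run_simulation(st, source_spec(650, 1), 50, seed = 1)
  expect_equal(res$transmitted_mW, 1)
  pk <- propagate_packet(st, source_spec(650, 1), seed = 2)
  expect_equal(pk$status, "transmitted")
  expect_equal(unname(c(pk$x, pk$y)), c(0, 0))
})

test_that("runs are deterministic and linear in source power", {
  st <- build_stack("male", "cyst", 850)
  a <- run_simulation(st, source_spec(850, 8), 5e3, seed = 77)
  b <- run_simulation(st, source_spec(850, 8), 5e3, seed = 77)
  expect_identical(a$flux_mW, b$flux_mW)
  expect_identical(a$detector$irradiance, b$detector$irradiance)
  expect_identical(a$absorbed_mW, b$absorbed_mW)

  dbl <- run_simulation(st, source_spec(850, 16), 5e3, seed = 77)
  expect_equal(dbl$flux_mW, 2 * a$flux_mW, tolerance = 1e-12)
  expect_equal(dbl$reflected_mW, 2 * a$reflected_mW, tolerance = 1e-12)
  expect_equal(dbl$absorbed_mW, 2 * a$absorbed_mW, tolerance = 1e-12)
})

test_that("detector bookkeeping closes: grid + out-of-aperture = transmitted", {
  st <- build_stack("female", "none", 850)
  det <- detector_config(16, 16, 30, 30)
  res <- run_simulation(st, source_spec(850), 1e4, seed = 12, detector = det)
  grid_power <- sum(res$detector$irradiance) * res$detector$bin_area_mm2
  expect_equal(grid_power + res$out_of_aperture_mW, res$transmitted_mW,
               tolerance = 1e-9)
  expect_equal(grid_power, res$flux_mW, tolerance = 1e-9)
  expect_gt(res$flux_se_mW, 0)
})

test_that("ballistic transmission matches the closed form and hand sums", {
  zero_all <- setNames(rep(0, 8), all_layer_names)
  empty <- build_stack("male", "none", 650, thickness_overrides = zero_all)
  expect_equal(ballistic_transmission(empty), 1)
  expect_equal(ballistic_transmission(single_slab(0.4, 0.6, thickness = 1)),
               exp(-1))
  st <- build_stack("male", "none", 850)
  expect_equal(ballistic_transmission(st),
               exp(-(oracle_sum("male", 850, "mu_a") +
                     oracle_sum("male", 850, "mu_s"))))
})

test_that("reduced-scattering similarity holds for a pure-scattering slab", {
  # (mu_s = 2, g = 0.9) vs the transport-equivalent (mu_s' = 0.2, g = 0)
  hg <- single_slab(0, 2, g = 0.9, thickness = 20)
  iso <- single_slab(0, 0.2, g = 0, thickness = 20)
  a <- run_simulation(hg, source_spec(650, 1), 4e4, seed = 21,
                      detector = open_detector())
  b <- run_simulation(iso, source_spec(650, 1), 4e4, seed = 22,
                      detector = open_detector())
  expect_equal(a$transmitted_mW, b$transmitted_mW, tolerance = 0.03)
})

test_that("single-packet propagation conserves weight and records a path", {
  st <- build_stack("female", "none", 650)
  pk <- propagate_packet(st, source_spec(650), seed = 4)
  expect_true(pk$status %in% c("reflected", "transmitted", "absorbed"))
  expect_equal(pk$reflected_weight + pk$absorbed_weight +
                 pk$transmitted_weight, 1, tolerance = 1e-9)
  expect_true(is.matrix(pk$path) && ncol(pk$path) == 3)
  expect_gte(nrow(pk$path), 1)
})

test_that("invalid simulation inputs are rejected", {
  st <- build_stack("male", "none", 650)
  expect_error(run_simulation(st, source_spec(650), 0, seed = 1),
               "n_photons")
  expect_error(source_spec(650, power_mW = 0), "power")
  expect_error(source_spec(650, beam = "cone", half_angle_deg = 95),
               "half_angle")
})
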
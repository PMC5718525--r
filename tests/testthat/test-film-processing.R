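# Film pipeline: scan averaging, optical density, quartic calibration,
# channel selection and the end-to-end dose round trip.

test_that("scan averaging is exact for identical and symmetric inputs", {
  geo <- grid_geometry(c(80, 80, 101), c(0.5, 0.5, 1), c(10, 10, 1))
  base <- simulate_film_scan(dose_grid(array(1, dim = c(10, 10, 1)), geo))
  expect_identical(average_scans(rep(list(base), 5))$pixels, base$pixels)

  up <- film_scan(base$pixels + 50, geometry = geo)
  dn <- film_scan(base$pixels - 50, geometry = geo)
  expect_equal(average_scans(list(up, dn))$pixels, base$pixels,
               tolerance = 1e-12)
  bad <- film_scan(array(100, dim = c(4, 4, 3)))
  expect_error(average_scans(list(base, bad)), "shape")
})

test_that("optical density follows the decade definition", {
  px <- array(1000, dim = c(2, 2, 3))
  scan <- film_scan(px)
  expect_equal(max(abs(pixel_to_od(scan, c(1000, 1000, 1000)))), 0)
  expect_equal(unclass(pixel_to_od(scan, c(10000, 10000, 10000)))[1, 1, 1], 1,
               tolerance = 1e-12)
  # invariance under common exposure rescaling
  od1 <- pixel_to_od(film_scan(px * 2), 2 * c(1000, 1100, 1200))
  od2 <- pixel_to_od(scan, c(1000, 1100, 1200))
  expect_equal(unclass(od1), unclass(od2), tolerance = 1e-12)
  expect_error(pixel_to_od(scan, c(-1, 1, 1)), "positive")
})

test_that("noiseless scans recover the generator's optical density to 1e-9", {
  geo <- grid_geometry(c(80, 80, 101), c(0.5, 0.5, 1), c(30, 30, 1))
  d <- array(rep(seq(0, 4, length.out = 30), 30), dim = c(30, 30, 1))
  resp <- film_response()
  scan <- simulate_film_scan(dose_grid(d, geo), resp)
  od <- pixel_to_od(scan, resp$reference)
  expected <- resp$channels$red$od_of_dose(d[, , 1])
  expect_lt(max(abs(unclass(od)[, , 1] - expected)), 1e-9)
})

test_that("quartic calibration recovers exact polynomial strip data", {
  coef_true <- c(0.1, 7, 9, 4, 2)   # dose = c0 + c1 od + ... + c4 od^4
  od <- seq(0, 0.6, length.out = 9)
  dose <- plugdose:::.polyval(coef_true, od)
  strips <- data.frame(dose_gy = dose, od_r = od, od_g = od * 0.6,
                       od_b = od * 0.4)
  cal <- fit_film_calibration(strips)
  expect_lt(max(abs(cal$coefficients[, "red"] - coef_true) /
                  pmax(abs(coef_true), 1)), 1e-8)
  expect_equal(cal$selected_channel, "red")   # largest OD span per Gy
  expect_error(fit_film_calibration(strips[1:5, ]), "at least 6")
})

test_that("a noisy saturating response still fits with R^2 >= 0.999", {
  doses <- seq(0, 10, length.out = 11)
  set.seed(88)
  strips <- data.frame(dose_gy = doses,
                       od_r = 0.8 * (1 - exp(-doses / 6)) + rnorm(11, 0, 0.002),
                       od_g = 0.5 * (1 - exp(-doses / 6)) + rnorm(11, 0, 0.002),
                       od_b = 0.3 * (1 - exp(-doses / 6)) + rnorm(11, 0, 0.002))
  cal <- fit_film_calibration(strips)
  expect_gte(cal$r_squared[["red"]], 0.999)
  expect_equal(cal$selected_channel, "red")
})

test_that("a non-monotone fitted curve is flagged with a warning", {
  # hard saturation: the quartic approximation overshoots and turns over
  od <- seq(0, 1, length.out = 9)
  dose <- 10 * (1 - exp(-8 * od)) / (1 - exp(-8))
  wob <- data.frame(dose_gy = dose, od_r = od, od_g = od, od_b = od)
  expect_warning(cal <- fit_film_calibration(wob), "not monotone")
  expect_false(all(cal$monotone))
})

test_that("the noiseless film pipeline is the identity within 0.1% of 4 Gy", {
  geo <- grid_geometry(c(78, 78, 101), c(0.5, 0.5, 1), c(60, 50, 1))
  d <- array(rep(seq(0, 4, length.out = 60), 50), dim = c(60, 50, 1))
  plane <- dose_grid(d, geo)
  resp <- film_response()
  scan <- average_scans(lapply(1:5, function(i) {
    simulate_film_scan(plane, resp, scan_id = i)
  }))
  cal <- fit_film_calibration(film_strips(resp))
  dmap <- od_to_dose(pixel_to_od(scan, resp$reference), cal)
  expect_lt(max(abs(dmap$values - plane$values)), 0.001 * 4)
  # OD 0 maps to (near) zero dose
  expect_lt(abs(plugdose:::.polyval(cal$coefficients[, "red"], 0)), 0.004)
})

test_that("film TIFF round trip preserves integer counts and shape", {
  geo <- grid_geometry(c(80, 80, 101), c(0.5, 0.5, 1), c(12, 9, 1))
  scan <- simulate_film_scan(
    dose_grid(array(runif(108, 0, 3), dim = c(12, 9, 1)), geo))
  quant <- film_scan(round(scan$pixels), geometry = geo)
  path <- tempfile(fileext = ".tif")
  write_film_tiff(quant, path)
  back <- read_film_tiff(path, geometry = geo)
  expect_equal(back$pixels, quant$pixels, tolerance = 1e-9)
  expect_equal(dim(back$pixels), c(12, 9, 3))
})
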
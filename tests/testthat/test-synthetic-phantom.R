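# Synthetic phantom: dose kernel, plug shielding, prescription rescaling,
# virtual gel measurement, multi-echo and film-scan simulators.

test_that("a single unplugged shot peaks at its isocenter voxel", {
  geo <- tiny_geometry(n = c(17, 17, 17), spacing = c(1, 1, 1))
  calc <- generate_calculated_dose(single_shot_plan(iso = c(100, 100, 100)), geo)
  peak <- arrayInd(which.max(calc$values), dim(calc$values))
  expect_equal(as.vector(peak), plugdose:::.nearest_voxel(geo, c(100, 100, 100)))
})

test_that("the three-shot plan reaches 16 Gy for 8 Gy at the 50% isodose", {
  calc <- generate_calculated_dose(table1_plan(), planning_geometry())
  expect_equal(max(calc$values), 16, tolerance = 1e-9)
  expect_true(all(calc$values >= 0))
})

test_that("plugged wedges shield their side relative to the mirror point", {
  plan <- single_shot_plan(plugs = list(c(0, 180, 0)))
  geo <- tiny_geometry(n = c(25, 25, 9), spacing = c(1, 1, 1),
                       origin = c(88, 88, 96))
  calc <- generate_calculated_dose(plan, geo)
  # 10 mm into the blocked sector (azimuth 90) vs mirror (azimuth 270)
  blocked <- sample_grid(calc, 100, 110, 100)
  open <- sample_grid(calc, 100, 90, 100)
  expect_lt(blocked, open)

  # unplugged run of the same generator confirms symmetry without the plug
  calc0 <- generate_calculated_dose(single_shot_plan(), geo)
  expect_equal(sample_grid(calc0, 100, 110, 100),
               sample_grid(calc0, 100, 90, 100), tolerance = 1e-9)
})

test_that("adding a plug sector never increases the raw kernel dose", {
  set.seed(31)
  pts <- cbind(runif(500, 90, 110), runif(500, 90, 110), runif(500, 95, 105))
  for (rep_i in 1:5) {
    a0 <- runif(1, 0, 300)
    sector <- c(a0, min(a0 + runif(1, 10, 80), 360), runif(1, 0, 0.9))
    plain <- single_shot_plan(collimator = sample(c(4, 8, 14, 18), 1))
    plugged <- single_shot_plan(collimator = plain$shots[[1]]$collimator,
                                plugs = list(sector))
    d0 <- evaluate_plan_dose(plain, pts[, 1], pts[, 2], pts[, 3])
    d1 <- evaluate_plan_dose(plugged, pts[, 1], pts[, 2], pts[, 3])
    expect_true(all(d1 <= d0 + 1e-12))
  }
})

test_that("plan validation errors name the offending shot", {
  expect_error(plan_spec(list(), 8, 0.5), "at least one shot")
  expect_error(
    plan_spec(list(shot_spec(c(300, 100, 100), 18))),
    "shot 1 .* outside the phantom")
  plan <- single_shot_plan(iso = c(100, 100, 100))
  small <- grid_geometry(c(150, 150, 150), c(1, 1, 1), c(5, 5, 5))
  expect_error(generate_calculated_dose(plan, small), "shot 1")
})

test_that("virtual measurement is the identity when noise is off", {
  calc <- generate_calculated_dose(single_shot_plan(), tiny_geometry())
  out <- simulate_measured_dose(calc, noise_spec(0, 0, 1))
  expect_identical(out$values, calc$values)
  expect_error(noise_spec(dose_noise_sigma = -1), ">= 0")
  expect_error(noise_spec(blur_fwhm = -0.5), ">= 0")
})

test_that("virtual measurement is bitwise reproducible given a seed", {
  calc <- generate_calculated_dose(single_shot_plan(), tiny_geometry())
  ns <- noise_spec(0.02, 0.5, 1 / 0.85, seed = 99)
  a <- simulate_measured_dose(calc, ns)
  b <- simulate_measured_dose(calc, ns)
  expect_identical(a$values, b$values)
  # sensitivity alone rescales exactly
  s <- simulate_measured_dose(calc, noise_spec(0, 0, 1 / 0.85))
  expect_equal(s$values, calc$values / 0.85, tolerance = 1e-12)
})

test_that("the CPMG simulator follows the exponential closed form", {
  cal <- gel_calibration(slope = 1, intercept = 0, dose_range = c(0, 20))
  geo <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(2, 2, 1))
  dose <- dose_grid(array(10, dim = c(2, 2, 1)), geo)  # R2 = 10 / s
  ser <- simulate_multiecho_series(dose, cal, s0 = 1000)
  expect_length(ser$te_ms, 8)
  expect_equal(ser$te_ms, seq(14, 112, by = 14))
  expect_equal(ser$signal[1, 1, 1, 1] / 1000, exp(-0.14), tolerance = 1e-12)
  expect_equal(ser$signal[1, 1, 1, 8] / 1000, exp(-1.12), tolerance = 1e-12)

  # zero dose gives the calibration intercept everywhere
  cal2 <- default_gel_calibration()
  zer <- simulate_multiecho_series(dose_grid(array(0, dim = c(2, 2, 1)), geo),
                                   cal2, s0 = 500)
  r2 <- fit_r2_map(zer)
  expect_equal(max(abs(r2$r2 - cal2$intercept)), 0, tolerance = 1e-9)
  expect_error(simulate_multiecho_series(dose, cal, te_ms = numeric(0)),
               "empty")
})

test_that("film scans of a zero-dose plane sit at the unexposed reference", {
  geo <- grid_geometry(c(80, 80, 101), c(0.5, 0.5, 1), c(20, 20, 1))
  plane <- dose_grid(array(0, dim = c(20, 20, 1)), geo)
  resp <- film_response()
  scan <- simulate_film_scan(plane, resp)
  for (ch in 1:3) {
    expect_equal(max(abs(scan$pixels[, , ch] - resp$reference[[ch]])), 0,
                 tolerance = 1e-9)
  }
})

test_that("film response is monotone and errors above the calibrated range", {
  geo <- grid_geometry(c(80, 80, 101), c(0.5, 0.5, 1), c(50, 4, 1))
  ramp <- dose_grid(array(rep(seq(0, 9.5, length.out = 50), 4),
                          dim = c(50, 4, 1)), geo)
  scan <- simulate_film_scan(ramp)
  red <- scan$pixels[, 1, 1]
  expect_true(all(diff(red) < 0))
  hot <- dose_grid(array(11, dim = c(50, 4, 1)), geo)
  expect_error(simulate_film_scan(hot), "range")
})

test_that("averaging five seeded scans shrinks noise variance about 5-fold", {
  geo <- grid_geometry(c(80, 80, 101), c(0.5, 0.5, 1), c(120, 120, 1))
  plane <- dose_grid(array(2, dim = c(120, 120, 1)), geo)
  sigma <- 200
  scans <- lapply(1:5, function(s) {
    simulate_film_scan(plane, noise_sigma = sigma, seed = 500 + s, scan_id = s)
  })
  avg <- average_scans(scans)
  v1 <- stats::var(as.vector(scans[[1]]$pixels[, , 1]))
  v5 <- stats::var(as.vector(avg$pixels[, , 1]))
  expect_equal(v5 / v1, 1 / 5, tolerance = 0.2)
  expect_identical(average_scans(list(scans[[1]]))$pixels, scans[[1]]$pixels)
})
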
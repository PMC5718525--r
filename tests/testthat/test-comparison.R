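# Comparison statistics: dose difference, gamma index, pass-rate tables,
# DVH, DDDVH, D4 diagram, contours and relative-dose conversion.

test_that("dose difference is measured minus calculated and antisymmetric", {
  g <- tiny_geometry()
  a <- dose_grid(array(runif(9^3, 0, 10), dim = c(9, 9, 9)), g)
  b <- dose_grid(a$values + 0.5, g)
  expect_equal(max(abs(dose_difference(a, a)$values)), 0)
  expect_equal(unique(as.vector(dose_difference(b, a)$values)), 0.5,
               tolerance = 1e-12)
  expect_equal(dose_difference(a, b)$values, -dose_difference(b, a)$values)
  other <- dose_grid(a$values, grid_geometry(c(0, 0, 0), c(1, 1, 1), c(9, 9, 9)))
  expect_error(dose_difference(a, other), "common geometry")
})

test_that("gamma is zero for identical grids and one for a flat offset", {
  g <- grid_geometry(c(90, 90, 90), c(1, 1, 1), c(11, 11, 11))
  ref <- dose_grid(array(8, dim = c(11, 11, 11)), g)
  pp <- gamma_params(2, 1, normalization_dose = 16)

  same <- gamma_index(ref, ref, pp)
  expect_equal(max(same$gamma), 0)
  expect_equal(same$pass_rate, 100)
  expect_equal(same$evaluated_count, 11^3)

  # flat field offset by exactly the dose tolerance: DTA cannot help
  off <- dose_grid(ref$values + 0.02 * 16, g)
  gm <- gamma_index(ref, off, pp)
  expect_equal(max(abs(gm$gamma - 1)), 0, tolerance = 1e-9)
})

test_that("fast gamma equals the exhaustive oracle on smooth random pairs", {
  for (s in c(11, 23)) {
    pair <- correlated_pair(s, n = 13)
    pp <- gamma_params(2, 1, normalization_dose = 10,
                       search_radius = 2, interp_step = 0.2)
    fast <- gamma_index(pair$calculated, pair$measured, pp)
    oracle <- gamma_index_exhaustive(pair$calculated, pair$measured, pp)
    expect_lt(max(abs(fast$gamma - oracle)), 1e-6)
  }
})

test_that("pass rates are monotone in the tolerance criteria", {
  pair <- correlated_pair(7)
  tab <- pass_rate_table(pair$calculated, pair$measured,
                         normalization_dose = 10)
  p <- stats::setNames(tab$pass_rate_pct,
                       paste0(tab$dose_tol_pct, "/", tab$dta_mm))
  expect_gte(p[["3/2"]], p[["2/2"]])
  expect_gte(p[["2/2"]], p[["1/1"]])
  expect_gte(p[["1/1"]], p[["0.5/0.5"]])
  expect_gte(p[["3/2"]], p[["3/1"]])
})

test_that("a low-dose cutoff shrinks the evaluated voxel set", {
  pair <- correlated_pair(3)
  pp_all <- gamma_params(2, 1, normalization_dose = 10)
  pp_cut <- gamma_params(2, 1, normalization_dose = 10, low_dose_cutoff = 40)
  all_v <- gamma_index(pair$calculated, pair$measured, pp_all)
  cut_v <- gamma_index(pair$calculated, pair$measured, pp_cut)
  expect_lt(cut_v$evaluated_count, all_v$evaluated_count)
  expect_gt(cut_v$evaluated_count, 0)
})

test_that("gamma parameter invariants are enforced", {
  expect_error(gamma_params(0, 1), "dose_tol")
  expect_error(gamma_params(2, 0), "dta")
  expect_error(gamma_params(2, 1, search_radius = 0.5), "search_radius")
  expect_error(gamma_params(2, 1, interp_step = 0.5), "interp_step")
})

test_that("the cumulative DVH matches step and ramp closed forms", {
  g <- tiny_geometry()
  uniform <- dose_grid(array(8, dim = c(9, 9, 9)), g)
  h <- dvh(uniform, normalization = 16)
  expect_equal(h$volume_pct[h$dose_pct == 0], 100)
  expect_true(all(h$volume_pct[h$dose_pct <= 50] == 100))
  expect_true(all(h$volume_pct[h$dose_pct > 50] == 0))
  expect_true(all(diff(h$volume_pct) <= 0))

  n <- 9^3
  ramp <- dose_grid(array(seq(0, 16, length.out = n), dim = c(9, 9, 9)), g)
  hr <- dvh(ramp, normalization = 16)
  expect_equal(hr$volume_pct[hr$dose_pct == 50], 50, tolerance = 1)
  # uniform distribution: cumulative volume falls linearly
  mid <- hr[hr$dose_pct > 0 & hr$dose_pct < 100, ]
  expect_lt(max(abs(mid$volume_pct - (100 - mid$dose_pct))), 1)
})

test_that("DDDVH conserves voxels, is antisymmetric and reads in percent", {
  g <- tiny_geometry()
  set.seed(12)
  a <- dose_grid(array(runif(9^3, 0, 16), dim = c(9, 9, 9)), g)
  b <- dose_grid(pmax(a$values + rnorm(9^3, 0, 0.5), 0), g)

  same <- dddvh(a, a, normalization = 16)
  expect_true(all(same$delta == 0))

  d1 <- dddvh(b, a, normalization = 16)
  d2 <- dddvh(a, b, normalization = 16)
  expect_equal(sum(d1$delta), 0, tolerance = 1e-15)
  expect_equal(d1$delta, -d2$delta)

  # 1% of voxels moved into one bin reads as 0.01
  n <- 1000
  gg <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(10, 10, 10))
  calc <- dose_grid(array(5, dim = c(10, 10, 10)), gg)
  mv <- array(5, dim = c(10, 10, 10)); mv[1:10] <- 7.5
  meas <- dose_grid(mv, gg)
  dd <- dddvh(meas, calc, normalization = 10, bin_width_pct = 1)
  bin75 <- dd[dd$bin_low_pct <= 75 & dd$bin_high_pct > 75, ]
  expect_equal(bin75$delta, 10 / n)
})

test_that("the D4 diagram reports per-bin percent differences", {
  g <- tiny_geometry()
  set.seed(9)
  calc <- dose_grid(array(runif(9^3, 0.5, 16), dim = c(9, 9, 9)), g)
  meas <- dose_grid(calc$values * 1.02, g)
  d4 <- d4_diagram(meas, calc, normalization = 16)
  filled <- d4[d4$n > 0, ]
  expect_true(all(abs(filled$mean_diff_pct - 2) < 1e-9))
  expect_true(all(filled$sd_diff_pct < 1e-9))
  expect_equal(sum(d4$n), 9^3)

  idn <- d4_diagram(calc, calc, normalization = 16)
  expect_true(all(abs(idn$mean_diff_pct[idn$n > 0]) < 1e-12))

  withzero <- dose_grid(calc$values * (runif(9^3) > 0.1), g)
  dz <- d4_diagram(meas, withzero, normalization = 16)
  expect_equal(sum(dz$n) + attr(dz, "excluded_zero_dose"), 9^3)
})

test_that("low-dose bins inflate the D4 percent spread under absolute noise", {
  g <- grid_geometry(c(0, 0, 0), c(1, 1, 1), c(20, 20, 20))
  set.seed(21)
  calc <- dose_grid(array(runif(8000, 0.5, 16), dim = c(20, 20, 20)), g)
  meas <- dose_grid(calc$values + rnorm(8000, 0, 0.16), g)  # 1% of 16 Gy
  d4 <- d4_diagram(meas, calc, normalization = 16)
  low <- d4$sd_diff_pct[d4$bin_center_pct < 15 & d4$n > 10]
  high <- d4$sd_diff_pct[d4$bin_center_pct > 70 & d4$n > 10]
  expect_gt(min(low), 5 * max(high))
  expect_gt(max(low), 10)   # below 20% dose the spread exceeds +/-10%
})

test_that("isodose contours of a radial field are circular at the right radius", {
  g <- grid_geometry(c(80, 80, 101), c(0.5, 0.5, 1), c(81, 81, 1))
  cx <- geom_coords(g, 1); cy <- geom_coords(g, 2)
  r <- sqrt(outer((cx - 100)^2, (cy - 100)^2, "+"))
  dose <- 16 * exp(-r^2 / 150)
  plane <- dose_grid(array(dose, dim = c(81, 81, 1)), g)
  cl <- isodose_contours(plane, levels_gy = c(8, 20))
  expect_length(cl, 1)   # 20 Gy exceeds the maximum: no contour
  radii <- sqrt((cl[[1]]$x - 100)^2 + (cl[[1]]$y - 100)^2)
  expect_lt(stats::sd(radii), 0.25)   # half the 0.5 mm pixel
  expect_equal(mean(radii), sqrt(-150 * log(8 / 16)), tolerance = 0.01)
})

test_that("relative isodose levels convert to the printed absolute doses", {
  expect_equal(relative_to_absolute(50, 16), 8)
  expect_equal(relative_to_absolute(80, 16), 12.8)
  expect_equal(relative_to_absolute(26, 16), 4.16)
  expect_equal(relative_to_absolute(90, 4), 3.6)
  expect_equal(relative_to_absolute(100, 7.3), 7.3)
  expect_equal(relative_to_absolute(c(5, 26, 50, 70, 90), 16),
               c(0.8, 4.16, 8, 11.2, 14.4))
  expect_error(relative_to_absolute(50, 0), "positive")
})
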
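# Geometry containers, trilinear resampling, subvolume and plane extraction.

test_that("grid geometry validates its invariants", {
  expect_error(grid_geometry(c(0, 0, 0), c(1, -1, 1), c(5, 5, 5)), "positive")
  expect_error(grid_geometry(c(0, 0, 0), c(1, 1, 1), c(5, 0, 5)), ">= 1")
  g <- grid_geometry(c(70, 65, 90), c(1, 1, 1), c(46, 61, 25))
  expect_equal(geom_coords(g, 1)[1], 70)
  expect_equal(geom_extent(g)["max", ], c(x = 115, y = 125, z = 114))
})

test_that("resampling reproduces constant and affine fields exactly", {
  src <- tiny_geometry(n = c(9, 9, 9), spacing = c(2.5, 2.5, 2.5),
                       origin = c(90, 90, 90))
  tgt <- grid_geometry(c(92, 92, 92), c(1, 1, 1), c(15, 15, 15))

  const <- dose_grid(array(3.7, dim = c(9, 9, 9)), src)
  rc <- resample_grid(const, tgt)
  expect_equal(max(abs(rc$values - 3.7)), 0)

  cx <- geom_coords(src, 1); cy <- geom_coords(src, 2); cz <- geom_coords(src, 3)
  lin <- outer(outer(2 * cx, 0.5 * cy, "+"), -0.25 * cz, "+") + 1
  rl <- resample_grid(dose_grid(lin, src), tgt)
  expected <- outer(outer(2 * geom_coords(tgt, 1), 0.5 * geom_coords(tgt, 2),
                          "+"), -0.25 * geom_coords(tgt, 3), "+") + 1
  expect_lt(max(abs(rl$values - expected)), 1e-12)
})

# max second derivative of the analytic plan dose along each axis,
# estimated on fine lines through the shot isocenters
max_axis_curvature <- function(plan, rescale) {
  C <- 0
  for (s in plan$shots) {
    for (a in 1:3) {
      t <- seq(-15, 15, by = 0.05)
      p <- matrix(rep(s$isocenter, each = length(t)), ncol = 3)
      p[, a] <- p[, a] + t
      d <- evaluate_plan_dose(plan, p[, 1], p[, 2], p[, 3]) * rescale
      C <- max(C, max(abs(diff(d, differences = 2))) / 0.05^2)
    }
  }
  C
}

test_that("resampling a smooth shot field matches the analytic generator", {
  # a well-resolved source (0.5 mm) resampled onto an off-lattice 1 mm
  # grid stays within 0.5% of the maximum dose
  plan <- single_shot_plan()
  src <- grid_geometry(c(85, 85, 90), c(0.5, 0.5, 0.5), c(61, 61, 41))
  calc <- generate_calculated_dose(plan, src)
  tgt <- grid_geometry(c(86.25, 86.25, 91.25), c(1, 1, 1), c(27, 27, 17))
  rs <- resample_grid(calc, tgt)
  cx <- geom_coords(tgt, 1); cy <- geom_coords(tgt, 2); cz <- geom_coords(tgt, 3)
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  px <- rep(cx, times = ny * nz)
  py <- rep(rep(cy, each = nx), times = nz)
  pz <- rep(cz, each = nx * ny)
  analytic <- evaluate_plan_dose(plan, px, py, pz) * calc$meta$rescale
  expect_lt(max(abs(rs$values - analytic)), 0.005 * max(calc$values))
  # convexity: interpolation stays inside the source range
  expect_gte(min(rs$values), min(calc$values))
  expect_lte(max(rs$values), max(calc$values))

  # the coarse 2.5 mm planning grid obeys the trilinear second-order bound
  plan3 <- table1_plan()
  calc3 <- generate_calculated_dose(plan3, planning_geometry())
  tgt3 <- geometry_from_box(box_mm(c(80, 110), c(75, 115), c(92, 112)), 1)
  rs3 <- resample_grid(calc3, tgt3)
  c1 <- geom_coords(tgt3, 1); c2 <- geom_coords(tgt3, 2); c3 <- geom_coords(tgt3, 3)
  n1 <- length(c1); n2 <- length(c2); n3 <- length(c3)
  p1 <- rep(c1, times = n2 * n3)
  p2 <- rep(rep(c2, each = n1), times = n3)
  p3 <- rep(c3, each = n1 * n2)
  an3 <- evaluate_plan_dose(plan3, p1, p2, p3) * calc3$meta$rescale
  bound <- 3 * 2.5^2 / 8 * max_axis_curvature(plan3, calc3$meta$rescale)
  expect_lt(max(abs(rs3$values - an3)), bound)
})

test_that("no-data propagates and disjoint extents error", {
  src <- tiny_geometry()
  v <- array(1, dim = c(9, 9, 9)); v[5, 5, 5] <- NA
  g <- dose_grid(v, src)
  r <- resample_grid(g, grid_geometry(c(93, 93, 93), c(1, 1, 1), c(13, 13, 13)))
  expect_true(any(is.na(r$values)))
  expect_error(
    resample_grid(g, grid_geometry(c(500, 500, 500), c(1, 1, 1), c(5, 5, 5))),
    "overlap")
})

test_that("subvolume extraction counts inclusive lattice points", {
  # the analysis box X 70-115, Y 65-125, Z 90-114 on an aligned 1 mm grid
  g <- grid_geometry(c(60, 60, 85), c(1, 1, 1), c(61, 71, 35))
  grid <- dose_grid(array(0, dim = g$shape), g)
  sub <- extract_subvolume(grid, box_mm(c(70, 115), c(65, 125), c(90, 114)))
  expect_equal(sub$geometry$shape, c(46L, 61L, 25L))
  expect_equal(sub$geometry$origin, c(70, 65, 90))

  # identity box and single-voxel box
  full <- extract_subvolume(grid, box_mm(c(60, 120), c(60, 130), c(85, 119)))
  expect_identical(full$values, grid$values)
  one <- extract_subvolume(grid, box_mm(c(70, 70), c(65, 65), c(90, 90)))
  expect_equal(one$geometry$shape, c(1L, 1L, 1L))
  expect_error(extract_subvolume(grid, box_mm(c(200, 201), c(0, 1), c(0, 1))),
               "no voxel")
})

test_that("plane extraction is exact on slices and linear between them", {
  g <- grid_geometry(c(90, 90, 95), c(1, 1, 2), c(11, 11, 7))
  cz <- geom_coords(g, 3)
  vals <- array(0, dim = g$shape)
  for (k in seq_along(cz)) vals[, , k] <- k * 1.5   # linear in slice index
  grid <- dose_grid(vals, g)

  aligned <- extract_plane(grid, "z", 101)   # slice center
  k <- which(cz == 101)
  expect_identical(aligned$values[, , 1], vals[, , k])

  mid <- extract_plane(grid, "z", 100)       # midway between 99 and 101
  expect_equal(mid$values[, , 1], (vals[, , k - 1] + vals[, , k]) / 2)
  expect_error(extract_plane(grid, "z", 300), "outside")
})

test_that("line profiles are flat on constant fields and peak at the shot", {
  plan <- single_shot_plan()
  calc <- generate_calculated_dose(plan, tiny_geometry(n = c(21, 21, 21),
                                                       spacing = c(1, 1, 1),
                                                       origin = c(90, 90, 90)))
  prof <- line_profile(calc, c(90, 100, 100), c(110, 100, 100), step = 0.25)
  expect_equal(prof$x[which.max(prof$dose_gy)], 100, tolerance = 1e-6)

  const <- dose_grid(array(2, dim = c(21, 21, 21)), calc$geometry)
  pc <- line_profile(const, c(90, 95, 95), c(110, 105, 105), step = 0.5)
  expect_true(all(abs(pc$dose_gy - 2) < 1e-12))
})

test_that("resample round trip stays within twice the second-order bound", {
  plan <- table1_plan()
  src <- planning_geometry()
  calc <- generate_calculated_dose(plan, src)
  fine <- geometry_from_box(box_mm(c(75, 110), c(70, 115), c(92, 112)), 1)
  back <- resample_grid(resample_grid(calc, fine), src)
  keep <- !is.na(back$values)
  expect_gt(mean(keep), 0.05)
  bound <- 3 / 8 * (2.5^2 + 1^2) *
    max_axis_curvature(plan, calc$meta$rescale)
  expect_lt(max(abs(back$values[keep] - calc$values[keep])), bound)
})
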
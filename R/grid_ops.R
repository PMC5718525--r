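# Resampling, subvolume and plane extraction. All interpolation is
# trilinear at voxel centers; target positions outside the source extent
# are marked no-data (no extrapolation), and no-data voxels in the source
# propagate to any interpolated value that touches them.

#' Sample a dose grid at arbitrary mm positions (trilinear)
#'
#' @param grid A [dose_grid()].
#' @param x,y,z Numeric vectors of equal length, positions in mm.
#' @return Numeric vector of interpolated doses; `NA` outside the grid
#'   extent or where a contributing voxel is no-data.
#' @export
sample_grid <- function(grid, x, y, z) {
  stopifnot(inherits(grid, "dose_grid"))
  g <- grid$geometry
  n <- g$shape
  v <- grid$values
  eps <- 1e-7

  t1 <- (x - g$origin[1]) / g$spacing[1]
  t2 <- (y - g$origin[2]) / g$spacing[2]
  t3 <- (z - g$origin[3]) / g$spacing[3]
  ok <- t1 > -eps & t1 < n[1] - 1 + eps &
        t2 > -eps & t2 < n[2] - 1 + eps &
        t3 > -eps & t3 < n[3] - 1 + eps

  t1 <- pmin(pmax(t1, 0), n[1] - 1)
  t2 <- pmin(pmax(t2, 0), n[2] - 1)
  t3 <- pmin(pmax(t3, 0), n[3] - 1)

  i1 <- pmin(floor(t1), max(n[1] - 2, 0)); f1 <- t1 - i1
  i2 <- pmin(floor(t2), max(n[2] - 2, 0)); f2 <- t2 - i2
  i3 <- pmin(floor(t3), max(n[3] - 2, 0)); f3 <- t3 - i3

  # singleton axes carry no interpolation weight
  if (n[1] == 1L) f1 <- f1 * 0
  if (n[2] == 1L) f2 <- f2 * 0
  if (n[3] == 1L) f3 <- f3 * 0

  s1 <- n[1]; s12 <- n[1] * n[2]
  j1a <- i1 + 1; j1b <- pmin(i1 + 2, n[1])
  j2a <- i2;     j2b <- pmin(i2 + 1, n[2] - 1)
  j3a <- i3;     j3b <- pmin(i3 + 1, n[3] - 1)

  corner <- function(a, b, c) v[a + b * s1 + c * s12]
  w <- function(fa, fb, fc) fa * fb * fc
  out <-
    w(1 - f1, 1 - f2, 1 - f3) * corner(j1a, j2a, j3a) +
    w(f1,     1 - f2, 1 - f3) * corner(j1b, j2a, j3a) +
    w(1 - f1, f2,     1 - f3) * corner(j1a, j2b, j3a) +
    w(f1,     f2,     1 - f3) * corner(j1b, j2b, j3a) +
    w(1 - f1, 1 - f2, f3)     * corner(j1a, j2a, j3b) +
    w(f1,     1 - f2, f3)     * corner(j1b, j2a, j3b) +
    w(1 - f1, f2,     f3)     * corner(j1a, j2b, j3b) +
    w(f1,     f2,     f3)     * corner(j1b, j2b, j3b)
  out[!ok] <- NA_real_
  out
}

#' Resample a dose grid onto a target geometry
#'
#' Trilinear interpolation at the target voxel centers. Target voxels
#' outside the source support are marked no-data; there is no
#' extrapolation. Trilinear interpolation reproduces constant and affine
#' fields exactly and never produces values outside the source range.
#'
#' @param grid A [dose_grid()].
#' @param target A [grid_geometry()] overlapping the source extent.
#' @return A [dose_grid()] on `target`.
#' @export
resample_grid <- function(grid, target) {
  stopifnot(inherits(grid, "dose_grid"), inherits(target, "grid_geometry"))
  if (geom_equal(grid$geometry, target)) {
    return(dose_grid(grid$values, target, meta = grid$meta))
  }
  es <- geom_extent(grid$geometry)
  et <- geom_extent(target)
  if (any(et["min", ] > es["max", ] + 1e-9) ||
      any(et["max", ] < es["min", ] - 1e-9)) {
    stop("target geometry does not overlap the source extent")
  }
  cx <- geom_coords(target, 1)
  cy <- geom_coords(target, 2)
  cz <- geom_coords(target, 3)
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  px <- rep(cx, times = ny * nz)
  py <- rep(rep(cy, each = nx), times = nz)
  pz <- rep(cz, each = nx * ny)
  vals <- sample_grid(grid, px, py, pz)
  dose_grid(array(vals, dim = c(nx, ny, nz)), target, meta = grid$meta)
}

#' Extract the voxels whose centers fall inside an inclusive mm box
#'
#' @param grid A [dose_grid()].
#' @param box A [box_mm()]; both endpoints are inclusive on every axis.
#' @return A [dose_grid()] restricted to the box, with updated geometry.
#' @export
extract_subvolume <- function(grid, box) {
  stopifnot(inherits(grid, "dose_grid"), inherits(box, "box_mm"))
  eps <- 1e-9
  sel <- lapply(1:3, function(a) {
    cc <- geom_coords(grid$geometry, a)
    which(cc >= box$min[a] - eps & cc <= box$max[a] + eps)
  })
  if (any(vapply(sel, length, 1L) == 0L)) {
    stop("box contains no voxel centers of the grid")
  }
  vals <- grid$values[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  org <- vapply(1:3, function(a) geom_coords(grid$geometry, a)[sel[[a]][1]], 0)
  geo <- grid_geometry(org, grid$geometry$spacing,
                       vapply(sel, length, 1L))
  dose_grid(vals, geo, meta = grid$meta)
}

#' Extract an axis-aligned plane at a mm coordinate
#'
#' If the coordinate aligns with a slice center (to within 1e-6 of the
#' spacing) that slice is returned bit-exactly; otherwise the two
#' bracketing slices are linearly interpolated.
#'
#' @param grid A [dose_grid()].
#' @param axis `"x"`, `"y"` or `"z"` (or 1:3), the axis normal to the plane.
#' @param coordinate Position of the plane in mm; must lie within the grid
#'   extent along `axis`.
#' @return A [dose_grid()] with a singleton dimension on `axis`, positioned
#'   at `coordinate`.
#' @export
extract_plane <- function(grid, axis, coordinate) {
  stopifnot(inherits(grid, "dose_grid"))
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  stopifnot(axis %in% 1:3)
  g <- grid$geometry
  t <- (coordinate - g$origin[axis]) / g$spacing[axis]
  if (t < -1e-9 || t > g$shape[axis] - 1 + 1e-9) {
    stop("plane coordinate lies outside the grid extent")
  }
  t <- min(max(t, 0), g$shape[axis] - 1)
  idx <- list(seq_len(g$shape[1]), seq_len(g$shape[2]), seq_len(g$shape[3]))
  if (abs(t - round(t)) < 1e-6) {
    idx[[axis]] <- round(t) + 1
    vals <- grid$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    i0 <- floor(t); f <- t - i0
    idx0 <- idx; idx0[[axis]] <- i0 + 1
    idx1 <- idx; idx1[[axis]] <- i0 + 2
    vals <- (1 - f) * grid$values[idx0[[1]], idx0[[2]], idx0[[3]], drop = FALSE] +
            f * grid$values[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE]
  }
  org <- g$origin; org[axis] <- coordinate
  shp <- g$shape; shp[axis] <- 1L
  dose_grid(array(vals, dim = shp), grid_geometry(org, g$spacing, shp),
            meta = grid$meta)
}

#' Sample a straight-line dose profile between two mm points
#'
#' @param grid A [dose_grid()].
#' @param start,end Length-3 mm positions.
#' @param step Sampling step along the line in mm.
#' @return A data frame with columns `distance_mm`, `x`, `y`, `z` and
#'   `dose_gy`.
#' @export
line_profile <- function(grid, start, end, step = 0.5) {
  stopifnot(inherits(grid, "dose_grid"), step > 0)
  start <- as.numeric(start); end <- as.numeric(end)
  len <- sqrt(sum((end - start)^2))
  t <- seq(0, len, by = step)
  if (len - t[length(t)] > 1e-9) t <- c(t, len)
  u <- if (len > 0) (end - start) / len else c(0, 0, 0)
  pts <- cbind(start[1] + t * u[1], start[2] + t * u[2], start[3] + t * u[3])
  data.frame(distance_mm = t, x = pts[, 1], y = pts[, 2], z = pts[, 3],
             dose_gy = sample_grid(grid, pts[, 1], pts[, 2], pts[, 3]))
}
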
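# Grid geometry and dose-grid containers. All public coordinates are mm in
# the Leksell stereotactic frame, axis order (X, Y, Z), voxel-center
# convention: voxel [i, j, k] (1-based) is centered at
# origin + (i-1, j-1, k-1) * spacing.

#' Define the geometry of a regular 3D grid in the Leksell frame
#'
#' @param origin Numeric length-3, mm position of the center of voxel
#'   `[1, 1, 1]` on the (X, Y, Z) axes.
#' @param spacing Numeric length-3, voxel spacing in mm; all entries must be
#'   positive.
#' @param shape Integer length-3, voxel counts per axis; all entries must be
#'   at least 1.
#' @return An object of class `grid_geometry`.
#' @examples
#' # the 2.5 mm planning grid used for the reference dose calculation
#' grid_geometry(c(60, 60, 60), c(2.5, 2.5, 2.5), c(33, 33, 33))
#' @export
grid_geometry <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(round(as.numeric(shape)))
  if (length(origin) != 3L || length(spacing) != 3L || length(shape) != 3L) {
    stop("origin, spacing and shape must each have length 3")
  }
  if (any(!is.finite(origin))) stop("origin must be finite")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be positive on all axes")
  }
  if (any(is.na(shape)) || any(shape < 1L)) {
    stop("shape must be >= 1 on all axes")
  }
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  ext <- geom_extent(x)
  cat("<grid_geometry> ", paste(x$shape, collapse = " x "), " voxels, ",
      paste(format(x$spacing), collapse = " x "), " mm spacing\n", sep = "")
  cat("  extent (mm): X [", ext["min", 1], ", ", ext["max", 1], "]  Y [",
      ext["min", 2], ", ", ext["max", 2], "]  Z [", ext["min", 3], ", ",
      ext["max", 3], "]\n", sep = "")
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param geom A [grid_geometry()].
#' @param axis Axis index 1 (X), 2 (Y) or 3 (Z).
#' @return Numeric vector of voxel-center positions in mm.
#' @export
geom_coords <- function(geom, axis) {
  stopifnot(inherits(geom, "grid_geometry"), axis %in% 1:3)
  geom$origin[axis] + (seq_len(geom$shape[axis]) - 1) * geom$spacing[axis]
}

#' Extent of a grid (first to last voxel center) in mm
#'
#' @param geom A [grid_geometry()].
#' @return A 2x3 matrix with rows `min` and `max`.
#' @export
geom_extent <- function(geom) {
  stopifnot(inherits(geom, "grid_geometry"))
  m <- rbind(min = geom$origin,
             max = geom$origin + (geom$shape - 1) * geom$spacing)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Test whether two grid geometries coincide
#'
#' @param a,b [grid_geometry()] objects.
#' @param tol Absolute tolerance in mm for origin and spacing.
#' @export
geom_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Axis-aligned box with inclusive mm bounds
#'
#' Boxes select voxels by their center position; both endpoints are
#' inclusive.
#'
#' @param xlim,ylim,zlim Length-2 numeric, `c(min, max)` in mm.
#' @return An object of class `box_mm`.
#' @examples
#' # analysis subvolume enclosing the three shots
#' box_mm(c(70, 115), c(65, 125), c(90, 114))
#' @export
box_mm <- function(xlim, ylim, zlim) {
  lims <- rbind(x = as.numeric(xlim), y = as.numeric(ylim),
                z = as.numeric(zlim))
  if (ncol(lims) != 2L || any(!is.finite(lims))) {
    stop("xlim, ylim and zlim must each be finite length-2 numerics")
  }
  if (any(lims[, 1] > lims[, 2])) stop("box min must be <= max on every axis")
  structure(list(min = lims[, 1], max = lims[, 2]), class = "box_mm")
}

#' Build a grid geometry covering a box at a given spacing
#'
#' The grid starts at the box minimum and includes every lattice point whose
#' center lies inside the (inclusive) box.
#'
#' @param box A [box_mm()].
#' @param spacing Scalar or length-3 spacing in mm.
#' @return A [grid_geometry()].
#' @export
geometry_from_box <- function(box, spacing = 1) {
  stopifnot(inherits(box, "box_mm"))
  spacing <- rep_len(as.numeric(spacing), 3L)
  shape <- floor((box$max - box$min) / spacing + 1e-9) + 1
  grid_geometry(box$min, spacing, shape)
}

#' A 3D dose grid in the Leksell frame
#'
#' @param values 3D numeric array of absorbed dose in Gy; `NA` marks
#'   no-data voxels.
#' @param geometry A [grid_geometry()] whose shape matches `dim(values)`.
#' @param meta Optional named list of provenance metadata carried through
#'   file round trips.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, geometry, meta = list()) {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!all(dim(values) == geometry$shape)) {
    stop("dim(values) does not match geometry$shape")
  }
  storage.mode(values) <- "double"
  structure(list(values = values, geometry = geometry, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  v <- x$values
  cat("<dose_grid> ", paste(dim(v), collapse = " x "), " voxels\n", sep = "")
  cat("  dose (Gy): min ", format(suppressWarnings(min(v, na.rm = TRUE))),
      ", max ", format(suppressWarnings(max(v, na.rm = TRUE))),
      ", no-data ", sum(is.na(v)), "\n", sep = "")
  print(x$geometry)
  invisible(x)
}

# internal: voxel index (1-based triple) closest to a mm position
.nearest_voxel <- function(geom, pos) {
  idx <- round((pos - geom$origin) / geom$spacing) + 1
  pmin(pmax(idx, 1), geom$shape)
}
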
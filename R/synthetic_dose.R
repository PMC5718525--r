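# Synthetic dose engine: a smooth analytic multi-shot kernel with azimuthal
# plug shielding, plus the virtual measurement model (resampling to the gel
# readout geometry, sensitivity scaling, Gaussian blur, multiplicative
# noise). The kernel is a qualitative stand-in for a treatment planning
# system: a single maximum per shot, monotone falloff with a penumbra width
# tied to the collimator size, and one-sided falloff inside plugged wedges.

# run expr with a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# 1D sigmoidal shot profile: ~1 inside the collimator radius, smooth
# monotone falloff with penumbra width collimator/10
.shot_profile <- function(u, fwhm) {
  1 / (1 + exp((abs(u) - fwhm / 2) / (fwhm / 10)))
}

# azimuthal plug transmission factor at axial offsets (dx, dy) from the
# shot axis; wedge edges are smoothed over `edge_deg` and the wedge effect
# ramps in radially over ~rho0 mm so the field stays smooth on the axis
.plug_factor <- function(dx, dy, sectors, edge_deg = 10, rho0 = 2) {
  if (length(sectors) == 0L) return(1)
  phi <- (atan2(dy, dx) * 180 / pi) %% 360
  rho2 <- dx^2 + dy^2
  radial <- rho2 / (rho2 + rho0^2)
  fac <- 1
  for (s in sectors) {
    # circular angular distance to the closed sector [start, end]
    inside <- phi >= s["start"] & phi <= s["end"]
    d1 <- pmin(abs(phi - s["start"]), 360 - abs(phi - s["start"]))
    d2 <- pmin(abs(phi - s["end"]), 360 - abs(phi - s["end"]))
    d <- ifelse(inside, 0, pmin(d1, d2))
    m <- ifelse(d < edge_deg, 0.5 * (1 + cos(pi * d / edge_deg)), 0)
    m[inside] <- 1
    fac <- fac * (1 - (1 - s["transmission"]) * m * radial)
  }
  fac
}

#' Evaluate the raw (unnormalized) plan dose at arbitrary points
#'
#' Sum over shots of `weight * profile(x) * profile(y) * profile(z) *
#' plug_factor`, before any prescription rescaling. The rescale factor that
#' [generate_calculated_dose()] applied to a grid is stored in its
#' `meta$rescale`, so analytic values comparable with a generated grid are
#' `evaluate_plan_dose(...) * rescale`.
#'
#' @param plan A [plan_spec()].
#' @param x,y,z Numeric vectors of equal length, positions in mm.
#' @return Numeric vector of raw dose values (arbitrary units, >= 0).
#' @export
evaluate_plan_dose <- function(plan, x, y, z) {
  stopifnot(inherits(plan, "plan_spec"))
  total <- numeric(length(x))
  for (s in plan$shots) {
    k <- .shot_profile(x - s$isocenter[1], s$collimator) *
         .shot_profile(y - s$isocenter[2], s$collimator) *
         .shot_profile(z - s$isocenter[3], s$collimator)
    k <- k * .plug_factor(x - s$isocenter[1], y - s$isocenter[2],
                          s$plug_sectors)
    total <- total + s$weight * k
  }
  total
}

#' Generate the reference ("calculated") dose grid for a plan
#'
#' Evaluates the analytic multi-shot kernel on the grid and rescales so the
#' grid maximum equals `prescription_dose / prescription_isodose` (16 Gy for
#' 8 Gy prescribed to the 50% isodose).
#'
#' @param plan A [plan_spec()].
#' @param geometry A [grid_geometry()]; every shot isocenter must lie inside
#'   its extent.
#' @return A [dose_grid()] with maximum `prescription_dose /
#'   prescription_isodose`; the applied rescale factor is stored in
#'   `meta$rescale`.
#' @export
generate_calculated_dose <- function(plan, geometry) {
  stopifnot(inherits(plan, "plan_spec"), inherits(geometry, "grid_geometry"))
  ext <- geom_extent(geometry)
  for (i in seq_along(plan$shots)) {
    iso <- plan$shots[[i]]$isocenter
    if (any(iso < ext["min", ] - 1e-9) || any(iso > ext["max", ] + 1e-9)) {
      stop(sprintf("shot %d isocenter (%g, %g, %g) lies outside the dose grid",
                   i, iso[1], iso[2], iso[3]))
    }
  }
  cx <- geom_coords(geometry, 1)
  cy <- geom_coords(geometry, 2)
  cz <- geom_coords(geometry, 3)
  nx <- length(cx); ny <- length(cy); nz <- length(cz)
  px <- rep(cx, times = ny * nz)
  py <- rep(rep(cy, each = nx), times = nz)
  pz <- rep(cz, each = nx * ny)
  raw <- evaluate_plan_dose(plan, px, py, pz)
  mx <- max(raw)
  if (mx <= 0) stop("plan delivers no dose inside the grid")
  rescale <- (plan$prescription_dose / plan$prescription_isodose) / mx
  dose_grid(array(raw * rescale, dim = c(nx, ny, nz)), geometry,
            meta = list(rescale = rescale))
}

#' Specify the virtual-measurement noise model
#'
#' @param dose_noise_sigma Multiplicative Gaussian noise as a fraction of
#'   the local dose (0.015 = 1.5%).
#' @param blur_fwhm Isotropic Gaussian blur FWHM in mm (gel diffusion and
#'   imaging point spread).
#' @param sensitivity_factor Gel response scale: the simulated measurement
#'   reads `sensitivity_factor * dose`. The default 1/0.85 makes the gel
#'   over-respond so that the downstream measured-to-calculated comparison
#'   recovers a 0.85 dose scaling factor.
#' @param seed Integer RNG seed, or `NULL` to draw from the current stream.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(dose_noise_sigma = 0.015, blur_fwhm = 0.5,
                       sensitivity_factor = 1 / 0.85, seed = NULL) {
  if (!is.finite(dose_noise_sigma) || dose_noise_sigma < 0) {
    stop("dose_noise_sigma must be >= 0")
  }
  if (!is.finite(blur_fwhm) || blur_fwhm < 0) stop("blur_fwhm must be >= 0")
  if (!is.finite(sensitivity_factor) || sensitivity_factor <= 0) {
    stop("sensitivity_factor must be > 0")
  }
  structure(list(dose_noise_sigma = dose_noise_sigma, blur_fwhm = blur_fwhm,
                 sensitivity_factor = sensitivity_factor, seed = seed),
            class = "noise_spec")
}

# separable normalized Gaussian convolution; NA voxels stay NA and do not
# contaminate their neighbours
gaussian_blur <- function(values, spacing, fwhm) {
  if (fwhm <= 0) return(values)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  na_mask <- is.na(values)
  v <- values
  v[na_mask] <- 0
  w <- (!na_mask) * 1
  shift_axis <- function(a, axis, k) {
    if (k == 0) return(a)
    n <- dim(a)[axis]
    idx <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
    src <- seq_len(n) - k
    pad <- src < 1 | src > n
    src[pad] <- 1
    idx[[axis]] <- src
    out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    dim(out) <- dim(a)
    padidx <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
    padidx[[axis]] <- which(pad)
    if (length(padidx[[axis]])) out[padidx[[1]], padidx[[2]], padidx[[3]]] <- 0
    out
  }
  for (axis in 1:3) {
    r <- ceiling(3 * sigma / spacing[axis])
    if (r < 1) next
    kk <- (-r):r
    kern <- exp(-0.5 * (kk * spacing[axis] / sigma)^2)
    kern <- kern / sum(kern)
    num <- array(0, dim(v)); den <- array(0, dim(v))
    for (j in seq_along(kk)) {
      num <- num + kern[j] * shift_axis(v, axis, kk[j])
      den <- den + kern[j] * shift_axis(w, axis, kk[j])
    }
    v <- ifelse(den > 0, num / den, 0)
    # weights stay binary per axis pass so edges renormalize correctly
  }
  v[na_mask] <- NA_real_
  v
}

#' Simulate a gel dose measurement of a calculated grid
#'
#' The virtual measurement resamples the calculated dose to the readout
#' geometry, applies multiplicative Gaussian dose noise, scales by the gel
#' sensitivity factor, and blurs with an isotropic Gaussian. With all noise
#' terms off and matching geometry the output is identical to the input.
#'
#' @param calc A [dose_grid()] with finite, non-negative dose.
#' @param noise A [noise_spec()].
#' @param geometry Target readout geometry, or `NULL` to keep the geometry
#'   of `calc`. The gel study reads out at 0.5 x 0.5 mm in-plane with 2 mm
#'   slices.
#' @return A [dose_grid()] on the readout geometry. Deterministic given
#'   `noise$seed`.
#' @export
simulate_measured_dose <- function(calc, noise, geometry = NULL) {
  stopifnot(inherits(calc, "dose_grid"), inherits(noise, "noise_spec"))
  finite <- calc$values[!is.na(calc$values)]
  if (any(!is.finite(finite)) || any(finite < 0)) {
    stop("calculated dose must be finite and non-negative")
  }
  out <- if (is.null(geometry)) calc else resample_grid(calc, geometry)
  v <- out$values
  if (noise$dose_noise_sigma > 0) {
    eps <- with_seed(noise$seed, stats::rnorm(length(v)))
    v <- v * (1 + noise$dose_noise_sigma * eps)
  }
  v <- v * noise$sensitivity_factor
  v <- gaussian_blur(v, out$geometry$spacing, noise$blur_fwhm)
  dose_grid(v, out$geometry,
            meta = c(out$meta, list(noise = unclass(noise))))
}

#' Default readout geometry of the gel study
#'
#' 0.5 x 0.5 mm in-plane pixels with 2 mm slices, covering the analysis
#' subvolume with a small margin so resampling to the 1 mm comparison grid
#' has full support.
#'
#' @return A [grid_geometry()].
#' @export
gel_readout_geometry <- function() {
  grid_geometry(c(68, 63, 88), c(0.5, 0.5, 2), c(99, 129, 15))
}

#' Default planning-grid geometry of the gel study
#'
#' The 2.5 mm isotropic calculation grid, spanning 60-140 mm on each axis
#' of the Leksell frame.
#'
#' @return A [grid_geometry()].
#' @export
planning_geometry <- function() {
  grid_geometry(c(60, 60, 60), c(2.5, 2.5, 2.5), c(33, 33, 33))
}
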
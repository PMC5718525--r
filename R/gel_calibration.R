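# Linear R2-dose calibration from irradiated vials, R2-to-dose conversion,
# and the measured-versus-calculated dose scaling factor.

#' Construct a gel calibration directly
#'
#' @param slope Response slope in s^-1 Gy^-1 (must be positive).
#' @param intercept R2 at zero dose, s^-1.
#' @param dose_range Length-2 calibrated dose range in Gy.
#' @param residuals,r_squared Optional fit diagnostics.
#' @param n_vials Optional number of vials the fit used.
#' @return An object of class `gel_calibration`.
#' @export
gel_calibration <- function(slope, intercept, dose_range = c(0, 17),
                            residuals = numeric(0), r_squared = NA_real_,
                            n_vials = NA_integer_) {
  if (!is.finite(slope) || slope <= 0) {
    stop("gel response slope must be positive")
  }
  dose_range <- as.numeric(dose_range)
  if (length(dose_range) != 2L || dose_range[1] >= dose_range[2]) {
    stop("dose_range must be an increasing length-2 numeric")
  }
  structure(list(slope = slope, intercept = intercept,
                 dose_range = dose_range, residuals = residuals,
                 r_squared = r_squared, n_vials = n_vials),
            class = "gel_calibration")
}

#' @export
print.gel_calibration <- function(x, ...) {
  cat(sprintf("<gel_calibration> R2 = %.4g + %.4g * D  (s^-1, D in Gy)\n",
              x$intercept, x$slope))
  cat(sprintf("  dose range %g-%g Gy, R^2 = %s, %s vials\n",
              x$dose_range[1], x$dose_range[2],
              format(x$r_squared), format(x$n_vials)))
  invisible(x)
}

#' Read a vial calibration table from CSV
#'
#' Expected columns: `dose_gy`, `r2_s1` (mean R2 over the vial ROI),
#' optionally `sd_r2` and `n_voxels`.
#'
#' @param path CSV path.
#' @return A data frame validated as a vial table.
#' @export
read_vial_table <- function(path) {
  df <- utils::read.csv(path)
  .check_vial_table(df)
  df
}

.check_vial_table <- function(df) {
  if (!all(c("dose_gy", "r2_s1") %in% names(df))) {
    stop("vial table needs columns dose_gy and r2_s1")
  }
  if (anyDuplicated(df$dose_gy)) stop("vial doses must be unique")
  if (any(df$dose_gy < 0)) stop("vial doses must be >= 0")
  invisible(df)
}

#' Generate a synthetic vial calibration table
#'
#' Eleven vials spanning 0-17 Gy by default, with mean R2 on (optionally
#' noisy samples of) the linear response whose endpoints are 1.65 s^-1 at
#' 0 Gy and 83 s^-1 at 17 Gy.
#'
#' @param doses Vial doses in Gy.
#' @param slope,intercept Line parameters (s^-1 Gy^-1 and s^-1).
#' @param noise_sd Gaussian noise SD on the vial mean R2, s^-1.
#' @param seed Integer RNG seed, or `NULL`.
#' @param n_voxels Reported ROI voxel count per vial.
#' @return A data frame with columns `dose_gy`, `r2_s1`, `sd_r2`,
#'   `n_voxels`.
#' @export
synthetic_vial_table <- function(doses = seq(0, 17, length.out = 11),
                                 slope = (83 - 1.65) / 17, intercept = 1.65,
                                 noise_sd = 0, seed = NULL, n_voxels = 200) {
  r2 <- intercept + slope * doses
  if (noise_sd > 0) {
    r2 <- r2 + with_seed(seed, stats::rnorm(length(doses), sd = noise_sd))
  }
  data.frame(dose_gy = doses, r2_s1 = r2, sd_r2 = rep(noise_sd, length(doses)),
             n_voxels = rep(n_voxels, length(doses)))
}

#' Fit the linear R2-dose calibration from vial data
#'
#' Ordinary least squares of the vial mean R2 on the delivered dose. The
#' residuals are kept for the randomness diagnostic (a sound linear fit
#' leaves residuals scattered around zero with no trend).
#'
#' @param vials A vial table (see [read_vial_table()]) with at least three
#'   vials.
#' @return A [gel_calibration()] with residuals and R^2 populated and
#'   `dose_range` set to the span of the vial doses.
#' @export
fit_linear_calibration <- function(vials) {
  .check_vial_table(vials)
  if (nrow(vials) < 3L) stop("at least 3 vials are required for calibration")
  fit <- stats::lm(r2_s1 ~ dose_gy, data = vials)
  cf <- stats::coef(fit)
  if (!is.finite(cf[["dose_gy"]]) || cf[["dose_gy"]] <= 0) {
    stop("fitted gel response slope is not positive; check the vial data")
  }
  gel_calibration(slope = unname(cf[["dose_gy"]]),
                  intercept = unname(cf[["(Intercept)"]]),
                  dose_range = range(vials$dose_gy),
                  residuals = unname(stats::residuals(fit)),
                  r_squared = suppressWarnings(summary(fit)$r.squared),
                  n_vials = nrow(vials))
}

#' The bundled gel calibration
#'
#' Fit of the shipped 11-vial table (0-17 Gy, linear response from
#' 1.65 to 83 s^-1).
#'
#' @return A [gel_calibration()].
#' @export
default_gel_calibration <- function() {
  fit_linear_calibration(read_vial_table(
    system.file("extdata", "vial_calibration.csv",
                package = "plugdose", mustWork = TRUE)))
}

#' Convert an R2 map to a dose grid via the linear calibration
#'
#' `dose = (R2 - intercept) / slope`. Invalid map voxels become no-data.
#' Doses falling outside the calibrated range are clamped to it
#' (`clamp = "clamp"`), marked no-data (`clamp = "mark"`), or kept on the
#' extrapolated line (`clamp = "none"` — appropriate before a dose
#' scaling factor is applied, when the raw gel dose may legitimately
#' overshoot the calibrated range).
#'
#' @param map An `r2_map` from [fit_r2_map()].
#' @param cal A [gel_calibration()].
#' @param clamp Out-of-range policy, `"clamp"`, `"mark"` or `"none"`.
#' @return A [dose_grid()] on the map geometry.
#' @export
r2_to_dose <- function(map, cal, clamp = c("clamp", "mark", "none")) {
  stopifnot(inherits(map, "r2_map"), inherits(cal, "gel_calibration"))
  clamp <- match.arg(clamp)
  dose <- (map$r2 - cal$intercept) / cal$slope
  dose[!map$valid] <- NA_real_
  low <- cal$dose_range[1]; high <- cal$dose_range[2]
  if (clamp == "clamp") {
    dose <- pmin(pmax(dose, low), high)
  } else if (clamp == "mark") {
    dose[dose < low | dose > high] <- NA_real_
  }
  dose_grid(array(dose, dim = map$geometry$shape), map$geometry)
}

#' Derive the measured-to-calculated dose scaling factor
#'
#' Ratio of means `mean(calculated) / mean(measured)` over a relatively
#' uniform high-dose region. If the grids differ in geometry both are
#' first resampled onto a common isotropic grid spanning the overlap of
#' their extents (1 mm by default, matching the comparison grid). By
#' default the region is the interior of the 80% isodose of the
#' calculated grid (the flattest available dose plateau); pass a
#' [box_mm()] to choose explicitly.
#'
#' @param measured,calculated [dose_grid()] objects.
#' @param region A [box_mm()] or `NULL` for the default isodose region.
#' @param isodose_fraction Fraction of the calculated maximum defining the
#'   default region (0.8).
#' @param common_spacing Spacing in mm of the common grid used when the
#'   inputs differ in geometry.
#' @return Scalar scaling factor; multiplying the measured dose by it
#'   matches the calculated dose in the region (see [apply_scaling()]).
#' @export
derive_scaling_factor <- function(measured, calculated, region = NULL,
                                  isodose_fraction = 0.8,
                                  common_spacing = 1) {
  stopifnot(inherits(measured, "dose_grid"), inherits(calculated, "dose_grid"))
  if (!geom_equal(measured$geometry, calculated$geometry)) {
    em <- geom_extent(measured$geometry)
    ec <- geom_extent(calculated$geometry)
    lo <- pmax(em["min", ], ec["min", ])
    hi <- pmin(em["max", ], ec["max", ])
    if (any(lo > hi)) stop("measured and calculated extents do not overlap")
    common <- geometry_from_box(box_mm(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                       c(lo[3], hi[3])), common_spacing)
    measured <- resample_grid(measured, common)
    calculated <- resample_grid(calculated, common)
  }
  mv <- measured$values
  cv <- calculated$values
  keep <- !is.na(mv) & !is.na(cv)
  if (is.null(region)) {
    mx <- max(cv, na.rm = TRUE)
    keep <- keep & cv >= isodose_fraction * mx
  } else {
    stopifnot(inherits(region, "box_mm"))
    g <- calculated$geometry
    cx <- geom_coords(g, 1); cy <- geom_coords(g, 2); cz <- geom_coords(g, 3)
    inx <- cx >= region$min[1] - 1e-9 & cx <= region$max[1] + 1e-9
    iny <- cy >= region$min[2] - 1e-9 & cy <= region$max[2] + 1e-9
    inz <- cz >= region$min[3] - 1e-9 & cz <= region$max[3] + 1e-9
    inbox <- outer(outer(inx, iny, "&"), inz, "&")
    keep <- keep & inbox
  }
  if (!any(keep)) stop("scaling region is empty in the common grid")
  m_mean <- mean(mv[keep])
  if (m_mean == 0) stop("measured dose averages to zero in the scaling region")
  mean(cv[keep]) / m_mean
}

#' Apply a dose scaling factor
#'
#' @param grid A [dose_grid()].
#' @param factor Scalar multiplier.
#' @return The rescaled [dose_grid()].
#' @export
apply_scaling <- function(grid, factor) {
  stopifnot(inherits(grid, "dose_grid"), is.finite(factor))
  dose_grid(grid$values * factor, grid$geometry, meta = grid$meta)
}
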
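# Measured-versus-calculated comparison statistics: dose difference, gamma
# index (dose-difference / distance-to-agreement) with pass-rate tables,
# cumulative DVH, differential-DVH difference (DDDVH), dose-dependent
# dose-difference (D4) diagram, line profiles and isodose contours.

#' Voxelwise dose difference (measured minus calculated)
#'
#' @param measured,calculated [dose_grid()] objects on a common geometry.
#' @return A [dose_grid()]; no-data in either input propagates.
#' @export
dose_difference <- function(measured, calculated) {
  stopifnot(inherits(measured, "dose_grid"), inherits(calculated, "dose_grid"))
  if (!geom_equal(measured$geometry, calculated$geometry)) {
    stop("dose grids must share a common geometry; resample first")
  }
  dose_grid(measured$values - calculated$values, measured$geometry)
}

#' Gamma-evaluation parameters
#'
#' @param dose_tol Dose tolerance as % of the normalization dose.
#' @param dta Distance-to-agreement tolerance in mm.
#' @param normalization_dose Global normalization in Gy; `NULL` uses the
#'   maximum of the reference (calculated) grid.
#' @param search_radius Radius of the candidate search sphere in mm
#'   (default `3 * dta`); gamma values whose minimum sits on the sphere
#'   boundary are flagged as saturated.
#' @param interp_step Reference interpolation step in mm (default
#'   `dta / 10`, must be at most `dta / 5`).
#' @param low_dose_cutoff Optional % of normalization below which evaluated
#'   voxels are excluded; `NULL` evaluates every voxel.
#' @param local Use local normalization (tolerance as % of the local
#'   reference dose) instead of the global normalization dose.
#' @return An object of class `gamma_params`.
#' @export
gamma_params <- function(dose_tol, dta, normalization_dose = NULL,
                         search_radius = 3 * dta, interp_step = dta / 10,
                         low_dose_cutoff = NULL, local = FALSE) {
  if (!is.finite(dose_tol) || dose_tol <= 0) stop("dose_tol must be > 0")
  if (!is.finite(dta) || dta <= 0) stop("dta must be > 0")
  if (search_radius < dta) stop("search_radius must be >= dta")
  if (interp_step > dta / 5 + 1e-12) stop("interp_step must be <= dta / 5")
  structure(list(dose_tol = dose_tol, dta = dta,
                 normalization_dose = normalization_dose,
                 search_radius = search_radius, interp_step = interp_step,
                 low_dose_cutoff = low_dose_cutoff, local = local),
            class = "gamma_params")
}

# candidate offsets: the interp_step lattice inside the search sphere,
# sorted by squared distance (offset zero first)
.gamma_offsets <- function(search_radius, interp_step) {
  m <- floor(search_radius / interp_step + 1e-9)
  k <- (-m):m
  off <- as.matrix(expand.grid(x = k, y = k, z = k)) * interp_step
  d2 <- rowSums(off^2)
  keep <- d2 <= search_radius^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  list(offsets = off[ord, , drop = FALSE], d2 = d2[ord])
}

#' Gamma index of a measured grid against a calculated reference
#'
#' For each evaluated voxel the gamma value is the minimum over reference
#' positions `r_c` on an `interp_step` lattice within `search_radius` of
#' `sqrt(|r_c - r_m|^2 / dta^2 + (D_c(r_c) - D_m(r_m))^2 / dd^2)`, with
#' `dd = dose_tol/100 * normalization` (global mode). The reference dose is
#' trilinearly interpolated; candidates outside the reference support are
#' skipped. A voxel passes when gamma <= 1.
#'
#' @param calculated Reference [dose_grid()].
#' @param measured Evaluated [dose_grid()] on the same geometry (resample
#'   to a common grid, typically 1 mm isotropic, beforehand).
#' @param params A [gamma_params()].
#' @return An object of class `gamma_map`: the gamma array, a saturation
#'   mask (minimum found on the search-sphere boundary), the pass rate in
#'   %, and the evaluated voxel count.
#' @seealso [gamma_index_exhaustive()] for the brute-force reference
#'   implementation.
#' @export
gamma_index <- function(calculated, measured, params) {
  stopifnot(inherits(calculated, "dose_grid"), inherits(measured, "dose_grid"),
            inherits(params, "gamma_params"))
  if (!geom_equal(calculated$geometry, measured$geometry)) {
    stop("gamma evaluation requires a common grid; resample first")
  }
  norm <- params$normalization_dose
  if (is.null(norm)) norm <- max(calculated$values, na.rm = TRUE)
  if (!is.finite(norm) || norm <= 0) stop("normalization dose must be positive")

  ev <- measured$values
  if (!is.null(params$low_dose_cutoff)) {
    ev[ev < params$low_dose_cutoff / 100 * norm] <- NA_real_
  }
  if (all(is.na(ev))) stop("no voxels to evaluate")

  lat <- .gamma_offsets(params$search_radius, params$interp_step)
  res <- gamma_search_cpp(calculated$values, calculated$geometry$shape,
                          calculated$geometry$origin,
                          calculated$geometry$spacing,
                          ev, lat$offsets, lat$d2,
                          params$dta, params$dose_tol / 100 * norm,
                          isTRUE(params$local), params$dose_tol / 100)
  gam <- array(res$gamma, dim = dim(ev))
  sat <- array(res$saturated, dim = dim(ev))
  evaluated <- sum(!is.na(gam))
  structure(list(gamma = gam, saturated = sat, params = params,
                 normalization_dose = norm,
                 pass_rate = 100 * sum(gam <= 1, na.rm = TRUE) / evaluated,
                 evaluated_count = evaluated,
                 geometry = calculated$geometry),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf("<gamma_map> %g%%/%g mm: pass rate %.2f%% (%d voxels, %d saturated)\n",
              x$params$dose_tol, x$params$dta, x$pass_rate,
              x$evaluated_count, sum(x$saturated, na.rm = TRUE)))
  invisible(x)
}

#' Exhaustive brute-force gamma index (reference implementation)
#'
#' Independent check for [gamma_index()]: the reference grid is upsampled
#' onto the `interp_step` lattice by separable 1D linear interpolation
#' (equivalent to trilinear interpolation on aligned lattices) and every
#' candidate inside the search sphere is scanned without shortcuts.
#' Requires `interp_step` to divide the grid spacing exactly. Slow; meant
#' for validation on small grids.
#'
#' @inheritParams gamma_index
#' @return A numeric array of gamma values (NA where not evaluated).
#' @export
gamma_index_exhaustive <- function(calculated, measured, params) {
  stopifnot(inherits(calculated, "dose_grid"), inherits(measured, "dose_grid"),
            inherits(params, "gamma_params"))
  if (!geom_equal(calculated$geometry, measured$geometry)) {
    stop("gamma evaluation requires a common grid")
  }
  g <- calculated$geometry
  f <- g$spacing / params$interp_step
  if (any(abs(f - round(f)) > 1e-6)) {
    stop("interp_step must divide the grid spacing for the exhaustive search")
  }
  f <- as.integer(round(f))
  norm <- params$normalization_dose
  if (is.null(norm)) norm <- max(calculated$values, na.rm = TRUE)
  dd <- params$dose_tol / 100 * norm

  # separable upsampling of the reference onto the fine lattice
  fine <- calculated$values
  for (axis in 1:3) {
    if (f[axis] == 1L) next
    n <- dim(fine)[axis]
    xout <- seq(1, n, by = 1 / f[axis])
    fine <- apply(fine, setdiff(1:3, axis), function(line) {
      stats::approx(seq_len(n), line, xout = xout)$y
    })
    fine <- aperm(fine, order(c(axis, setdiff(1:3, axis))))
  }
  nf <- dim(fine)

  m <- floor(params$search_radius / params$interp_step + 1e-9)
  k <- (-m):m
  off <- as.matrix(expand.grid(x = k, y = k, z = k))
  d2mm <- rowSums(off^2) * params$interp_step^2
  keep <- d2mm <= params$search_radius^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  d2mm <- d2mm[keep]

  ev <- measured$values
  if (!is.null(params$low_dose_cutoff)) {
    ev[ev < params$low_dose_cutoff / 100 * norm] <- NA_real_
  }
  out <- array(NA_real_, dim = dim(ev))
  for (iz in seq_len(dim(ev)[3])) {
    fz <- (iz - 1L) * f[3] + 1L
    zi <- fz + off[, 3]
    okz <- zi >= 1L & zi <= nf[3]
    for (iy in seq_len(dim(ev)[2])) {
      fy <- (iy - 1L) * f[2] + 1L
      yi <- fy + off[, 2]
      oky <- okz & yi >= 1L & yi <= nf[2]
      for (ix in seq_len(dim(ev)[1])) {
        Dm <- ev[ix, iy, iz]
        if (is.na(Dm)) next
        fx <- (ix - 1L) * f[1] + 1L
        xi <- fx + off[, 1]
        ok <- oky & xi >= 1L & xi <= nf[1]
        lin <- xi[ok] + (yi[ok] - 1L) * nf[1] + (zi[ok] - 1L) * nf[1] * nf[2]
        Dc <- fine[lin]
        tol <- if (isTRUE(params$local)) params$dose_tol / 100 * Dc else dd
        g2 <- d2mm[ok] / params$dta^2 + (Dc - Dm)^2 / tol^2
        out[ix, iy, iz] <- sqrt(min(g2, na.rm = TRUE))
      }
    }
  }
  out
}

#' Gamma pass rates over a set of tolerance criteria
#'
#' Runs [gamma_index()] for each `(dose_tol %, dta mm)` pair on the same
#' voxel set. The default criteria are the five used for the plugged-plan
#' verification: 3%/2 mm, 3%/1 mm, 2%/2 mm, 1%/1 mm and 0.5%/0.5 mm.
#'
#' @param calculated,measured [dose_grid()] objects on a common geometry.
#' @param criteria List of length-2 numerics `c(dose_tol, dta)`.
#' @param ... Further arguments passed to [gamma_params()].
#' @return A data frame with columns `dose_tol_pct`, `dta_mm`,
#'   `pass_rate_pct`, `mean_gamma`, `evaluated`.
#' @export
pass_rate_table <- function(calculated, measured,
                            criteria = list(c(3, 2), c(3, 1), c(2, 2),
                                            c(1, 1), c(0.5, 0.5)), ...) {
  rows <- lapply(criteria, function(cr) {
    gm <- gamma_index(calculated, measured,
                      gamma_params(dose_tol = cr[1], dta = cr[2], ...))
    data.frame(dose_tol_pct = cr[1], dta_mm = cr[2],
               pass_rate_pct = gm$pass_rate,
               mean_gamma = mean(gm$gamma, na.rm = TRUE),
               evaluated = gm$evaluated_count)
  })
  do.call(rbind, rows)
}

#' Cumulative dose-volume histogram
#'
#' Relative volume (% of evaluated voxels) receiving at least each dose
#' level, with dose expressed both in Gy and as % of the normalization
#' dose. Starts at 100% and is monotone non-increasing.
#'
#' @param dose A [dose_grid()].
#' @param normalization Normalization dose in Gy (100% level); default the
#'   grid maximum.
#' @param bin_width_pct Dose step in % of normalization.
#' @return A data frame with columns `dose_pct`, `dose_gy`, `volume_pct`.
#' @export
dvh <- function(dose, normalization = NULL, bin_width_pct = 1) {
  stopifnot(inherits(dose, "dose_grid"), bin_width_pct > 0)
  d <- dose$values[!is.na(dose$values)]
  if (length(d) == 0L) stop("no voxels to histogram")
  if (is.null(normalization)) normalization <- max(d)
  stopifnot(normalization > 0)
  pct <- 100 * d / normalization
  top <- max(100, ceiling(max(pct) / bin_width_pct) * bin_width_pct)
  edges <- seq(0, top, by = bin_width_pct)
  vol <- vapply(edges, function(e) 100 * mean(pct >= e), 0)
  data.frame(dose_pct = edges, dose_gy = edges / 100 * normalization,
             volume_pct = vol)
}

#' Differential-DVH difference (DDDVH)
#'
#' Bins both grids' voxels by dose and reports, per bin, the difference in
#' voxel counts (measured minus calculated) normalized by the total voxel
#' count: a value of 0.01 means the measured dose has 1% of voxels more in
#' that bin. Bins sum to zero exactly because both histograms count the
#' same voxel set.
#'
#' @param measured,calculated [dose_grid()] objects on a common geometry.
#' @param normalization Normalization dose in Gy; default the calculated
#'   maximum.
#' @param bin_width_pct Bin width in % of normalization.
#' @return A data frame with columns `bin_low_pct`, `bin_high_pct`,
#'   `bin_center_pct`, `delta` (signed fraction of total voxels).
#' @export
dddvh <- function(measured, calculated, normalization = NULL,
                  bin_width_pct = 1) {
  stopifnot(inherits(measured, "dose_grid"), inherits(calculated, "dose_grid"))
  if (!geom_equal(measured$geometry, calculated$geometry)) {
    stop("dose grids must share a common geometry")
  }
  keep <- !is.na(measured$values) & !is.na(calculated$values)
  mv <- measured$values[keep]
  cv <- calculated$values[keep]
  n <- length(mv)
  if (n == 0L) stop("no common voxels")
  if (is.null(normalization)) normalization <- max(cv)
  mp <- 100 * mv / normalization
  cp <- 100 * cv / normalization
  lo <- floor(min(0, mp, cp) / bin_width_pct) * bin_width_pct
  hi <- ceiling((max(mp, cp) + 1e-9) / bin_width_pct) * bin_width_pct
  breaks <- seq(lo, hi + bin_width_pct, by = bin_width_pct)
  nm <- tabulate(findInterval(mp, breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1)
  nc <- tabulate(findInterval(cp, breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1)
  data.frame(bin_low_pct = breaks[-length(breaks)],
             bin_high_pct = breaks[-1],
             bin_center_pct = (breaks[-1] + breaks[-length(breaks)]) / 2,
             delta = (nm - nc) / n)
}

#' Dose-dependent dose-difference (D4) diagram
#'
#' Voxels are binned by the calculated dose as % of the normalization
#' dose; each bin reports the mean and SD of the percent dose difference
#' `100 * (measured - calculated) / calculated` (local denominator).
#' Voxels with zero calculated dose are excluded from the ratio and
#' reported in the `excluded_zero_dose` attribute.
#'
#' @param measured,calculated [dose_grid()] objects on a common geometry.
#' @param normalization Normalization dose in Gy; default the calculated
#'   maximum.
#' @param bin_width_pct Bin width in % of normalization (default 5).
#' @return A data frame with columns `bin_center_pct`, `mean_diff_pct`,
#'   `sd_diff_pct`, `n`.
#' @export
d4_diagram <- function(measured, calculated, normalization = NULL,
                       bin_width_pct = 5) {
  stopifnot(inherits(measured, "dose_grid"), inherits(calculated, "dose_grid"))
  if (!geom_equal(measured$geometry, calculated$geometry)) {
    stop("dose grids must share a common geometry")
  }
  keep <- !is.na(measured$values) & !is.na(calculated$values)
  mv <- measured$values[keep]
  cv <- calculated$values[keep]
  if (is.null(normalization)) normalization <- max(cv)
  nonzero <- cv > 0
  excluded <- sum(!nonzero)
  mv <- mv[nonzero]; cv <- cv[nonzero]
  pct <- 100 * cv / normalization
  rel <- 100 * (mv - cv) / cv
  edges <- seq(0, max(100, ceiling(max(pct) / bin_width_pct) * bin_width_pct),
               by = bin_width_pct)
  bin <- findInterval(pct, edges, rightmost.closed = TRUE)
  agg <- lapply(seq_len(length(edges) - 1), function(b) {
    r <- rel[bin == b]
    data.frame(bin_center_pct = (edges[b] + edges[b + 1]) / 2,
               mean_diff_pct = if (length(r)) mean(r) else NA_real_,
               sd_diff_pct = if (length(r) > 1) stats::sd(r) else
                 if (length(r) == 1) 0 else NA_real_,
               n = length(r))
  })
  out <- do.call(rbind, agg)
  attr(out, "excluded_zero_dose") <- excluded
  out
}

#' Isodose contours of a dose plane
#'
#' Marching-squares contour polylines at the requested dose levels, in mm
#' coordinates of the plane.
#'
#' @param plane A [dose_grid()] with exactly one singleton dimension.
#' @param levels_gy Dose levels in Gy.
#' @return A list of data frames with columns `level_gy` and the two
#'   in-plane mm coordinates; levels above the plane maximum yield no
#'   entries.
#' @export
isodose_contours <- function(plane, levels_gy) {
  stopifnot(inherits(plane, "dose_grid"))
  shp <- plane$geometry$shape
  flat <- which(shp == 1L)
  if (length(flat) != 1L) stop("plane must have exactly one singleton axis")
  axes <- setdiff(1:3, flat)
  m <- plane$values
  dim(m) <- shp[axes]
  c1 <- geom_coords(plane$geometry, axes[1])
  c2 <- geom_coords(plane$geometry, axes[2])
  nm <- c("x", "y", "z")[axes]
  cl <- grDevices::contourLines(x = c1, y = c2, z = m, levels = levels_gy)
  lapply(cl, function(li) {
    out <- data.frame(level_gy = li$level, a = li$x, b = li$y)
    names(out)[2:3] <- nm
    out
  })
}

#' Convert a relative isodose level to absolute dose
#'
#' @param percent Isodose level in % of the normalization dose.
#' @param normalization Normalization dose in Gy (the 100% level), > 0.
#' @return Dose in Gy: `percent / 100 * normalization`.
#' @examples
#' relative_to_absolute(50, 16)   # the 8 Gy prescription isodose
#' relative_to_absolute(90, 4)    # 3.6 Gy on the film plane
#' @export
relative_to_absolute <- function(percent, normalization) {
  if (!all(is.finite(normalization)) || any(normalization <= 0)) {
    stop("normalization must be positive")
  }
  percent / 100 * normalization
}
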
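# Radiochromic film processing: scan averaging, optical-density conversion,
# per-channel quartic OD-dose calibration with working-channel selection,
# and 2D dose-map production. The companion simulator (simulate_film_scan)
# inverts the same response so the pipeline is exercisable without scans.

FILM_CHANNELS <- c("red", "green", "blue")

#' A flatbed RGB film scan
#'
#' @param pixels 3D numeric array `(nx, ny, 3)` of transmission counts in
#'   `[1, 65535]` (16 bits per channel; values may be non-integer after
#'   averaging).
#' @param dpi Scan resolution in dots per inch.
#' @param scan_ids Identifiers of the scans averaged into this object.
#' @param geometry Optional in-plane [grid_geometry()] (singleton Z) tying
#'   pixels to Leksell mm coordinates.
#' @return An object of class `film_scan`.
#' @export
film_scan <- function(pixels, dpi = 150, scan_ids = 1L, geometry = NULL) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be an (nx, ny, 3) array")
  }
  if (any(!is.finite(pixels)) || any(pixels < 1) || any(pixels > 65535)) {
    stop("pixel counts must lie in [1, 65535]")
  }
  structure(list(pixels = pixels, dpi = dpi, scan_ids = scan_ids,
                 geometry = geometry),
            class = "film_scan")
}

#' Synthetic film response (dose as a quartic in optical density)
#'
#' Defines, per channel, the monotone response `dose = q(OD)` with
#' `q(0) = 0` and positive coefficients, together with the unexposed
#' reference pixel value. The red channel has the largest OD change per Gy,
#' mirroring its selection as the working channel; green and blue span
#' 0.6 and 0.4 of the red OD range. The inverse (dose to OD), needed by the
#' scan simulator, is tabulated on a dense monotone spline.
#'
#' @param dose_range Calibrated dose range in Gy (0-10 for the red
#'   channel).
#' @param reference Unexposed pixel value per channel.
#' @return An object of class `film_response`.
#' @export
film_response <- function(dose_range = c(0, 10),
                          reference = c(red = 42000, green = 48000, blue = 52000)) {
  base <- c(9, 8, 5, 3)                       # red: dose = 9 od + 8 od^2 + ...
  scale <- c(red = 1, green = 0.6, blue = 0.4)
  channels <- lapply(scale, function(s) {
    cf <- base / s^(1:4)
    od_hi <- stats::uniroot(function(x) .polyval(c(0, cf), x) - dose_range[2],
                            c(0, 5), tol = 1e-12)$root
    od_s <- seq(0, od_hi * 1.02, length.out = 4001)
    dose_s <- .polyval(c(0, cf), od_s)
    list(coef = c(0, cf), od_max = od_hi,
         od_of_dose = stats::splinefun(dose_s, od_s, method = "monoH.FC"))
  })
  names(channels) <- FILM_CHANNELS
  structure(list(channels = channels, reference = reference,
                 dose_range = dose_range),
            class = "film_response")
}

.polyval <- function(coef, x) {
  # coef[1] + coef[2] x + ... + coef[n] x^(n-1)
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' Simulate a flatbed scan of a film exposed to a dose plane
#'
#' Dose maps to per-channel optical density through the inverse of the
#' film response, and OD to transmission counts via
#' `pixel = reference * 10^-OD`. Optional additive Gaussian scanner noise
#' in counts. Pixels stay continuous; quantization to 16-bit integers
#' happens only on TIFF export.
#'
#' @param dose_plane A [dose_grid()] with a singleton Z dimension.
#' @param response A [film_response()].
#' @param noise_sigma Scanner noise SD in counts.
#' @param seed Integer RNG seed, or `NULL`.
#' @param scan_id Identifier recorded on the scan.
#' @return A [film_scan()] carrying the plane geometry.
#' @export
simulate_film_scan <- function(dose_plane, response = film_response(),
                               noise_sigma = 0, seed = NULL, scan_id = 1L) {
  stopifnot(inherits(dose_plane, "dose_grid"),
            inherits(response, "film_response"))
  if (dose_plane$geometry$shape[3] != 1L) {
    stop("dose_plane must have a singleton Z dimension")
  }
  d <- dose_plane$values[, , 1]
  if (any(is.na(d))) stop("dose plane contains no-data voxels")
  if (any(d < -1e-9) || any(d > response$dose_range[2] + 1e-9)) {
    stop(sprintf("dose outside the calibrated film range [%g, %g] Gy",
                 response$dose_range[1], response$dose_range[2]))
  }
  d <- pmin(pmax(d, 0), response$dose_range[2])
  px <- array(NA_real_, dim = c(dim(d), 3L))
  for (ch in seq_along(FILM_CHANNELS)) {
    od <- response$channels[[ch]]$od_of_dose(d)
    px[, , ch] <- response$reference[[ch]] * 10^(-od)
  }
  if (noise_sigma > 0) {
    px <- px + with_seed(seed, stats::rnorm(length(px), sd = noise_sigma))
  }
  px <- pmin(pmax(px, 1), 65535)
  film_scan(px, scan_ids = scan_id, geometry = dose_plane$geometry)
}

#' Average repeated scans pixel by pixel
#'
#' Scanning the same film several times and averaging suppresses random
#' scanner noise by `1/n` in variance.
#'
#' @param scans List of [film_scan()] objects with identical shapes.
#' @return A [film_scan()] holding the per-pixel arithmetic mean.
#' @export
average_scans <- function(scans) {
  if (length(scans) == 0L) stop("no scans to average")
  stopifnot(all(vapply(scans, inherits, TRUE, "film_scan")))
  dims <- lapply(scans, function(s) dim(s$pixels))
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("scans differ in shape; cannot average")
  }
  acc <- Reduce(`+`, lapply(scans, `[[`, "pixels")) / length(scans)
  film_scan(acc, dpi = scans[[1]]$dpi,
            scan_ids = unlist(lapply(scans, `[[`, "scan_ids")),
            geometry = scans[[1]]$geometry)
}

#' Convert scan pixels to optical density
#'
#' `OD = log10(reference / pixel)` per channel, with pixels clipped to at
#' least 1. OD is invariant to a common exposure rescaling of pixel and
#' reference.
#'
#' @param scan A [film_scan()].
#' @param reference Per-channel unexposed pixel value (positive,
#'   length 3).
#' @return An `od_image`: an `(nx, ny, 3)` array of OD with the scan
#'   geometry attached.
#' @export
pixel_to_od <- function(scan, reference) {
  stopifnot(inherits(scan, "film_scan"))
  reference <- rep_len(as.numeric(reference), 3L)
  if (any(reference <= 0)) stop("reference pixel values must be positive")
  od <- scan$pixels
  for (ch in 1:3) od[, , ch] <- log10(reference[ch] / pmax(scan$pixels[, , ch], 1))
  structure(od, class = "od_image", geometry = scan$geometry)
}

#' Fit per-channel quartic OD-dose calibrations from strip data
#'
#' Least-squares fit of dose as a fourth-degree polynomial in OD for each
#' channel. The working channel is the one with the largest OD response
#' per Gy over the strip range (in practice the red channel up to 10 Gy).
#' A fitted curve that is not monotone over the observed OD span is
#' flagged and warned about, not rejected.
#'
#' @param strips Data frame with columns `dose_gy`, `od_r`, `od_g`,
#'   `od_b`; at least 6 strips spanning the dose range (a quartic needs
#'   five points, plus one residual degree of freedom).
#' @return An object of class `film_calibration` with per-channel
#'   coefficients (intercept first), R^2, OD spans, the selected channel
#'   and monotonicity flags.
#' @export
fit_film_calibration <- function(strips) {
  need <- c("dose_gy", "od_r", "od_g", "od_b")
  if (!all(need %in% names(strips))) {
    stop("strips needs columns dose_gy, od_r, od_g, od_b")
  }
  if (nrow(strips) < 6L) {
    stop("at least 6 calibration strips are required for a quartic fit")
  }
  odcols <- c(red = "od_r", green = "od_g", blue = "od_b")
  coefs <- matrix(NA_real_, nrow = 5, ncol = 3,
                  dimnames = list(paste0("c", 0:4), FILM_CHANNELS))
  r2 <- monotone <- stats::setNames(rep(NA, 3), FILM_CHANNELS)
  span <- matrix(NA_real_, 2, 3, dimnames = list(c("lo", "hi"), FILM_CHANNELS))
  grad <- stats::setNames(rep(NA_real_, 3), FILM_CHANNELS)
  for (ch in FILM_CHANNELS) {
    od <- strips[[odcols[[ch]]]]
    fit <- stats::lm(strips$dose_gy ~ od + I(od^2) + I(od^3) + I(od^4))
    coefs[, ch] <- unname(stats::coef(fit))
    r2[ch] <- suppressWarnings(summary(fit)$r.squared)
    span[, ch] <- range(od)
    grad[ch] <- diff(range(od)) / diff(range(strips$dose_gy))
    gd <- seq(span["lo", ch], span["hi", ch], length.out = 200)
    deriv <- .polyval(coefs[2:5, ch] * (1:4), gd)
    monotone[ch] <- all(deriv >= -1e-9)
  }
  if (!all(monotone)) {
    warning("fitted dose-OD curve is not monotone over the data span for: ",
            paste(FILM_CHANNELS[!monotone], collapse = ", "))
  }
  structure(list(coefficients = coefs, r_squared = r2, od_span = span,
                 response_gradient = grad, monotone = monotone,
                 dose_range = range(strips$dose_gy),
                 selected_channel = names(which.max(grad))),
            class = "film_calibration")
}

#' @export
print.film_calibration <- function(x, ...) {
  cat("<film_calibration> quartic dose(OD) per channel\n")
  cat("  R^2:", paste(sprintf("%s %.6f", FILM_CHANNELS, x$r_squared),
                      collapse = ", "), "\n")
  cat("  selected channel:", x$selected_channel, "\n")
  invisible(x)
}

#' Convert an OD image to a 2D dose map
#'
#' Applies the selected channel's quartic. OD outside the fitted span is
#' clamped to it (`clamp = "clamp"`) or marked no-data (`clamp = "mark"`).
#'
#' @param od An `od_image` from [pixel_to_od()].
#' @param cal A [fit_film_calibration()] result.
#' @param channel Channel override; default the calibration's selected
#'   channel.
#' @param clamp Out-of-span policy.
#' @return A [dose_grid()] (singleton Z) if the OD image carries a
#'   geometry, otherwise a plain matrix of dose.
#' @export
od_to_dose <- function(od, cal, channel = NULL, clamp = c("clamp", "mark")) {
  stopifnot(inherits(od, "od_image"), inherits(cal, "film_calibration"))
  clamp <- match.arg(clamp)
  channel <- if (is.null(channel)) cal$selected_channel else
    match.arg(channel, FILM_CHANNELS)
  x <- unclass(od)[, , match(channel, FILM_CHANNELS)]
  lo <- cal$od_span["lo", channel]; hi <- cal$od_span["hi", channel]
  if (clamp == "clamp") {
    x <- pmin(pmax(x, lo), hi)
  } else {
    x[x < lo | x > hi] <- NA_real_
  }
  dose <- .polyval(cal$coefficients[, channel], x)
  geo <- attr(od, "geometry")
  if (is.null(geo)) return(dose)
  dose_grid(array(dose, dim = geo$shape), geo)
}
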
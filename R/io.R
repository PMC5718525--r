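# File formats. Two interchange routes for dose grids: a lossless
# gzip-compressed float64 array with a JSON geometry sidecar (the internal
# exchange format), and DICOM RT Dose (explicit VR little endian) at the
# boundary. Film scans round-trip through 48-bit RGB TIFF.

#' Write a dose grid as a compressed array with a JSON sidecar
#'
#' Produces `<basename>.json` (geometry, dtype, provenance metadata) and
#' `<basename>.dose.gz` (little-endian float64 voxel values, X fastest).
#' The round trip is bit-exact for both geometry and dose.
#'
#' @param grid A [dose_grid()].
#' @param basename Output path without extension.
#' @param meta Named list merged into the grid metadata before writing.
#' @return `basename`, invisibly.
#' @export
write_dose_archive <- function(grid, basename, meta = list()) {
  stopifnot(inherits(grid, "dose_grid"))
  g <- grid$geometry
  side <- list(format = "plugdose-dose-v1",
               origin_mm = g$origin, spacing_mm = g$spacing,
               shape = g$shape, dtype = "float64-le",
               meta = utils::modifyList(grid$meta, meta))
  jsonlite::write_json(side, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- gzfile(paste0(basename, ".dose.gz"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(grid$values), con, size = 8, endian = "little")
  invisible(basename)
}

#' Read a dose grid written by [write_dose_archive()]
#'
#' @param basename Path without extension.
#' @return A [dose_grid()].
#' @export
read_dose_archive <- function(basename) {
  side <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "plugdose-dose-v1")) {
    stop("not a plugdose dose archive: ", basename)
  }
  geo <- grid_geometry(side$origin_mm, side$spacing_mm, side$shape)
  n <- prod(geo$shape)
  con <- gzfile(paste0(basename, ".dose.gz"), "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(v) != n) stop("dose archive is truncated: ", basename)
  meta <- side$meta
  dose_grid(array(v, dim = geo$shape), geo,
            meta = if (is.null(meta)) list() else as.list(meta))
}

#' Write an echo series as a compressed archive with a JSON sidecar
#'
#' @param series An [echo_series()].
#' @param basename Output path without extension.
#' @return `basename`, invisibly.
#' @export
write_echo_archive <- function(series, basename) {
  stopifnot(inherits(series, "echo_series"))
  g <- series$geometry
  side <- list(format = "plugdose-echo-v1",
               origin_mm = g$origin, spacing_mm = g$spacing, shape = g$shape,
               te_ms = series$te_ms, dtype = "float64-le")
  jsonlite::write_json(side, paste0(basename, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- gzfile(paste0(basename, ".echo.gz"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(series$signal), con, size = 8, endian = "little")
  invisible(basename)
}

#' Read an echo series written by [write_echo_archive()]
#'
#' @param basename Path without extension.
#' @return An [echo_series()].
#' @export
read_echo_archive <- function(basename) {
  side <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "plugdose-echo-v1")) {
    stop("not a plugdose echo archive: ", basename)
  }
  geo <- grid_geometry(side$origin_mm, side$spacing_mm, side$shape)
  n <- prod(geo$shape) * length(side$te_ms)
  con <- gzfile(paste0(basename, ".echo.gz"), "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  if (length(v) != n) stop("echo archive is truncated: ", basename)
  echo_series(array(v, dim = c(geo$shape, length(side$te_ms))),
              side$te_ms, geo)
}

# ---- DICOM RT Dose (explicit VR little endian) -----------------------------

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# one data element; VRs with a 4-byte length field carry 2 reserved bytes
.dicom_el <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(.u16(group), .u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .u32(length(value_raw)), value_raw)
  } else {
    c(head, .u16(length(value_raw)), value_raw)
  }
}

.ds <- function(x) charToRaw(paste(formatC(x, digits = 10, format = "g"),
                                   collapse = "\\"))

#' Write a dose grid as DICOM RT Dose
#'
#' Explicit VR little endian, 32-bit unsigned pixel data with
#' `DoseGridScaling` chosen so the grid maximum maps near the top of the
#' integer range; the quantization error is at most one scaling quantum.
#' `ImagePositionPatient`, `PixelSpacing` and `GridFrameOffsetVector`
#' carry the Leksell mm geometry (frames along Z, rows along Y, columns
#' along X).
#'
#' @param grid A [dose_grid()] with finite non-negative dose (no-data
#'   voxels are written as zero dose).
#' @param path Output file path.
#' @param scaling Dose grid scaling in Gy per integer unit; default
#'   `max(dose) / (2^31 - 1)`.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path, scaling = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  v <- grid$values
  v[is.na(v)] <- 0
  if (any(v < 0)) stop("RT Dose requires non-negative dose")
  g <- grid$geometry
  if (is.null(scaling)) {
    scaling <- max(v, 1e-12) / (2^31 - 1)
  }
  ints <- as.integer(round(v / scaling))
  sop_class <- "1.2.840.10008.5.1.4.1.1.481.2"
  sop_inst <- paste0("1.2.826.0.1.3680043.9.7435.",
                     paste(sample(0:9, 12, replace = TRUE), collapse = ""),
                     ".", as.integer(Sys.time()) %% 100000L)
  ui <- function(s) charToRaw(s)

  meta <- c(
    .dicom_el(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .dicom_el(0x0002, 0x0002, "UI", ui(sop_class)),
    .dicom_el(0x0002, 0x0003, "UI", ui(sop_inst)),
    .dicom_el(0x0002, 0x0010, "UI", ui("1.2.840.10008.1.2.1")),
    .dicom_el(0x0002, 0x0012, "UI", ui("1.2.826.0.1.3680043.9.7435.1"))
  )
  offsets <- (seq_len(g$shape[3]) - 1) * g$spacing[3]
  body <- c(
    .dicom_el(0x0008, 0x0016, "UI", ui(sop_class)),
    .dicom_el(0x0008, 0x0018, "UI", ui(sop_inst)),
    .dicom_el(0x0008, 0x0060, "CS", charToRaw("RTDOSE")),
    .dicom_el(0x0020, 0x0032, "DS", .ds(g$origin)),
    .dicom_el(0x0020, 0x0037, "DS", .ds(c(1, 0, 0, 0, 1, 0))),
    .dicom_el(0x0028, 0x0002, "US", .u16(1)),
    .dicom_el(0x0028, 0x0004, "CS", charToRaw("MONOCHROME2")),
    .dicom_el(0x0028, 0x0008, "IS", charToRaw(as.character(g$shape[3]))),
    .dicom_el(0x0028, 0x0010, "US", .u16(g$shape[2])),   # rows = Y
    .dicom_el(0x0028, 0x0011, "US", .u16(g$shape[1])),   # columns = X
    .dicom_el(0x0028, 0x0030, "DS", .ds(c(g$spacing[2], g$spacing[1]))),
    .dicom_el(0x0028, 0x0100, "US", .u16(32)),
    .dicom_el(0x0028, 0x0101, "US", .u16(32)),
    .dicom_el(0x0028, 0x0102, "US", .u16(31)),
    .dicom_el(0x0028, 0x0103, "US", .u16(0)),
    .dicom_el(0x3004, 0x0002, "CS", charToRaw("GY")),
    .dicom_el(0x3004, 0x0004, "CS", charToRaw("PHYSICAL")),
    .dicom_el(0x3004, 0x000A, "CS", charToRaw("PLAN")),
    .dicom_el(0x3004, 0x000C, "DS", .ds(offsets)),
    .dicom_el(0x3004, 0x000E, "DS", .ds(scaling)),
    .dicom_el(0x7FE0, 0x0010, "OW",
              writeBin(ints, raw(), size = 4, endian = "little"))
  )
  out <- c(raw(128), charToRaw("DICM"),
           .dicom_el(0x0002, 0x0000, "UL", .u32(length(meta))),
           meta, body)
  writeBin(out, path)
  invisible(path)
}

#' Read a DICOM RT Dose file
#'
#' Supports explicit VR little endian with the standard grid tags
#' (`ImagePositionPatient`, `PixelSpacing`, `GridFrameOffsetVector`,
#' `DoseGridScaling`); errors name any missing geometry tag. Frame offsets
#' must be uniformly spaced.
#'
#' @param path Path to an RT Dose file.
#' @return A [dose_grid()].
#' @export
read_rtdose <- function(path) {
  raw_all <- readBin(path, raw(), n = file.info(path)$size)
  if (length(raw_all) < 132 ||
      rawToChar(raw_all[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path)
  }
  pos <- 133L
  n_all <- length(raw_all)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  rd16 <- function(at) readBin(raw_all[at:(at + 1)], integer(), size = 2,
                               endian = "little", signed = FALSE)
  rd32 <- function(at) readBin(raw_all[at:(at + 3)], integer(), size = 4,
                               endian = "little")
  tags <- list()
  while (pos + 7L <= n_all) {
    group <- rd16(pos); elem <- rd16(pos + 2L)
    vr <- rawToChar(raw_all[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      if (pos + 11L > n_all) stop("truncated DICOM element header in ", path)
      len <- rd32(pos + 8L)
      data_at <- pos + 12L
    } else {
      len <- rd16(pos + 6L)
      data_at <- pos + 8L
    }
    if (len < 0 || data_at + len - 1L > n_all) {
      stop("truncated DICOM element (", sprintf("%04X,%04X", group, elem),
           ") in ", path)
    }
    key <- sprintf("%04X%04X", group, elem)
    tags[[key]] <- list(vr = vr, data = raw_all[data_at:(data_at + len - 1L)],
                        len = len)
    pos <- data_at + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  need <- c(ImagePositionPatient = "00200032", Rows = "00280010",
            Columns = "00280011", PixelSpacing = "00280030",
            NumberOfFrames = "00280008", GridFrameOffsetVector = "3004000C",
            DoseGridScaling = "3004000E", PixelData = "7FE00010")
  missing <- names(need)[!need %in% names(tags)]
  if (length(missing)) {
    stop("RT Dose file is missing required tag(s): ",
         paste(missing, collapse = ", "))
  }
  ds_vec <- function(key) as.numeric(strsplit(trimws(rawToChar(
    tags[[key]]$data)), "\\", fixed = TRUE)[[1]])
  us_val <- function(key) readBin(tags[[key]]$data, integer(), size = 2,
                                  endian = "little", signed = FALSE)
  ipp <- ds_vec(need[["ImagePositionPatient"]])
  pxs <- ds_vec(need[["PixelSpacing"]])       # (row spacing, col spacing)
  nframes <- as.integer(trimws(rawToChar(tags[[need[["NumberOfFrames"]]]]$data)))
  rows <- us_val(need[["Rows"]]); cols <- us_val(need[["Columns"]])
  gfov <- ds_vec(need[["GridFrameOffsetVector"]])
  scaling <- ds_vec(need[["DoseGridScaling"]])
  if (length(gfov) != nframes) stop("GridFrameOffsetVector length mismatch")
  dz <- if (nframes > 1) diff(gfov) else 1
  if (nframes > 2 && diff(range(dz)) > 1e-6 * max(abs(dz))) {
    stop("non-uniform GridFrameOffsetVector is not supported")
  }
  bits_key <- "00280100"
  bits <- if (bits_key %in% names(tags)) us_val(bits_key) else 32L
  pd <- tags[[need[["PixelData"]]]]
  nvox <- as.numeric(rows) * cols * nframes
  if (bits == 32L) {
    if (pd$len < 4 * nvox) stop("PixelData is truncated in ", path)
    ints <- readBin(pd$data, integer(), n = nvox, size = 4, endian = "little")
    ints <- ifelse(ints < 0, ints + 2^32, ints)
  } else if (bits == 16L) {
    if (pd$len < 2 * nvox) stop("PixelData is truncated in ", path)
    ints <- readBin(pd$data, integer(), n = nvox, size = 2,
                    endian = "little", signed = FALSE)
  } else {
    stop("unsupported BitsAllocated: ", bits)
  }
  geo <- grid_geometry(origin = c(ipp[1], ipp[2], ipp[3] + gfov[1]),
                       spacing = c(pxs[2], pxs[1], dz[1]),
                       shape = c(cols, rows, nframes))
  dose_grid(array(ints * scaling, dim = geo$shape), geo,
            meta = list(source = "rtdose", scaling = scaling))
}

# ---- film TIFF -------------------------------------------------------------

#' Write a film scan as 48-bit RGB TIFF
#'
#' Pixels are quantized to 16-bit integers per channel on write.
#'
#' @param scan A [film_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_film_tiff <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  img <- aperm(scan$pixels, c(2, 1, 3)) / 65535   # TIFF is row-major (Y, X)
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 48-bit RGB TIFF as a film scan
#'
#' @param path TIFF path.
#' @param dpi Resolution to record on the scan.
#' @param geometry Optional in-plane [grid_geometry()] to attach.
#' @return A [film_scan()] with integer pixel counts.
#' @export
read_film_tiff <- function(path, dpi = 150, geometry = NULL) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("expected an RGB TIFF: ", path)
  }
  px <- aperm(round(img[, , 1:3] * 65535), c(2, 1, 3))
  film_scan(pmax(px, 1), dpi = dpi, geometry = geometry)
}
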
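## Minimal GeoTIFF I/O: single-band float32, uncompressed, little-endian,
## EPSG:4326, NaN nodata. Written from scratch because the environment has no
## R GeoTIFF library; the output carries the standard ModelPixelScale,
## ModelTiepoint and GeoKeyDirectory tags plus GDAL_NODATA, so GDAL-based
## tools read it as an ordinary geographic raster.

tiff_tag <- function(code, type, count, value_or_offset, inline_raw = NULL) {
  w <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                  endian = "little")
  out <- c(w(code, 2), w(type, 2), w(count, 4))
  if (!is.null(inline_raw)) {
    stopifnot(length(inline_raw) <= 4)
    out <- c(out, inline_raw, rep(as.raw(0), 4 - length(inline_raw)))
  } else {
    out <- c(out, w(value_or_offset, 4))
  }
  out
}

#' Write a single-band float32 GeoTIFF
#'
#' @param values Numeric matrix in raster orientation: rows are latitude
#'   bands from north to south, columns longitude from west to east. `NA`
#'   and `NaN` become float32 NaN nodata.
#' @param path Output file path.
#' @param origin Coordinates `c(lon, lat)` of the *outer corner* of the
#'   top-left pixel (north-west corner of the raster extent).
#' @param pixel_size Cell size in degrees, `c(dx, dy)` with both positive
#'   (dy is applied southward).
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(values, path, origin, pixel_size) {
  stopifnot(is.matrix(values), length(origin) == 2L, length(pixel_size) == 2L,
            all(pixel_size > 0))
  h <- nrow(values); w <- ncol(values)
  int2 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  n_tags <- 15L
  ifd_offset <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  off_scale <- ifd_offset + ifd_size
  off_tie <- off_scale + 24L
  off_keys <- off_tie + 48L
  off_data <- off_keys + 40L

  tags <- c(
    tiff_tag(256, 4, 1, w),                       # ImageWidth
    tiff_tag(257, 4, 1, h),                       # ImageLength
    tiff_tag(258, 3, 1, NULL, int2(32)),          # BitsPerSample
    tiff_tag(259, 3, 1, NULL, int2(1)),           # Compression = none
    tiff_tag(262, 3, 1, NULL, int2(1)),           # Photometric = min-is-black
    tiff_tag(273, 4, 1, off_data),                # StripOffsets
    tiff_tag(277, 3, 1, NULL, int2(1)),           # SamplesPerPixel
    tiff_tag(278, 4, 1, h),                       # RowsPerStrip
    tiff_tag(279, 4, 1, 4L * w * h),              # StripByteCounts
    tiff_tag(284, 3, 1, NULL, int2(1)),           # PlanarConfig
    tiff_tag(339, 3, 1, NULL, int2(3)),           # SampleFormat = IEEE float
    tiff_tag(33550, 12, 3, off_scale),            # ModelPixelScale
    tiff_tag(33922, 12, 6, off_tie),              # ModelTiepoint
    tiff_tag(34735, 3, 20, off_keys),             # GeoKeyDirectory
    tiff_tag(42113, 2, 4, NULL, c(charToRaw("nan"), as.raw(0)))  # GDAL_NODATA
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  writeBin(as.integer(n_tags), con, size = 2, endian = "little")
  writeBin(tags, con)
  writeBin(as.integer(0), con, size = 4, endian = "little")   # next IFD
  writeBin(as.numeric(c(pixel_size[1], pixel_size[2], 0)), con,
           size = 8, endian = "little")
  writeBin(as.numeric(c(0, 0, 0, origin[1], origin[2], 0)), con,
           size = 8, endian = "little")
  # GeoKeys: geographic model, pixel-is-area, EPSG:4326, degrees
  keys <- c(1, 1, 0, 4,
            1024, 0, 1, 2,
            1025, 0, 1, 1,
            2048, 0, 1, 4326,
            2054, 0, 1, 9102)
  writeBin(as.integer(keys), con, size = 2, endian = "little")
  writeBin(as.numeric(t(values)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a GeoTIFF written by [write_geotiff()]
#'
#' Minimal reader for little-endian single-band uncompressed float32 GeoTIFF
#' with a single strip (the format this package writes).
#'
#' @param path File path.
#' @return List with `values` (matrix, raster orientation), `origin`,
#'   `pixel_size`, `crs` (EPSG code from the GeoKey directory), `nodata`.
#' @export
read_geotiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, raw(), 2)) != "II")
    stop("only little-endian TIFF supported", call. = FALSE)
  magic <- readBin(con, integer(), 1, size = 2, endian = "little")
  if (magic != 42) stop("not a TIFF file", call. = FALSE)
  ifd <- readBin(con, integer(), 1, size = 4, endian = "little")
  seek(con, ifd)
  n <- readBin(con, integer(), 1, size = 2, endian = "little")
  tags <- list()
  for (i in seq_len(n)) {
    code <- readBin(con, integer(), 1, size = 2, endian = "little",
                    signed = FALSE)
    type <- readBin(con, integer(), 1, size = 2, endian = "little")
    count <- readBin(con, integer(), 1, size = 4, endian = "little")
    val_raw <- readBin(con, raw(), 4)
    tags[[as.character(code)]] <- list(type = type, count = count,
                                       raw = val_raw)
  }
  grab <- function(code, dsize, reader) {
    tg <- tags[[as.character(code)]]
    if (is.null(tg)) return(NULL)
    total <- tg$count * dsize
    if (total <= 4) {
      reader(tg$raw, tg$count)
    } else {
      off <- readBin(tg$raw, integer(), 1, size = 4, endian = "little")
      seek(con, off)
      reader(readBin(con, raw(), total), tg$count)
    }
  }
  r_long <- function(r, k) readBin(r, integer(), k, size = 4, endian = "little")
  r_short <- function(r, k) readBin(r, integer(), k, size = 2, endian = "little")
  r_dbl <- function(r, k) readBin(r, numeric(), k, size = 8, endian = "little")
  rd <- function(code, type_size, rdr) grab(code, type_size, rdr)

  tag_int <- function(code) {
    tg <- tags[[as.character(code)]]
    if (is.null(tg)) return(NULL)
    if (tg$type == 3) r_short(tg$raw, 1) else r_long(tg$raw, 1)
  }
  w <- tag_int(256); h <- tag_int(257)
  strip_off <- tag_int(273)
  scale <- rd(33550, 8, r_dbl)
  tie <- rd(33922, 8, r_dbl)
  keys <- rd(34735, 2, r_short)
  crs <- NA_integer_
  if (!is.null(keys)) {
    km <- matrix(keys[-(1:4)], ncol = 4, byrow = TRUE)
    hit <- km[km[, 1] == 2048, , drop = FALSE]
    if (nrow(hit)) crs <- hit[1, 4]
  }
  seek(con, strip_off)
  vals <- readBin(con, numeric(), w * h, size = 4, endian = "little")
  list(values = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       origin = tie[4:5], pixel_size = scale[1:2],
       crs = crs, nodata = NaN)
}
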
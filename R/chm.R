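#' Canopy height model container
#'
#' A `chm` stores a gridded canopy surface: a numeric matrix of heights (m)
#' above ground, the world coordinates of the lower-left corner of the grid,
#' and the (square) cell size. Row 1 of `values` is the *bottom* row of the
#' grid (smallest y); column 1 the westernmost. The center of cell
#' `(row, col)` sits at `origin + (index - 0.5) * cell_size_m`. Cells with no
#' data are `NA`.
#'
#' @param values Numeric matrix of canopy heights (m); `NA` = no data.
#' @param origin `c(x, y)` of the grid's lower-left corner (m).
#' @param cell_size_m Cell edge length (m); default 0.10 m.
#' @param nodata Sentinel written to disk for `NA` cells.
#' @return An object of class `chm`.
#' @export
chm <- function(values, origin = c(0, 0), cell_size_m = 0.1, nodata = NaN) {
  check_positive_scalar(cell_size_m, "cell_size_m")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(is.finite(values) & values < 0)) {
    ss_abort("canopy heights must be non-negative.",
             "standscan_validation_error")
  }
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size_m = cell_size_m, nodata = nodata),
            class = "chm")
}

#' @export
print.chm <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<chm> %d x %d cells @ %.3g m, origin (%.6g, %.6g)\n",
              nrow(x$values), ncol(x$values), x$cell_size_m,
              x$origin[1], x$origin[2]))
  if (length(v)) cat(sprintf("  height range %.2f-%.2f m\n", min(v), max(v)))
  invisible(x)
}

#' @export
dim.chm <- function(x) dim(x$values)

# world coordinates of all cell centers (vectors aligned with rows/cols)
chm_cell_x <- function(x) x$origin[1] + (seq_len(ncol(x$values)) - 0.5) * x$cell_size_m
chm_cell_y <- function(x) x$origin[2] + (seq_len(nrow(x$values)) - 0.5) * x$cell_size_m

#' Read or write a canopy height model raster
#'
#' Two single-band raster encodings are supported, chosen by file extension:
#' `.tif`/`.tiff` — GeoTIFF, 32-bit float, uncompressed, georeferenced by
#' `ModelPixelScale`/`ModelTiepoint` tags with a `GDAL_NODATA` tag; and
#' `.asc` — ESRI ASCII grid. The GeoTIFF codec is self-contained (written and
#' read with `writeBin()`/`readBin()`); it reads any uncompressed single-band
#' stripped float32 GeoTIFF, which is what standard tools emit for this kind
#' of product when compression is off. Multi-band or compressed input is
#' rejected.
#'
#' @param path File path ending in `.tif`, `.tiff`, or `.asc`.
#' @param x A [chm()].
#' @return `read_chm_raster()` returns a [chm()]; `write_chm_raster()`
#'   returns `path` invisibly.
#' @export
read_chm_raster <- function(path) {
  if (!file.exists(path)) {
    ss_abort(paste0("file not found: ", path), "standscan_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = ,
         tiff = read_chm_tiff(path),
         asc = read_chm_asc(path),
         ss_abort(paste0("unsupported raster extension: .", ext),
                  "standscan_format_error"))
}

#' @rdname read_chm_raster
#' @export
write_chm_raster <- function(x, path) {
  stopifnot(inherits(x, "chm"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = ,
         tiff = write_chm_tiff(x, path),
         asc = write_chm_asc(x, path),
         ss_abort(paste0("unsupported raster extension: .", ext),
                  "standscan_format_error"))
  invisible(path)
}

# ---- ESRI ASCII grid ----

write_chm_asc <- function(x, path) {
  nd <- if (is.finite(x$nodata)) x$nodata else -9999
  v <- x$values
  v[!is.finite(v)] <- nd
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("NCOLS %d", ncol(v)),
               sprintf("NROWS %d", nrow(v)),
               sprintf("XLLCORNER %.10g", x$origin[1]),
               sprintf("YLLCORNER %.10g", x$origin[2]),
               sprintf("CELLSIZE %.10g", x$cell_size_m),
               sprintf("NODATA_VALUE %.10g", nd)), con)
  for (r in rev(seq_len(nrow(v)))) {  # rows on disk run north to south
    writeLines(paste(format(v[r, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
}

read_chm_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z_]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  nx <- hdr$NCOLS; ny <- hdr$NROWS
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nx * ny) {
    ss_abort("ASCII grid body does not match NCOLS x NROWS.",
             "standscan_format_error")
  }
  m <- matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)  # top-down on disk
  m <- m[rev(seq_len(ny)), , drop = FALSE]
  nd <- hdr$NODATA_VALUE %||% -9999
  m[m == nd] <- NA_real_
  chm(m, origin = c(hdr$XLLCORNER, hdr$YLLCORNER), cell_size_m = hdr$CELLSIZE,
      nodata = nd)
}

# ---- minimal GeoTIFF (single band, float32, uncompressed) ----

write_chm_tiff <- function(x, path) {
  v <- x$values
  ny <- nrow(v); nx <- ncol(v)
  pix <- as.vector(t(v[rev(seq_len(ny)), , drop = FALSE]))  # row-major, top row first
  pix[!is.finite(pix)] <- NaN
  data_len <- 4L * nx * ny
  nodata_str <- if (is.finite(x$nodata)) sprintf("%.10g", x$nodata) else "nan"
  # pad below 5 bytes so the value always lives outside the IFD entry
  nodata_str <- formatC(nodata_str, width = 5, flag = "-")
  nodata_raw <- c(charToRaw(nodata_str), as.raw(0L))
  n_entries <- 13L
  ifd_offset <- 8L + data_len
  ifd_len <- 2L + n_entries * 12L + 4L
  ext_offset <- ifd_offset + ifd_len
  scale_off <- ext_offset                 # 3 doubles
  tie_off <- scale_off + 24L              # 6 doubles
  nodata_off <- tie_off + 48L

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wd <- function(x) writeBin(as.numeric(x), con, size = 8, endian = "little")
  # header
  writeBin(charToRaw("II"), con)
  wi(42L, 2); wi(ifd_offset, 4)
  # pixel data (float32)
  writeBin(pix, con, size = 4, endian = "little")
  # IFD
  wi(n_entries, 2)
  entry <- function(tag, type, count, value, is_offset = FALSE) {
    wi(tag, 2); wi(type, 2); wi(count, 4)
    if (type == 3L && !is_offset) {  # SHORT packed left-justified
      wi(value, 2); wi(0L, 2)
    } else {
      wi(value, 4)
    }
  }
  entry(256L, 4L, 1L, nx)                  # ImageWidth
  entry(257L, 4L, 1L, ny)                  # ImageLength
  entry(258L, 3L, 1L, 32L)                 # BitsPerSample
  entry(259L, 3L, 1L, 1L)                  # Compression: none
  entry(262L, 3L, 1L, 1L)                  # Photometric: min-is-black
  entry(273L, 4L, 1L, 8L)                  # StripOffsets
  entry(277L, 3L, 1L, 1L)                  # SamplesPerPixel
  entry(278L, 4L, 1L, ny)                  # RowsPerStrip
  entry(279L, 4L, 1L, data_len)            # StripByteCounts
  entry(339L, 3L, 1L, 3L)                  # SampleFormat: IEEE float
  entry(33550L, 12L, 3L, scale_off, TRUE)  # ModelPixelScale
  entry(33922L, 12L, 6L, tie_off, TRUE)    # ModelTiepoint
  entry(42113L, 2L, length(nodata_raw), nodata_off, TRUE)  # GDAL_NODATA
  wi(0L, 4)                                # next IFD: none
  wd(c(x$cell_size_m, x$cell_size_m, 0))
  # tiepoint: raster (0,0) corner pins to the upper-left world corner
  wd(c(0, 0, 0, x$origin[1], x$origin[2] + ny * x$cell_size_m, 0))
  writeBin(nodata_raw, con)
}

read_chm_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) ss_abort("not a TIFF file.", "standscan_format_error")
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
  else if (rawToChar(raw[1:2]) == "MM") "big"
  else ss_abort("not a TIFF file.", "standscan_format_error")
  ri <- function(off, size, n = 1L, signed = TRUE) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  if (ri(2, 2, signed = FALSE) != 42L) {
    ss_abort("not a TIFF file.", "standscan_format_error")
  }
  ifd <- ri(4, 4)
  n_entries <- ri(ifd, 2, signed = FALSE)
  type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8, `11` = 4,
                 `12` = 8)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- ifd + 2 + (k - 1) * 12
    tag <- ri(e, 2, signed = FALSE)
    type <- ri(e + 2, 2, signed = FALSE)
    count <- ri(e + 4, 4)
    tsz <- type_size[[as.character(type)]] %||% 1
    total <- tsz * count
    voff <- if (total <= 4) e + 8 else ri(e + 8, 4)
    val <- switch(as.character(type),
                  `2` = rawToChar(raw[(voff + 1):(voff + count - 1)]),
                  `3` = ri(voff, 2, n = count, signed = FALSE),
                  `4` = ri(voff, 4, n = count),
                  `12` = readBin(raw[(voff + 1):(voff + 8 * count)], "double",
                                 n = count, size = 8, endian = endian),
                  ri(voff, tsz, n = count))
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    tags[[as.character(tag)]] %||% default %||%
      ss_abort(sprintf("TIFF missing required tag %d.", tag),
               "standscan_format_error")
  }
  nx <- need(256); ny <- need(257)
  if ((need(277, 1L)) != 1L) {
    ss_abort("multi-band rasters are not supported.",
             "standscan_format_error")
  }
  if ((need(259, 1L)) != 1L) {
    ss_abort("compressed TIFFs are not supported.", "standscan_format_error")
  }
  if (need(258, 32L) != 32L || need(339, 3L) != 3L) {
    ss_abort("only float32 sample data is supported.",
             "standscan_format_error")
  }
  offs <- need(273); counts <- need(279)
  pix <- numeric(0)
  for (s in seq_along(offs)) {
    pix <- c(pix, readBin(raw[(offs[s] + 1):(offs[s] + counts[s])],
                          "double", n = counts[s] / 4, size = 4,
                          endian = endian))
  }
  if (length(pix) != nx * ny) {
    ss_abort("TIFF pixel payload does not match dimensions.",
             "standscan_format_error")
  }
  m <- matrix(pix, nrow = ny, ncol = nx, byrow = TRUE)
  m <- m[rev(seq_len(ny)), , drop = FALSE]  # back to bottom-up rows
  scale <- tags[["33550"]] %||% c(1, 1, 0)
  tie <- tags[["33922"]] %||% c(0, 0, 0, 0, ny * scale[2], 0)
  origin <- c(tie[4] - tie[1] * scale[1], tie[5] - (ny - tie[2]) * scale[2])
  nodata <- NaN
  nd_str <- tags[["42113"]]
  if (!is.null(nd_str)) {
    nd <- suppressWarnings(as.numeric(trimws(nd_str)))
    if (is.finite(nd)) {
      nodata <- nd
      m[m == nd] <- NA_real_
    }
  }
  m[is.nan(m)] <- NA_real_
  chm(m, origin = origin, cell_size_m = scale[1], nodata = nodata)
}
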
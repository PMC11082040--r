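#' Height-normalized point cloud
#'
#' A tibble of `(x_m, y_m, z_m)` points with `z_m` = height above ground.
#' Slightly negative heights (ground-filtering noise) are tolerated up to
#' `tolerance_m`.
#'
#' @param points Data frame or matrix with columns/cols `x_m, y_m, z_m`
#'   (or unnamed 3 columns in that order).
#' @param tolerance_m Largest admissible negative height (default 0.05 m).
#' @return A tibble of class `point_cloud`.
#' @export
point_cloud <- function(points, tolerance_m = 0.05) {
  if (is.matrix(points)) {
    points <- as.data.frame(points)
    names(points) <- c("x_m", "y_m", "z_m")[seq_len(ncol(points))]
  }
  points <- as_tibble(points)
  if (!all(c("x_m", "y_m", "z_m") %in% names(points))) {
    ss_abort("point cloud needs columns x_m, y_m, z_m.",
             "standscan_format_error")
  }
  points <- points[, c("x_m", "y_m", "z_m")]
  if (nrow(points) > 0 && min(points$z_m) < -tolerance_m) {
    ss_abort(sprintf("point heights below -%.3g m; is the cloud normalized?",
                     tolerance_m),
             "standscan_validation_error")
  }
  structure(points, class = c("point_cloud", class(tibble())))
}

#' Read and write point clouds
#'
#' `read_point_cloud()` accepts LAS 1.2+ binary files (`.las`; point data
#' formats 0-3, uncompressed) or delimited XYZ text (`.xyz`, `.txt`, `.csv`:
#' whitespace- or comma-separated `x y z` per line, optional header).
#' Compressed `.laz` input is rejected with a format error. All units are
#' meters. `write_point_cloud()` chooses the encoding from the extension;
#' LAS output uses point format 0 with 1 mm coordinate resolution.
#'
#' @param path File path.
#' @param tolerance_m Passed to [point_cloud()].
#' @return A [point_cloud()] (reader) or `path`, invisibly (writer).
#' @export
read_point_cloud <- function(path, tolerance_m = 0.05) {
  if (!file.exists(path)) {
    ss_abort(paste0("file not found: ", path), "standscan_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "laz") {
    ss_abort("compressed LAZ is not supported; decompress to LAS first.",
             "standscan_format_error")
  }
  pts <- switch(ext,
                las = read_las(path),
                xyz = ,
                txt = ,
                csv = read_xyz_text(path),
                ss_abort(paste0("unknown point-cloud extension: .", ext),
                         "standscan_format_error"))
  point_cloud(pts, tolerance_m = tolerance_m)
}

#' @rdname read_point_cloud
#' @param cloud A [point_cloud()].
#' @export
write_point_cloud <- function(cloud, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         las = write_las(cloud, path),
         xyz = ,
         txt = write.table(as.data.frame(cloud)[, c("x_m", "y_m", "z_m")],
                           path, row.names = FALSE, col.names = FALSE),
         csv = write.csv(as.data.frame(cloud)[, c("x_m", "y_m", "z_m")],
                         path, row.names = FALSE),
         ss_abort(paste0("unknown point-cloud extension: .", ext),
                  "standscan_format_error"))
  invisible(path)
}

read_xyz_text <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- grepl("[A-Za-z]", first)
  d <- read.table(path, header = has_header, sep = sep)
  if (ncol(d) < 3) {
    ss_abort("XYZ text needs at least three columns.",
             "standscan_format_error")
  }
  d <- d[, 1:3]
  names(d) <- c("x_m", "y_m", "z_m")
  d
}

# ---- LAS 1.2 binary (uncompressed) ----

read_las <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 227 || rawToChar(raw[1:4]) != "LASF") {
    ss_abort("not a LAS file (bad signature).", "standscan_format_error")
  }
  ru16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                                endian = "little", signed = FALSE)
  ru32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                                endian = "little")
  rdbl <- function(off) readBin(raw[(off + 1):(off + 8)], "double", size = 8,
                                endian = "little")
  pt_offset <- ru32(96)
  fmt <- as.integer(raw[105])
  if (fmt >= 128L) {
    ss_abort("LAZ-compressed point data is not supported.",
             "standscan_format_error")
  }
  rec_len <- ru16(105)
  n <- ru32(107)
  scale <- c(rdbl(131), rdbl(139), rdbl(147))
  off <- c(rdbl(155), rdbl(163), rdbl(171))
  if (n == 0) return(data.frame(x_m = numeric(0), y_m = numeric(0),
                                z_m = numeric(0)))
  # vectorized field extraction: indices of the 4 coordinate bytes per record
  starts <- pt_offset + (seq_len(n) - 1) * rec_len
  get_i32 <- function(field_off) {
    idx <- as.vector(outer(1:4, starts + field_off, `+`))
    readBin(raw[idx], "integer", n = n, size = 4, endian = "little")
  }
  data.frame(x_m = get_i32(0) * scale[1] + off[1],
             y_m = get_i32(4) * scale[2] + off[2],
             z_m = get_i32(8) * scale[3] + off[3])
}

write_las <- function(cloud, path) {
  n <- nrow(cloud)
  scale <- 0.001
  con <- file(path, "wb")
  on.exit(close(con))
  w8 <- function(x) writeBin(as.raw(x), con)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wd <- function(x) writeBin(as.numeric(x), con, size = 8, endian = "little")
  writeBin(charToRaw("LASF"), con)
  w16(0); w16(0)                       # source id, global encoding
  w8(rep(0, 16))                       # GUID
  w8(1); w8(2)                         # version 1.2
  writeBin(charToRaw(formatC("standscan", width = 32, flag = "-")), con)
  writeBin(charToRaw(formatC("standscan", width = 32, flag = "-")), con)
  w16(1); w16(2026)                    # day, year
  w16(227); w32(227)                   # header size, point data offset
  w32(0)                               # no VLRs
  w8(0); w16(20)                       # point format 0, 20-byte records
  w32(n); w32(c(n, 0, 0, 0, 0))        # counts by return
  wd(c(scale, scale, scale)); wd(c(0, 0, 0))
  rng <- function(v) if (n) range(v) else c(0, 0)
  rx <- rng(cloud$x_m); ry <- rng(cloud$y_m); rz <- rng(cloud$z_m)
  wd(c(rx[2], rx[1], ry[2], ry[1], rz[2], rz[1]))
  if (n > 0) {
    # interleave the 20-byte records as a raw block
    ints <- rbind(round(cloud$x_m / scale), round(cloud$y_m / scale),
                  round(cloud$z_m / scale))
    body <- raw(20 * n)
    coord_raw <- writeBin(as.integer(ints), raw(), size = 4,
                          endian = "little")
    cm <- matrix(coord_raw, nrow = 12)       # 12 coord bytes per record
    idx <- as.vector(outer(1:12, (seq_len(n) - 1) * 20, `+`))
    body[idx] <- as.vector(cm)
    # remaining 8 bytes per record (intensity, flags, ...) stay zero, except
    # return number = 1 for well-formedness
    body[(seq_len(n) - 1) * 20 + 15] <- as.raw(0x09)
    writeBin(body, con)
  }
  invisible(path)
}
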
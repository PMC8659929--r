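#' OCT B-scan image container
#'
#' A 2D grayscale peripapillary B-scan raster with physical scaling metadata.
#' Rows index depth (z, increasing downward, row 1 is the vitreous side) and
#' columns index angular position along the scan circle. Spectralis-style
#' scans are 768 x 496 pixels with a vertical scaling of 3.87 um/pixel; the
#' horizontal scaling (by default 15.21 um/pixel for a 3.7 mm scan-circle
#' diameter) is stored as metadata only and never used in thickness
#' computations.
#'
#' @param pixels numeric matrix with intensities in `[0, 255]`,
#'   at least 2 x 2.
#' @param z_scale_um vertical scaling in micrometers per pixel (positive).
#' @param x_scale_um horizontal scaling in micrometers per pixel (metadata).
#' @return Object of class `oct_image` with fields `pixels`, `z_scale_um`,
#'   `x_scale_um`.
#' @export
oct_image <- function(pixels, z_scale_um = 3.87, x_scale_um = 15.21) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 2 || ncol(pixels) < 2)
    stop("image must be at least 2 x 2")
  if (any(!is.finite(pixels)) || any(pixels < 0 | pixels > 255))
    stop("intensities must be finite and within [0, 255]")
  if (!is.numeric(z_scale_um) || length(z_scale_um) != 1 || z_scale_um <= 0)
    stop("'z_scale_um' must be a positive scalar")
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, z_scale_um = z_scale_um,
                 x_scale_um = x_scale_um),
            class = "oct_image")
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf("<oct_image> %d rows (z) x %d cols, z-scale %.2f um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$z_scale_um))
  invisible(x)
}

#' @export
dim.oct_image <- function(x) dim(x$pixels)

#' Read / write OCT rasters
#'
#' `read_oct()` reads an 8-bit grayscale PNG or TIFF file into an
#' [oct_image()]. Multi-channel files are rejected by default, or converted
#' to luminance (Rec. 601 weights) with `multichannel = "luminance"`.
#' `write_image()` writes any numeric matrix in `[0, 255]` (rounded to 8-bit)
#' to PNG or TIFF by file extension; the round trip is lossless for integer
#' 8-bit data.
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @param z_scale_um,x_scale_um physical scaling stored in the result.
#' @param multichannel `"reject"` (default) or `"luminance"`.
#' @return `read_oct()` returns an [oct_image()]; `write_image()` returns
#'   `path` invisibly.
#' @export
read_oct <- function(path, z_scale_um = 3.87, x_scale_um = 15.21,
                     multichannel = c("reject", "luminance")) {
  multichannel <- match.arg(multichannel)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(raw)) == 3) {
    if (multichannel == "reject")
      stop("multi-channel image rejected (set multichannel = \"luminance\")")
    nch <- dim(raw)[3]
    w <- if (nch >= 3) c(0.299, 0.587, 0.114) else rep(1 / nch, nch)
    raw <- Reduce(`+`, lapply(seq_len(min(nch, 3)), function(k)
      w[k] * raw[, , k]))
  }
  if (length(dim(raw)) != 2) stop("image is not 2D")
  if (any(dim(raw) == 0)) stop("zero-size image")
  oct_image(round(raw * 255), z_scale_um = z_scale_um,
            x_scale_um = x_scale_um)
}

#' @rdname read_oct
#' @param img numeric matrix in `[0, 255]` or an [oct_image()].
#' @export
write_image <- function(img, path) {
  f <- as_image_matrix(img)
  if (any(f < 0 | f > 255)) stop("pixel values must be in [0, 255]")
  ext <- tolower(tools::file_ext(path))
  norm <- round(f) / 255
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Layer boundary curve
#'
#' Per-column subpixel vertical position of one layer boundary: one row
#' value `y[k]` per image column, in R's 1-based row coordinates. A reported
#' value `y` means the intensity transition lies between rows `y` and `y+1`.
#' Columns where the detector found no qualifying edge carry
#' `detected = FALSE` (their `y` is filled by circular interpolation).
#'
#' @param y numeric vector of row positions (length = image width).
#' @param label one of `"UB"`, `"AB"`, `"LB"`.
#' @param detected logical vector, per-column detection flag.
#' @return Object of class `boundary_curve`.
#' @export
boundary_curve <- function(y, label = c("UB", "AB", "LB"),
                           detected = rep(TRUE, length(y))) {
  label <- match.arg(label)
  stopifnot(is.numeric(y), length(y) >= 1, length(detected) == length(y))
  if (any(!is.finite(y))) stop("boundary positions must be finite")
  structure(list(y = as.numeric(y), label = label,
                 detected = as.logical(detected)),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve #%s> %d columns, %d undetected, y in [%.1f, %.1f]\n",
              x$label, length(x$y), sum(!x$detected), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
length.boundary_curve <- function(x) length(x$y)

#' TSNIT sector map
#'
#' Linear correspondence between the polar angle of the peripapillary scan
#' circle and the (1-based) pixel columns of the unrolled B-scan. The eight
#' 45-degree spans map onto `cols/8`-column blocks; the Temporal sector is
#' the union of the first (0-45 deg) and last (315-360 deg) spans. For
#' `cols = 768` this reproduces the standard Spectralis sector table
#' (e.g. Nasal = 135-225 deg = columns 289-480).
#'
#' @param cols image width in pixels; must be divisible by 8 so the
#'   45-degree sector edges land on integer columns.
#' @return A `data.frame` (class `sector_map`) with columns `sector`,
#'   `deg_min`, `deg_max`, `col_min`, `col_max`, one row per 45/90-degree
#'   span in angular order (Temporal appears twice).
#' @export
sector_map <- function(cols = 768) {
  stopifnot(is.numeric(cols), length(cols) == 1, cols >= 8)
  if (cols %% 8 != 0) stop("'cols' must be divisible by 8")
  s <- cols / 8
  spans <- data.frame(
    sector  = c("T", "TS", "NS", "N", "NI", "TI", "T"),
    deg_min = c(0, 45, 90, 135, 225, 270, 315),
    deg_max = c(45, 90, 135, 225, 270, 315, 360),
    col_min = c(0, 1, 2, 3, 5, 6, 7) * s + 1,
    col_max = c(1, 2, 3, 5, 6, 7, 8) * s,
    stringsAsFactors = FALSE)
  class(spans) <- c("sector_map", "data.frame")
  spans
}

#' Columns belonging to one sector
#'
#' @param map a [sector_map()].
#' @param sector sector name (`"T"`, `"TS"`, `"NS"`, `"N"`, `"NI"`, `"TI"`).
#' @return Integer vector of 1-based columns (possibly two disjoint spans).
#' @export
sector_columns <- function(map, sector) {
  rows <- map[map$sector == sector, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown sector: ", sector)
  unlist(lapply(seq_len(nrow(rows)), function(i)
    seq.int(rows$col_min[i], rows$col_max[i])), use.names = FALSE)
}

#' Read / write boundary curves as CSV
#'
#' Writes up to three boundary curves to a CSV with columns
#' `x_1based, y_UB, y_AB, y_LB` (subpixel values; `NA` marks undetected
#' columns or absent curves). `read_boundaries()` restores the curves.
#'
#' @param curves list of [boundary_curve()] objects (distinct labels), all
#'   of the same length.
#' @param path CSV file path.
#' @return `write_boundaries()` returns `path` invisibly;
#'   `read_boundaries()` a named list of [boundary_curve()].
#' @export
write_boundaries <- function(curves, path) {
  stopifnot(is.list(curves), length(curves) >= 1)
  lens <- vapply(curves, function(b) length(b$y), integer(1))
  if (length(unique(lens)) != 1) stop("curves have mismatched lengths")
  n <- lens[[1]]
  out <- data.frame(x_1based = seq_len(n), y_UB = NA_real_,
                    y_AB = NA_real_, y_LB = NA_real_)
  for (b in curves) {
    col <- paste0("y_", b$label)
    v <- b$y
    v[!b$detected] <- NA_real_
    out[[col]] <- v
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path) {
  d <- read.csv(path)
  out <- list()
  for (lab in c("UB", "AB", "LB")) {
    col <- paste0("y_", lab)
    if (col %in% names(d) && any(!is.na(d[[col]]))) {
      y <- d[[col]]
      det <- !is.na(y)
      # undetected columns re-filled so the curve remains usable
      y[!det] <- approx_circular(which(det), y[det], which(!det), nrow(d))
      out[[lab]] <- boundary_curve(y, lab, det)
    }
  }
  out
}

#' Write a binary mask as PNG
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param path PNG file path.
#' @export
write_mask <- function(mask, path) {
  m <- (as_image_matrix(mask * 1) != 0) * 255
  write_image(m, path)
}

#' Write a sector report as JSON
#'
#' Serialises a [thickness_report()] result to the report JSON layout used
#' by the command-line tool: fields `T, TS, NS, N, NI, TI, G` (um), the
#' per-column thickness vector `w`, `z_scale_um` and an echo of the
#' configuration used.
#'
#' @param report a `sector_report`.
#' @param path output JSON path.
#' @param config optional [stage_config()] echoed into the file.
#' @export
write_report <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "sector_report"))
  obj <- c(as.list(report$sectors), list(G = report$G, w = report$w,
           z_scale_um = report$z_scale_um))
  if (!is.null(config)) obj$config_echo <- config
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# circular linear interpolation of missing values on a ring of n columns
approx_circular <- function(idx_known, y_known, idx_missing, n) {
  if (length(idx_known) == 0) stop("no detected columns to interpolate from")
  if (length(idx_missing) == 0) return(numeric(0))
  xs <- c(idx_known - n, idx_known, idx_known + n)
  ys <- rep(y_known, 3)
  approx(xs, ys, xout = idx_missing, ties = "ordered")$y
}
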
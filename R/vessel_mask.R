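#' Suppress vertical vessel shadows by frequency-domain filtering
#'
#' Blood vessels crossing the scan circle cast vertical shadow columns on
#' the retinal layers. This filter removes them by attenuating, in the 2D
#' DFT of the image, components with nonzero horizontal frequency
#' concentrated near zero vertical frequency, while passing DC and all
#' purely vertical variation (the horizontal layer edges). The real-valued,
#' zero-phase transfer function is the smooth notch
#' `H1(wx, wy) = 1 - (1 - exp(-wx^2 / (2 sx^2))) * exp(-wy^2 / (2 sy^2))`
#' with `sx = 2*pi*nx/cols`, `sy = 2*pi*ny/rows` (normalised radians), so no
#' ringing is introduced by hard band edges. The FFT is periodic in both
#' directions; the circular B-scan is genuinely periodic in x.
#'
#' @param I [oct_image()] or numeric matrix.
#' @param nx,ny notch widths in cycles across the image width/height
#'   (positive; defaults 2 and 6).
#' @return Filtered image, clipped to `[0, 255]`.
#' @export
suppress_vertical_shadows <- function(I, nx = 2, ny = 6) {
  f <- as_image_matrix(I)
  if (nx <= 0 || ny <= 0) stop("notch widths must be positive")
  nr <- nrow(f); nc <- ncol(f)
  sx <- 2 * pi * nx / nc
  sy <- 2 * pi * ny / nr
  wy <- dft_omega(nr)
  wx <- dft_omega(nc)
  H <- 1 - outer(exp(-wy^2 / (2 * sy^2)),
                 1 - exp(-wx^2 / (2 * sx^2)))
  out <- Re(fft(fft(f) * H, inverse = TRUE)) / (nr * nc)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

# signed DFT bin frequencies in radians/sample, fft bin order
dft_omega <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  2 * pi * k / n
}

#' Shadow residual
#'
#' Modulus of the negative part of the difference between the image and its
#' shadow-suppressed version: `max(0, filtered - I)`. Nonzero exactly where
#' the original is darker than the filtered image, i.e. in the shaded
#' columns.
#'
#' @param I original image ([oct_image()] or matrix).
#' @param filtered output of [suppress_vertical_shadows()].
#' @return Nonnegative residual matrix.
#' @export
shadow_residual <- function(I, filtered) {
  f <- as_image_matrix(I)
  g <- as_image_matrix(filtered)
  if (!all(dim(f) == dim(g))) stop("shape mismatch")
  d <- g - f
  d[d < 0] <- 0
  d
}

#' Refine the shadow residual into a binary vessel mask
#'
#' Cleans the residual with morphology and restricts it to the retinal band
#' of interest: opening by a horizontal 5-px line (removes residual specks
#' narrower than a vessel shadow), reconstruction under the residual
#' (restores the full shape of surviving shadows), opening by a vertical
#' 51-px line (keeps only tall structures spanning the layer band), zeroing
#' of all pixels outside the rows strictly between the UB and AB boundaries
#' per column, a second vertical-line opening, and binarisation at 10% of
#' the maximum. An all-zero pre-threshold image yields an empty mask with a
#' warning (no vessels present).
#'
#' @param residual nonnegative matrix from [shadow_residual()].
#' @param ub,ab [boundary_curve()]s delimiting the band (UB above AB).
#' @param hline_len,vline_len structuring-element lengths (defaults 5, 51).
#' @param thr_frac binarisation fraction of the maximum (default 0.10).
#' @return Object of class `vessel_mask`: list with `mask` (0/1 matrix) and
#'   `threshold` (the absolute threshold used).
#' @export
refine_mask <- function(residual, ub, ab, hline_len = 5, vline_len = 51,
                        thr_frac = 0.10) {
  res <- as_image_matrix(residual)
  if (any(res < 0)) stop("residual must be nonnegative")
  nc <- ncol(res); nr <- nrow(res)
  stopifnot(length(ub$y) == nc, length(ab$y) == nc)
  if (any(ub$y >= ab$y))
    rnfl_error("UB must lie strictly above AB in every column",
               "rnflseg_inconsistent")
  i3 <- mm_open(res, se_hline(hline_len))
  i4 <- mm_open(mm_reconstruct(i3, res), se_vline(vline_len))
  # band restriction: keep rows strictly between UB and AB
  rows <- matrix(seq_len(nr), nr, nc)
  band <- sweep(rows, 2, ub$y, ">") & sweep(rows, 2, ab$y, "<")
  i5 <- i4 * band
  i6 <- mm_open(i5, se_vline(vline_len))
  mx <- max(i6)
  if (mx == 0) {
    warning("empty vessel mask: no shadow residual above threshold")
    return(new_vessel_mask(matrix(0, nr, nc), 0))
  }
  thr <- thr_frac * mx
  new_vessel_mask((i6 > thr) * 1, thr)
}

new_vessel_mask <- function(mask, threshold) {
  structure(list(mask = mask, threshold = threshold), class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d, %d shaded pixels (threshold %.2f)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask != 0), x$threshold))
  invisible(x)
}

#' Carry the vessel mask into rectified space
#'
#' Applies the column shifts of an image rectification to the mask (vacated
#' pixels become background) and then dilates with a horizontal 5-px line to
#' widen the shaded areas, guarding against residual misalignment at shadow
#' edges.
#'
#' @param vm a [vessel_mask][refine_mask()].
#' @param rect the `rectified_image` of the same scan (or its `shifts`).
#' @param hline_len dilation line length (default 5).
#' @return A `vessel_mask` in rectified coordinates.
#' @export
dilate_mask_for_rectified <- function(vm, rect, hline_len = 5) {
  stopifnot(inherits(vm, "vessel_mask"))
  shifts <- if (inherits(rect, "rectified_image")) rect$shifts else
    as.integer(rect)
  m <- vm$mask
  if (length(shifts) != ncol(m)) stop("shift length does not match mask width")
  nr <- nrow(m)
  out <- m
  for (k in which(shifts != 0L)) {
    src <- seq_len(nr) - shifts[k]
    ok <- src >= 1 & src <= nr
    col <- numeric(nr)
    col[ok] <- m[src[ok], k]
    out[, k] <- col
  }
  new_vessel_mask((mm_dilate(out, se_hline(hline_len)) > 0) * 1,
                  vm$threshold)
}

#' Full vessel-shadow mask computation
#'
#' Convenience wrapper chaining [suppress_vertical_shadows()],
#' [shadow_residual()] and [refine_mask()].
#'
#' @param I [oct_image()] or matrix.
#' @param ub,ab band-delimiting [boundary_curve()]s.
#' @param cfg a [stage_config()].
#' @return A `vessel_mask`.
#' @export
vessel_shadow_mask <- function(I, ub, ab, cfg = stage_config()) {
  filt <- suppress_vertical_shadows(I, nx = cfg$vm_notch_nx,
                                    ny = cfg$vm_notch_ny)
  res <- shadow_residual(I, filt)
  refine_mask(res, ub, ab, hline_len = cfg$vm_hline,
              vline_len = cfg$vm_vline, thr_frac = cfg$vm_thr_frac)
}
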
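#' Signed vertical gradients
#'
#' One-sided parts of the vertical forward-difference gradient
#' `g[r, c] = f[r+1, c] - f[r, c]` (placed at row `r`; the last row is 0).
#' `vgrad_pos()` keeps the nonnegative part and responds to black-to-white
#' transitions in the downward direction (e.g. vitreous to RNFL);
#' `vgrad_neg()` keeps the nonpositive part and responds to white-to-black
#' transitions (e.g. RNFL to GCL). Their sum is the full gradient.
#'
#' @param f numeric matrix (or [oct_image()]) with at least 2 rows.
#' @return Numeric matrix of the same dimensions.
#' @export
vgrad_pos <- function(f) {
  g <- vgrad_full(f)
  g[g < 0] <- 0
  g
}

#' @rdname vgrad_pos
#' @export
vgrad_neg <- function(f) {
  g <- vgrad_full(f)
  g[g > 0] <- 0
  g
}

vgrad_full <- function(f) {
  f <- as_image_matrix(f)
  if (nrow(f) < 2) stop("vertical gradient needs at least 2 rows")
  rbind(f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE],
        matrix(0, 1, ncol(f)))
}

#' Column-wise edge selection window
#'
#' Parameters for [first_crossing()]: per column, the search interval is
#' `[rho + rho1, rho + rho2]` rows below the reference boundary position
#' `rho` (or the whole column when there is no reference), and the first row
#' whose gradient magnitude reaches `gamma_thr` with the requested sign is
#' selected.
#'
#' @param rho1,rho2 interval offsets in rows, `0 <= rho1 < rho2`.
#' @param gamma_thr positive intensity threshold.
#' @param polarity `"positive"` (value `>= gamma_thr`) or `"negative"`
#'   (value `<= -gamma_thr`).
#' @return Object of class `selection_window`.
#' @export
selection_window <- function(rho1, rho2, gamma_thr,
                             polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(rho1 >= 0, rho1 < rho2, gamma_thr > 0)
  structure(list(rho1 = rho1, rho2 = rho2, gamma_thr = gamma_thr,
                 polarity = polarity),
            class = "selection_window")
}

#' First threshold crossing down each column
#'
#' Scans each column of a signed-gradient image downward and picks the first
#' row inside the search window where the gradient reaches the window's
#' threshold with the window's polarity. With a reference boundary the
#' window is `[rho + rho1, rho + rho2]` (clipped to the image); without one
#' it is the whole column. Columns with no qualifying row (e.g. under vessel
#' shadows) are flagged undetected and filled by circular linear
#' interpolation from the nearest detected neighbours — the peripapillary
#' scan is a closed ring, so column 1 neighbours column `cols`.
#'
#' @param gradient signed-gradient matrix from [vgrad_pos()]/[vgrad_neg()].
#' @param reference optional [boundary_curve()] anchoring the window.
#' @param window a [selection_window()].
#' @param label label for the returned curve.
#' @return [boundary_curve()] with integer rows for detected columns and
#'   interpolated values (with `detected = FALSE`) elsewhere. Errors if no
#'   column has a qualifying row.
#' @export
first_crossing <- function(gradient, reference = NULL, window,
                           label = "UB") {
  g <- as_image_matrix(gradient)
  nr <- nrow(g); nc <- ncol(g)
  if (!inherits(window, "selection_window"))
    stop("'window' must be a selection_window")
  if (!is.null(reference)) {
    if (!inherits(reference, "boundary_curve"))
      stop("'reference' must be a boundary_curve")
    if (length(reference$y) != nc)
      stop("reference length does not match image width")
    lo <- pmax(1L, pmin(nr, as.integer(ceiling(reference$y + window$rho1))))
    hi <- pmin(nr, floor(reference$y + window$rho2))
    empty <- floor(reference$y + window$rho2) < 1 |
      ceiling(reference$y + window$rho1) > nr
  } else {
    lo <- rep(1L, nc); hi <- rep(nr, nc); empty <- rep(FALSE, nc)
  }
  thr <- window$gamma_thr
  neg <- window$polarity == "negative"
  y <- rep(NA_real_, nc)
  for (k in seq_len(nc)) {
    if (empty[k] || lo[k] > hi[k]) next
    col <- g[lo[k]:hi[k], k]
    hit <- if (neg) which(col <= -thr) else which(col >= thr)
    if (length(hit) > 0) y[k] <- lo[k] + hit[1] - 1
  }
  det <- !is.na(y)
  if (!any(det))
    rnfl_error("no boundary found: all columns undetected",
               "rnflseg_no_boundary")
  if (any(!det))
    y[!det] <- approx_circular(which(det), y[det], which(!det), nc)
  boundary_curve(y, label, det)
}

#' Circular moving-average smoothing of a boundary curve
#'
#' Low-pass filters a boundary with a sliding boxcar of odd width `N`,
#' treating the curve as periodic in x (the scan circle is closed). The mean
#' of the curve is preserved exactly. The wide window (`N = 101`) is used to
#' initialise the UB/AB active contours, the narrow one (`N = 15`) for LB.
#'
#' @param curve a [boundary_curve()] (or numeric vector).
#' @param N odd window width, `N <= length(curve)`.
#' @return Smoothed [boundary_curve()] (all columns marked detected).
#' @export
smooth_curve <- function(curve, N) {
  y <- if (inherits(curve, "boundary_curve")) curve$y else as.numeric(curve)
  lab <- if (inherits(curve, "boundary_curve")) curve$label else "UB"
  if (N %% 2 == 0) stop("'N' must be odd")
  if (N > length(y)) stop("'N' exceeds curve length")
  sm <- as.numeric(stats::filter(y, rep(1 / N, N), method = "convolution",
                                 sides = 2, circular = TRUE))
  boundary_curve(sm, lab)
}

#' Flatten an image with respect to a reference boundary
#'
#' Shifts each column vertically by an integer so that the (rounded)
#' reference boundary lands on a common row — the rounded mean of the
#' reference. Vacated pixels are filled by edge replication. The shifts are
#' recorded so curves can be mapped between original and rectified space;
#' the rectification of the AB boundary is what exposes the low-contrast
#' RNFL lower edge to horizontal structuring elements.
#'
#' @param I an [oct_image()] or numeric matrix.
#' @param reference fully detected [boundary_curve()] to flatten.
#' @return Object of class `rectified_image` with fields `pixels`, `shifts`
#'   (per-column integer shift added to row indices) and `reference_row`.
#' @export
rectify <- function(I, reference) {
  f <- as_image_matrix(I)
  if (!inherits(reference, "boundary_curve"))
    stop("'reference' must be a boundary_curve")
  if (length(reference$y) != ncol(f))
    stop("reference length does not match image width")
  ref_row <- round(mean(reference$y))
  shifts <- as.integer(ref_row - round(reference$y))
  out <- f
  nr <- nrow(f)
  for (k in which(shifts != 0L)) {
    src <- pmin(nr, pmax(1L, seq_len(nr) - shifts[k]))
    out[, k] <- f[src, k]
  }
  structure(list(pixels = out, shifts = shifts, reference_row = ref_row),
            class = "rectified_image")
}

#' @export
print.rectified_image <- function(x, ...) {
  cat(sprintf("<rectified_image> %d x %d, reference row %d, shifts in [%d, %d]\n",
              nrow(x$pixels), ncol(x$pixels), x$reference_row,
              min(x$shifts), max(x$shifts)))
  invisible(x)
}

#' Map curves between original and rectified space
#'
#' A pixel at row `r` of column `k` appears at row `r + shifts[k]` after
#' rectification; `rectify_curve()` applies that map to a boundary,
#' `unrectify_curve()` inverts it.
#'
#' @param curve a [boundary_curve()].
#' @param rect a `rectified_image` (or its integer `shifts` vector).
#' @return [boundary_curve()] in the other coordinate space.
#' @export
rectify_curve <- function(curve, rect) {
  shifts <- if (inherits(rect, "rectified_image")) rect$shifts else rect
  boundary_curve(curve$y + shifts, curve$label, curve$detected)
}

#' @rdname rectify_curve
#' @export
unrectify_curve <- function(curve, rect) {
  shifts <- if (inherits(rect, "rectified_image")) rect$shifts else rect
  boundary_curve(curve$y - shifts, curve$label, curve$detected)
}
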
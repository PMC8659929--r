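#' Structuring elements
#'
#' Binary probe shapes for the grayscale morphological operators. Four shapes
#' are used throughout the segmentation pipeline: a disk of radius `r`
#' (pixels at Euclidean distance `<= r` from the center, in a
#' `(2r+1) x (2r+1)` bounding box), a rectangle of width `a` and height `b`
#' pixels, and horizontal/vertical lines of length `c` pixels. All footprints
#' are centered and symmetric; rectangles and lines must have odd side
#' lengths so that a center pixel exists.
#'
#' @param r disk radius in pixels (positive integer).
#' @param a,b rectangle width and height in pixels (odd positive integers).
#' @param c line length in pixels (odd positive integer).
#' @return An object of class `structuring_element` with fields `shape`
#'   (descriptive string) and `footprint` (logical matrix).
#' @examples
#' se_disk(2)$footprint
#' se_rect(5, 3)$shape
#' @export
se_disk <- function(r) {
  stopifnot(length(r) == 1, r >= 1, r == round(r))
  d <- 2 * r + 1
  idx <- seq_len(d) - (r + 1)
  fp <- outer(idx^2, idx^2, "+") <= r^2
  new_se(sprintf("disk(%d)", r), fp)
}

#' @rdname se_disk
#' @export
se_rect <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1, a >= 1, b >= 1)
  if (a %% 2 == 0 || b %% 2 == 0)
    stop("rectangular structuring elements must have odd side lengths")
  new_se(sprintf("rect(%dx%d)", a, b), matrix(TRUE, nrow = b, ncol = a))
}

#' @rdname se_disk
#' @export
se_hline <- function(c) {
  stopifnot(length(c) == 1, c >= 1)
  if (c %% 2 == 0) stop("line structuring elements must have odd length")
  new_se(sprintf("hline(%d)", c), matrix(TRUE, nrow = 1, ncol = c))
}

#' @rdname se_disk
#' @export
se_vline <- function(c) {
  stopifnot(length(c) == 1, c >= 1)
  if (c %% 2 == 0) stop("line structuring elements must have odd length")
  new_se(sprintf("vline(%d)", c), matrix(TRUE, nrow = c, ncol = 1))
}

new_se <- function(shape, fp) {
  structure(list(shape = shape, footprint = fp), class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat("<structuring_element>", x$shape, "\n")
  invisible(x)
}

as_image_matrix <- function(f) {
  if (inherits(f, "oct_image")) f <- f$pixels
  if (!is.matrix(f) || !is.numeric(f))
    stop("expected a numeric matrix (or oct_image)")
  storage.mode(f) <- "double"
  f
}

check_se <- function(se) {
  if (!inherits(se, "structuring_element"))
    stop("'se' must be a structuring_element")
  if (!any(se$footprint)) stop("empty structuring element footprint")
  se
}

#' Grayscale morphological operators
#'
#' Flat grayscale erosion, dilation, opening (erosion then dilation) and
#' closing (dilation then erosion) with a binary [structuring
#' element][se_disk]. The opening removes bright details smaller than the
#' structuring element; the closing removes dark details smaller than it.
#' Out-of-image samples are ignored (equivalent to padding with +Inf for
#' erosion and -Inf for dilation), so openings/closings do not create border
#' artifacts. Rectangular footprints are decomposed into a horizontal and a
#' vertical line pass, which is exact for flat erosion/dilation.
#'
#' @param f numeric matrix (or [oct_image()]).
#' @param se a [structuring element][se_disk].
#' @return Numeric matrix of the same dimensions.
#' @seealso [mm_reconstruct()] for reconstruction by geodesic dilation.
#' @export
mm_erode <- function(f, se) {
  f <- as_image_matrix(f)
  se <- check_se(se)
  fp <- se$footprint
  if (all(fp) && nrow(fp) > 1 && ncol(fp) > 1) {
    # separable flat rectangle
    f <- .erode_cpp(f, matrix(TRUE, 1, ncol(fp)))
    return(.erode_cpp(f, matrix(TRUE, nrow(fp), 1)))
  }
  .erode_cpp(f, fp)
}

#' @rdname mm_erode
#' @export
mm_dilate <- function(f, se) {
  f <- as_image_matrix(f)
  se <- check_se(se)
  fp <- se$footprint
  if (all(fp) && nrow(fp) > 1 && ncol(fp) > 1) {
    f <- .dilate_cpp(f, matrix(TRUE, 1, ncol(fp)))
    return(.dilate_cpp(f, matrix(TRUE, nrow(fp), 1)))
  }
  .dilate_cpp(f, fp)
}

#' @rdname mm_erode
#' @export
mm_open <- function(f, se) mm_dilate(mm_erode(f, se), se)

#' @rdname mm_erode
#' @export
mm_close <- function(f, se) mm_erode(mm_dilate(f, se), se)

#' Morphological reconstruction by geodesic dilation
#'
#' Restores the shapes of the objects of the marker image `f` constrained by
#' the mask image `g`: the result is the largest image `<= g` obtainable by
#' iterated elementary geodesic dilation (8-connectivity) of the marker, i.e.
#' the exact fixed point. Requires `marker <= mask` pointwise; tiny
#' floating-point violations are clipped with a warning, as the pipeline
#' composes many operators on uint8-ranged float images.
#'
#' @param marker numeric matrix, the marker `f`.
#' @param mask numeric matrix of the same shape, the constraining mask `g`.
#' @return Numeric matrix: the reconstruction of `marker` under `mask`.
#' @export
mm_reconstruct <- function(marker, mask) {
  marker <- as_image_matrix(marker)
  mask <- as_image_matrix(mask)
  if (!all(dim(marker) == dim(mask)))
    stop("marker and mask must have identical dimensions")
  if (any(marker > mask)) {
    warning("marker exceeds mask; clipping marker to mask")
    marker <- pmin(marker, mask)
  }
  .reconstruct_cpp(marker, mask)
}

#' Image complement
#'
#' Negative of an 8-bit-ranged image: `255 - f`. Values must lie in
#' `[0, 255]`.
#'
#' @param f numeric matrix with values in `[0, 255]`.
#' @return `255 - f`.
#' @export
img_complement <- function(f) {
  f <- as_image_matrix(f)
  if (any(f < 0 | f > 255))
    stop("img_complement() requires values in [0, 255]")
  255 - f
}
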
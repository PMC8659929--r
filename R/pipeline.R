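#' Stage configuration
#'
#' Every structuring-element size, window width, selection threshold and
#' snake parameter used by the three boundary stages, with the standard
#' values as defaults: disk(7) opening for UB; disk(9) and disk(3) for the
#' AB preprocessing; selection windows (rho1, rho2, gamma) = (8, 260, 10)
#' for AB and (8, 60, 3) for LB; curve smoothing widths 101 (UB/AB) and 15
#' (LB); 31x3 / 11x3 rectangles and the 5-px horizontal / 51-px vertical
#' lines of the LB and vessel-mask stages; snake parameters alpha = 0.5,
#' beta = 1, gamma = 1, eta = 1. The UB stage's first-crossing threshold is
#' not separately standardised and defaults to the AB value (10).
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of class `stage_config`.
#' @examples
#' cfg <- stage_config(ub_radius = 9)
#' cfg$ub_radius
#' @export
stage_config <- function(...) {
  cfg <- list(
    # stage UB
    ub_radius = 7, ub_threshold = 10, smooth_wide = 101,
    # stage AB
    ab_radius_large = 9, ab_radius_small = 3,
    ab_rho1 = 8, ab_rho2 = 260, ab_threshold = 10,
    # vessel mask
    vm_notch_nx = 2, vm_notch_ny = 6, vm_hline = 5, vm_vline = 51,
    vm_thr_frac = 0.10,
    # stage LB
    lb_radius = 3, lb_close_w = 31, lb_close_h = 3,
    lb_open_w = 11, lb_open_h = 3,
    lb_rho1 = 8, lb_rho2 = 60, lb_threshold = 3, smooth_narrow = 15,
    # snake
    alpha = 0.5, beta = 1, gamma = 1, eta = 1,
    max_iter = 500, tol = 0.01, edge_blur_sigma = 1)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  sizes <- c("ub_radius", "ab_radius_large", "ab_radius_small", "lb_radius",
             "lb_close_w", "lb_close_h", "lb_open_w", "lb_open_h",
             "vm_hline", "vm_vline", "smooth_wide", "smooth_narrow")
  if (any(unlist(cfg[sizes]) <= 0)) stop("all sizes must be positive")
  structure(cfg, class = c("stage_config", "list"))
}

cfg_snake <- function(cfg) {
  snake_params(alpha = cfg$alpha, beta = cfg$beta, gamma_d = cfg$gamma,
               eta = cfg$eta, max_iter = cfg$max_iter, tol = cfg$tol)
}

#' Segment the RNFL upper boundary (UB)
#'
#' Opening by disk(7) suppresses bright vitreous artifacts (floaters,
#' speckle) smaller than the structuring element; the first positive
#' vertical-gradient crossing down each column gives a coarse boundary,
#' which is smoothed with a wide circular boxcar (N = 101) and refined by
#' the active contour attracted to the positive-gradient ridge of the
#' opened image.
#'
#' @param I an [oct_image()].
#' @param cfg a [stage_config()].
#' @return [boundary_curve()] labelled `"UB"`.
#' @export
segment_ub <- function(I, cfg = stage_config()) {
  stopifnot(inherits(I, "oct_image"))
  opened <- mm_open(I$pixels, se_disk(cfg$ub_radius))
  grad <- vgrad_pos(opened)
  win <- selection_window(0, nrow(grad), cfg$ub_threshold, "positive")
  init <- first_crossing(grad, NULL, win, label = "UB")
  sm <- smooth_curve(init, cfg$smooth_wide)
  out <- snake_evolve(sm, grad, cfg_snake(cfg),
                      blur_sigma = cfg$edge_blur_sigma)
  boundary_curve(out$y, "UB", init$detected)
}

#' Segment the auxiliary boundary (AB) and the vessel mask
#'
#' The AB is the lower edge of the outer nuclear layer — the strongest
#' black-to-white transition below the RNFL — used as the rectification
#' reference for the LB stage. Dark then bright details smaller than
#' disk(9) are removed with opening/closing by reconstruction, remaining
#' specks smaller than disk(3) with a plain opening and closing; the first
#' positive-gradient crossing inside the window `[UB + 8, UB + 260]` above
#' threshold 10 is selected per column, smoothed (N = 101), and refined by
#' the snake whose external forces are cancelled inside the blood-vessel
#' shadow mask computed by [vessel_shadow_mask()].
#'
#' @param I an [oct_image()].
#' @param ub the [segment_ub()] result.
#' @param cfg a [stage_config()].
#' @return List with `boundary` ([boundary_curve()] `"AB"`), `mask` (the
#'   `vessel_mask`), and `preprocessed` (the cleaned image driving the
#'   external forces).
#' @export
segment_ab <- function(I, ub, cfg = stage_config()) {
  stopifnot(inherits(I, "oct_image"), inherits(ub, "boundary_curve"))
  se9 <- se_disk(cfg$ab_radius_large)
  se3 <- se_disk(cfg$ab_radius_small)
  i1 <- img_complement(I$pixels)
  i3 <- mm_reconstruct(mm_open(i1, se9), i1)
  i4 <- img_complement(i3)
  i6 <- mm_reconstruct(mm_open(i4, se9), i4)
  i8 <- mm_close(mm_open(i6, se3), se3)
  grad <- vgrad_pos(i8)
  win <- selection_window(cfg$ab_rho1, cfg$ab_rho2, cfg$ab_threshold,
                          "positive")
  init <- first_crossing(grad, ub, win, label = "AB")
  sm <- smooth_curve(init, cfg$smooth_wide)
  vm <- vessel_shadow_mask(I, ub, sm, cfg)
  out <- snake_evolve(sm, grad, cfg_snake(cfg), mask = vm,
                      blur_sigma = cfg$edge_blur_sigma)
  list(boundary = boundary_curve(out$y, "AB", init$detected),
       mask = vm, preprocessed = i8)
}

#' Segment the RNFL lower boundary (LB)
#'
#' Works in rectified space: the image is flattened on the AB boundary so
#' horizontal structuring elements align with the layers, and the vessel
#' mask is rectified with the same column shifts and widened by a 5-px
#' horizontal dilation. Dark then bright details smaller than disk(3) are
#' removed by reconstruction; a 31x3 closing bridges the vessel-shadow gaps
#' in the RNFL and an 11x3 opening removes narrow bright specks. The first
#' negative vertical-gradient crossing (value `<= -3`) inside
#' `[UB_rect + 8, UB_rect + 60]` is selected per column, lightly smoothed
#' (N = 15), refined by the snake on the negative-gradient magnitude ridge
#' with mask-cancelled forces, and mapped back to original coordinates.
#' If the resulting LB lies above the UB in more than 5% of columns the
#' scan is rejected as inconsistent (such acquisitions are repeated in
#' practice).
#'
#' @param I an [oct_image()].
#' @param ub,ab boundaries from the previous stages.
#' @param mask the `vessel_mask` from [segment_ab()].
#' @param cfg a [stage_config()].
#' @return [boundary_curve()] labelled `"LB"` in original coordinates.
#' @export
segment_lb <- function(I, ub, ab, mask, cfg = stage_config()) {
  stopifnot(inherits(I, "oct_image"), inherits(ub, "boundary_curve"),
            inherits(ab, "boundary_curve"), inherits(mask, "vessel_mask"))
  if (any(ub$y >= ab$y))
    rnfl_error("UB must lie above AB in every column",
               "rnflseg_inconsistent")
  rect <- rectify(I, ab)
  vm_r <- dilate_mask_for_rectified(mask, rect, hline_len = cfg$vm_hline)
  se3 <- se_disk(cfg$lb_radius)
  i1 <- img_complement(rect$pixels)
  i3 <- mm_reconstruct(mm_open(i1, se3), i1)
  i4 <- img_complement(i3)
  i6 <- mm_reconstruct(mm_open(i4, se3), i4)
  i7 <- mm_close(i6, se_rect(cfg$lb_close_w, cfg$lb_close_h))
  i8 <- mm_open(i7, se_rect(cfg$lb_open_w, cfg$lb_open_h))
  grad <- vgrad_neg(i8)
  ub_r <- rectify_curve(ub, rect)
  win <- selection_window(cfg$lb_rho1, cfg$lb_rho2, cfg$lb_threshold,
                          "negative")
  init <- first_crossing(grad, ub_r, win, label = "LB")
  sm <- smooth_curve(init, cfg$smooth_narrow)
  out <- snake_evolve(sm, -grad, cfg_snake(cfg), mask = vm_r,
                      blur_sigma = cfg$edge_blur_sigma)
  lb <- unrectify_curve(boundary_curve(out$y, "LB", init$detected), rect)
  if (mean(lb$y < ub$y) > 0.05)
    rnfl_error("segmentation inconsistent: LB above UB in more than 5% of columns",
               "rnflseg_inconsistent")
  lb
}

#' End-to-end RNFL segmentation
#'
#' Runs the three boundary stages in order (UB, then AB with the vessel
#' mask, then LB) and computes the sector thickness report. The whole path
#' is deterministic: identical input and configuration give a bit-identical
#' result.
#'
#' @param I an [oct_image()].
#' @param cfg a [stage_config()].
#' @return List with `ub`, `ab`, `lb` ([boundary_curve()]s), `mask` (the
#'   `vessel_mask`) and `report` (the `sector_report`).
#' @export
segment_rnfl <- function(I, cfg = stage_config()) {
  ub <- segment_ub(I, cfg)
  ab_res <- segment_ab(I, ub, cfg)
  lb <- segment_lb(I, ub, ab_res$boundary, ab_res$mask, cfg)
  list(ub = ub, ab = ab_res$boundary, lb = lb, mask = ab_res$mask,
       report = thickness_report(ub, lb, I))
}

#' RNFL thickness per TSNIT sector
#'
#' Thickness per column is the vertical distance between the lower and
#' upper boundary scaled to micrometers, `w[k] = (lb[k] - ub[k]) *
#' z_scale_um`; sector means follow the [sector_map()] partition and the
#' global mean G is the mean of `w` (equivalently the column-count-weighted
#' mean of the sector means).
#'
#' @param ub,lb RNFL boundaries ([boundary_curve()]s of image width).
#' @param I the segmented [oct_image()] (provides `z_scale_um` and width).
#' @return Object of class `sector_report`: `sectors` (named vector of
#'   means, um), `G`, `w`, `z_scale_um`.
#' @export
thickness_report <- function(ub, lb, I) {
  stopifnot(inherits(ub, "boundary_curve"), inherits(lb, "boundary_curve"),
            inherits(I, "oct_image"))
  nc <- ncol(I$pixels)
  if (length(ub$y) != nc || length(lb$y) != nc)
    stop("boundary length does not match image width")
  if (any(lb$y < ub$y))
    rnfl_error("negative thickness: LB above UB", "rnflseg_inconsistent")
  w <- (lb$y - ub$y) * I$z_scale_um
  sm <- sector_map(nc)
  secs <- c("T", "TS", "NS", "N", "NI", "TI")
  means <- vapply(secs, function(s) mean(w[sector_columns(sm, s)]),
                  numeric(1))
  structure(list(sectors = means, G = mean(w), w = w,
                 z_scale_um = I$z_scale_um),
            class = "sector_report")
}

#' @export
print.sector_report <- function(x, ...) {
  cat("RNFL thickness by sector (um):\n")
  print(round(x$sectors, 1))
  cat(sprintf("Global mean G: %.1f um\n", x$G))
  invisible(x)
}

#' Dice similarity coefficient
#'
#' Overlap agreement `2|A & B| / (|A| + |B|)` between two binary regions;
#' defined as 1 when both regions are empty.
#'
#' @param a,b logical or 0/1 matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_image_matrix(a * 1) != 0
  b <- as_image_matrix(b * 1) != 0
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Pixel region enclosed by the RNFL boundaries
#'
#' Binary mask of the pixels between the upper and lower boundary: row `r`
#' of column `k` is inside when `ub[k] + 0.5 <= r < lb[k] + 0.5` (the
#' reported boundary row `y` places the edge at `y + 0.5`). Used for
#' Dice-coefficient comparisons of segmentations.
#'
#' @param ub,lb [boundary_curve()]s.
#' @param rows image height.
#' @return Logical matrix `rows x length(ub)`.
#' @export
rnfl_region <- function(ub, lb, rows) {
  nc <- length(ub$y)
  r <- matrix(seq_len(rows), rows, nc)
  sweep(r, 2, ub$y + 0.5, ">=") & sweep(r, 2, lb$y + 0.5, "<")
}

#' Smallest non-significant thickness difference
#'
#' With a minimum delineation error of one pixel per boundary, two
#' boundaries per layer, and a vertical scaling of `z_scale_um` um/pixel,
#' thickness differences below `n_boundaries * 1 px * z_scale_um` (7.74 um
#' at the default scaling) cannot be resolved by the image.
#'
#' @param z_scale_um vertical scaling in um/pixel.
#' @param n_boundaries number of delineated boundaries (default 2).
#' @return The resolution bound in micrometers.
#' @export
thickness_resolution_bound <- function(z_scale_um = 3.87, n_boundaries = 2) {
  n_boundaries * 1 * z_scale_um
}
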
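test_that("shadow suppression passes DC and horizontal structure, removes vertical bars", {
  # purely horizontal structure (constant along x): untouched
  f <- matrix(rep(c(rep(40, 30), rep(180, 34)), 48), 64, 48)
  expect_equal(suppress_vertical_shadows(f), f, tolerance = 1e-6)
  const <- matrix(77, 32, 40)
  expect_equal(suppress_vertical_shadows(const), const, tolerance = 1e-9)
  # a narrow vertical dark bar at scan width: attenuated >= 10x, row means
  # preserved
  g <- matrix(200, 64, 768)
  g[, 382:384] <- 80
  filt <- suppress_vertical_shadows(g)
  resid_orig <- 200 - min(g)
  resid_filt <- max(abs(filt - rowMeans(g)))
  expect_lt(resid_filt, resid_orig / 10)
  expect_equal(rowMeans(filt), rowMeans(g), tolerance = 1e-6)
  expect_error(suppress_vertical_shadows(g, nx = 0), "positive")
})

test_that("shadow residual is the modulus of the negative difference", {
  f <- matrix(100, 10, 10)
  expect_equal(shadow_residual(f, f), matrix(0, 10, 10))
  g <- f; g[, 4] <- 70
  expect_equal(shadow_residual(g, f)[, 4], rep(30, 10))
  a <- rand_img(8, 8, 31); b <- rand_img(8, 8, 32)
  d <- a - b
  d[d > 0] <- 0
  expect_equal(shadow_residual(a, b), -d)
  expect_error(shadow_residual(a, matrix(0, 4, 4)), "mismatch")
})

test_that("mask refinement keeps tall in-band shadows and drops short blobs", {
  nr <- 200; nc <- 64
  ub <- boundary_curve(rep(20, nc), "UB")
  ab <- boundary_curve(rep(180, nc), "AB")
  expect_warning(vm0 <- refine_mask(matrix(0, nr, nc), ub, ab), "empty")
  expect_equal(sum(vm0$mask), 0)
  res <- matrix(0, nr, nc)
  res[40:119, 30:32] <- 50       # 3 px wide, 80 px tall, inside the band
  res[60:62, 10:14] <- 50        # 5 px wide but only 3 px tall
  vm <- refine_mask(res, ub, ab, hline_len = 3)
  expect_true(all(vm$mask[40:119, 31] == 1))
  expect_equal(sum(vm$mask[, 10:14]), 0)
  # residual entirely above the band: empty mask
  res2 <- matrix(0, nr, nc)
  res2[2:12, 30:34] <- 50
  expect_warning(vm2 <- refine_mask(res2, ub, ab), "empty")
  expect_equal(sum(vm2$mask), 0)
  # the mask never leaves the band between UB and AB
  rows <- matrix(seq_len(nr), nr, nc)
  band <- sweep(rows, 2, ub$y, ">") & sweep(rows, 2, ab$y, "<")
  expect_true(all(vm$mask[!band] == 0))
})

test_that("rectified mask follows the image shifts and widens by the hline", {
  nr <- 120; nc <- 40
  m <- matrix(0, nr, nc)
  m[30:100, 20] <- 1
  vm <- structure(list(mask = m, threshold = 1), class = "vessel_mask")
  shifts <- rep(0L, nc)
  d0 <- dilate_mask_for_rectified(vm, shifts)
  expect_equal(sum(d0$mask[30:100, 18:22]), 71 * 5)  # 5-column stripe
  empty <- structure(list(mask = m * 0, threshold = 0),
                     class = "vessel_mask")
  expect_equal(sum(dilate_mask_for_rectified(empty, shifts)$mask), 0)
  # nonzero shifts move the mask exactly like the image columns
  shifts[20] <- 7L
  d1 <- dilate_mask_for_rectified(vm, shifts, hline_len = 1)
  expect_equal(which(d1$mask[, 20] == 1), 37:107)
  expect_error(dilate_mask_for_rectified(vm, shifts[-1]), "length")
})

test_that("vessel mask is invariant to a global intensity offset", {
  nr <- 160; nc <- 64
  f <- matrix(150, nr, nc)
  f[20:140, 30:34] <- 60          # vertical shadow
  ub <- boundary_curve(rep(10, nc), "UB")
  ab <- boundary_curve(rep(150, nc), "AB")
  mk <- function(img) {
    filt <- suppress_vertical_shadows(img)
    refine_mask(shadow_residual(img, filt), ub, ab)$mask
  }
  m1 <- mk(f)
  m2 <- mk(f + 40)
  expect_gt(sum(m1), 0)
  expect_equal(m1, m2)
})

test_that("phantom vessel shadows are covered with few false positives", {
  ph <- cached_phantom(5, 0.05)
  ub <- segment_ub(ph$image)
  vm <- segment_ab(ph$image, ub)$mask$mask
  vt <- ph$truth$vessel_mask_true
  vs <- phantom_default_vessels()
  nc <- ncol(vt)
  for (i in seq_len(nrow(vs))) {
    cols <- which(abs(seq_len(nc) - vs$center[i]) <= vs$width[i] / 2)
    expect_gt(sum(vm[, cols] & vt[, cols]) / sum(vt[, cols]), 0.80)
  }
  rows <- matrix(seq_len(nrow(vt)), nrow(vt), nc)
  band <- sweep(rows, 2, ph$truth$ub_true$y, ">") &
    sweep(rows, 2, ph$truth$ab_true$y, "<")
  expect_lt(sum(vm == 1 & vt == 0) / sum(band), 0.05)
})
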
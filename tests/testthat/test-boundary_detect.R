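test_that("signed gradients decompose the vertical forward difference", {
  const <- matrix(9, 6, 6)
  expect_equal(vgrad_pos(const), matrix(0, 6, 6))
  expect_equal(vgrad_neg(const), matrix(0, 6, 6))
  # dark-above / bright-below step: one positive ridge at the step row
  f <- rbind(matrix(10, 4, 5), matrix(200, 4, 5))
  gp <- vgrad_pos(f)
  expect_equal(which(gp != 0, arr.ind = TRUE)[, "row"], rep(4, 5),
               ignore_attr = TRUE)
  expect_equal(vgrad_neg(f), matrix(0, 8, 5))
  gn <- vgrad_neg(255 - f)
  expect_equal(which(gn != 0, arr.ind = TRUE)[, "row"], rep(4, 5),
               ignore_attr = TRUE)
  f <- rand_img(8, 8, 5)
  expect_equal(vgrad_pos(f) + vgrad_neg(f), oracle_vgrad(f))
  expect_error(vgrad_pos(matrix(0, 1, 5)), "2 rows")
})

test_that("first crossing picks the first qualifying row inside the window", {
  nr <- 200; nc <- 12
  g <- matrix(0, nr, nc)
  g[120, ] <- 50
  win <- selection_window(0, nr, 10, "positive")
  bc <- first_crossing(g, NULL, win)
  expect_equal(bc$y, rep(120, nc))
  expect_true(all(bc$detected))
  # two ridges; window anchored at a reference picks the first inside it
  g2 <- matrix(0, nr, nc)
  g2[50, ] <- 30; g2[90, ] <- 30
  ref <- boundary_curve(rep(30, nc), "UB")
  bc2 <- first_crossing(g2, ref, selection_window(8, 260, 10, "positive"))
  expect_equal(bc2$y, rep(50, nc))
  # detected rows always inside the clipped window
  expect_true(all(bc2$y >= 38 & bc2$y <= 200))
  # sub-threshold column interpolated from its neighbours
  g3 <- g
  g3[120, 7] <- 5
  bc3 <- first_crossing(g3, NULL, win)
  expect_false(bc3$detected[7])
  expect_equal(bc3$y[7], 120)   # linear interpolation between columns 6 and 8
  # negative polarity
  g4 <- -g
  bc4 <- first_crossing(g4, NULL, selection_window(0, nr, 10, "negative"))
  expect_equal(bc4$y, rep(120, nc))
  # nothing above threshold anywhere: classed failure
  expect_error(first_crossing(matrix(0, nr, nc), NULL, win),
               class = "rnflseg_no_boundary")
})

test_that("interpolation of undetected columns is circular", {
  nr <- 50; nc <- 10
  g <- matrix(0, nr, nc)
  g[10, ] <- 40
  g[10, c(1, nc)] <- 0          # first and last columns undetected
  g[30, c(1, nc)] <- 0
  bc <- first_crossing(g, NULL, selection_window(0, nr, 10, "positive"))
  # ring neighbours are columns 2 and nc-1, both at 10
  expect_equal(bc$y[c(1, nc)], c(10, 10))
})

test_that("circular moving average has the boxcar frequency response", {
  n <- 768
  const <- boundary_curve(rep(5, n), "UB")
  expect_equal(smooth_curve(const, 101)$y, rep(5, n))
  # impulse response: spike h spread to h/N over N columns
  y <- rep(0, n); y[400] <- 101
  sm <- smooth_curve(boundary_curve(y + 100, "UB"), 101)
  expect_equal(sort(unique(round(sm$y, 6))), c(100, 101))
  expect_equal(sum(abs(sm$y - 101) < 1e-6), 101)
  # sinusoid scaled by the Dirichlet kernel of a length-N boxcar
  N <- 15
  th <- 2 * pi * (0:(n - 1)) / n
  sine <- sin(th)
  gain <- sin(pi * N / n) / (N * sin(pi / n))
  sm2 <- smooth_curve(boundary_curve(200 + 30 * sine, "UB"), N)
  expect_equal(sm2$y, 200 + 30 * gain * sine, tolerance = 1e-10)
  # mean preserved exactly
  set.seed(8)
  yr <- 100 + runif(n)
  expect_equal(mean(smooth_curve(boundary_curve(yr, "UB"), 101)$y), mean(yr))
  expect_error(smooth_curve(const, 100), "odd")
})

test_that("rectification flattens the reference and round-trips curves", {
  nr <- 60; nc <- 32
  f <- matrix(rep(seq_len(nr), nc), nr, nc)
  flat <- boundary_curve(rep(20, nc), "AB")
  r0 <- rectify(oct_image(f), flat)
  expect_equal(r0$shifts, rep(0L, nc))
  expect_equal(r0$pixels, f)
  ref <- boundary_curve(30 + 10 * sin(2 * pi * (1:nc) / nc), "AB")
  r1 <- rectify(oct_image(f), ref)
  ref_r <- rectify_curve(ref, r1)
  expect_true(all(abs(ref_r$y - r1$reference_row) <= 0.5 + 1e-9))
  # shift bookkeeping: map any curve there and back
  set.seed(2)
  cv <- boundary_curve(15 + runif(nc) * 5, "UB")
  back <- unrectify_curve(rectify_curve(cv, r1), r1)
  expect_lt(max(abs(back$y - cv$y)), 1)
  # pixel content moves with the shifts (away from replicated edges)
  k <- which.max(abs(r1$shifts))
  rows <- 25:35
  expect_equal(r1$pixels[rows + r1$shifts[k], k], f[rows, k])
})
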
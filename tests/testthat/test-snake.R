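# spatial-domain circulant machinery used as the independent oracle
circ_shift <- function(n) {
  P <- matrix(0, n, n)
  P[cbind(seq_len(n), c(2:n, 1))] <- 1
  P
}
internal_matrix <- function(alpha, beta, n) {
  D2 <- 2 * diag(n) - circ_shift(n) - t(circ_shift(n))
  alpha * D2 + beta * (D2 %*% D2)
}
bspline_matrix <- function(n) {
  first <- rep(0, n)
  first[1] <- 4 / 6; first[2] <- 1 / 6; first[n] <- 1 / 6
  out <- matrix(0, n, n)
  for (k in seq_len(n)) out[k, ] <- first[((seq_len(n) - k) %% n) + 1]
  out
}

test_that("internal filter has the closed form and its DC/fixed-point guarantees", {
  p <- snake_params()
  filt <- build_internal_filter(p, 8)
  # DC bin: no internal force
  expect_equal(filt$K[1], 0)
  expect_equal(filt$H[1], 1 / (p$gamma_d + p$eta))
  # omega = pi bin with alpha = 0.5, beta = 1: K = 0.5*4 + 16 = 18, H = 1/20
  expect_equal(filt$K[5], 18)
  expect_equal(filt$H[5], 1 / 20)
  # DC neutrality: H(0) * (a1 + a2) = 1 exactly
  expect_identical(filt$H[1] * (filt$a1 + filt$a2), 1)
  # spectrum matches the circulant internal-energy matrix
  Km <- internal_matrix(p$alpha, p$beta, 8)
  expect_equal(sort(Re(eigen(Km)$values)), sort(filt$K), tolerance = 1e-12)
  expect_error(build_internal_filter(p, 3), "at least 4")
  expect_error(snake_params(alpha = 0, beta = 0), "both")
})

test_that("B-spline spectrum is the DFT of (1/6, 4/6, 1/6) with unit DC", {
  S <- 12
  Fw <- bspline_spectrum(S)
  expect_equal(Fw[1], 1)
  expect_equal(Fw, Re(fft(c(4 / 6, 1 / 6, rep(0, S - 3), 1 / 6))))
})

test_that("external force pulls nodes toward a ridge and vanishes under the mask", {
  nr <- 60; S <- 8
  expect_equal(external_force(matrix(0, nr, S), rep(30, S)), rep(0, S))
  E <- matrix(rep(exp(-((1:nr) - 30)^2 / 8), S), nr, S)
  q_above <- external_force(E, rep(28, S))
  q_below <- external_force(E, rep(32, S))
  expect_true(all(q_above > 0))   # above the ridge: pushed down
  expect_true(all(q_below < 0))
  expect_equal(q_above, -q_below, tolerance = 1e-12)
  m <- matrix(0, nr, S); m[, 3] <- 1
  qm <- external_force(E, rep(28, S), mask = m)
  expect_equal(qm[3], 0)
  expect_equal(qm[-3], q_above[-3])
})

test_that("zero-force evolution preserves the mean and relaxes spikes to it", {
  S <- 32
  flat <- boundary_curve(rep(40, S), "UB")
  out <- snake_evolve(flat, matrix(0, 100, S), snake_params(max_iter = 50))
  expect_equal(out$y, flat$y, tolerance = 1e-9)
  spiked <- boundary_curve(c(rep(40, S - 1), 48), "UB")
  out2 <- snake_evolve(spiked, matrix(0, 100, S),
                       snake_params(max_iter = 2000, tol = 1e-9))
  expect_equal(out2$y, rep(mean(spiked$y), S), tolerance = 1e-4)
  expect_equal(mean(out2$y), mean(spiked$y), tolerance = 1e-9)
})

test_that("spike amplitude decreases monotonically under zero force", {
  S <- 16
  p <- snake_params()
  filt <- build_internal_filter(p, S)
  u1 <- u2 <- c(rep(10, S - 1), 20)
  amp <- max(u1) - mean(u1)
  for (it in 1:50) {
    U <- filt$H * (filt$a1 * fft(u1) + filt$a2 * fft(u2))
    u <- Re(fft(U, inverse = TRUE)) / S
    a <- max(abs(u - mean(u2)))
    expect_lt(a, amp + 1e-12)
    amp <- a
    u2 <- u1; u1 <- u
  }
})

test_that("frequency iteration equals the time-stepped spatial iteration", {
  S <- 24
  p <- snake_params(alpha = 0.3, beta = 0.7, gamma_d = 1.2, eta = 0.8)
  filt <- build_internal_filter(p, S)
  Fw <- bspline_spectrum(S)
  Km <- internal_matrix(p$alpha, p$beta, S)
  Nm <- bspline_matrix(S)
  A <- (p$gamma_d + p$eta) * diag(S) + Km
  set.seed(4)
  q <- rnorm(S)                 # fixed external force
  u1 <- u2 <- 100 + rnorm(S)
  v1 <- v2 <- u1
  for (it in 1:30) {
    U <- filt$H * (filt$a1 * fft(u1) + filt$a2 * fft(u2) +
                     p$eta * fft(q) * Fw)
    u <- Re(fft(U, inverse = TRUE)) / S
    v <- solve(A, filt$a1 * v1 + filt$a2 * v2 + p$eta * (Nm %*% q))
    expect_equal(u, as.numeric(v), tolerance = 1e-9)
    u2 <- u1; u1 <- u
    v2 <- v1; v1 <- v
  }
})

test_that("snake equilibrium solves the static circulant force balance", {
  # edge map linear in the row index gives a position-independent force,
  # so the equilibrium satisfies (alpha*D2 + beta*D4) u = eta * N q exactly
  S <- 16; nr <- 400
  p <- snake_params(max_iter = 50000, tol = 1e-12)
  set.seed(9)
  slope <- rnorm(S, 0, 0.05)
  slope <- slope - mean(slope)   # zero-mean force: equilibrium exists
  E <- outer(seq_len(nr), slope)
  E <- E - min(E)                # nonnegative, still linear per column
  init <- boundary_curve(rep(200, S), "UB")
  out <- snake_evolve(init, E, p, blur_sigma = 0, normalize = FALSE)
  q <- slope                     # d/dy of the edge map, any position
  Km <- internal_matrix(p$alpha, p$beta, S)
  Nm <- bspline_matrix(S)
  u_star <- MASS::ginv(Km) %*% (p$eta * (Nm %*% q))
  u_star <- as.numeric(u_star) - mean(u_star) + 200   # DC from the init
  expect_equal(out$y, u_star, tolerance = 1e-6)
})

test_that("non-finite node positions raise the divergence error naming the iteration", {
  S <- 16; nr <- 50
  E <- matrix(0, nr, S)
  E[, 4] <- NaN                 # poisoned force field -> non-finite update
  init <- boundary_curve(rep(25, S), "UB")
  err <- tryCatch(
    snake_evolve(init, E, snake_params(), blur_sigma = 0, normalize = FALSE),
    rnflseg_snake_divergence = function(e) e)
  expect_s3_class(err, "rnflseg_snake_divergence")
  expect_match(conditionMessage(err), "iteration 1")
})
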
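#' Active-contour parameters
#'
#' Parameters of the frequency-domain B-spline snake: elasticity `alpha` and
#' stiffness `beta` weight the first- and second-difference internal
#' energies; `gamma_d` (damping) and `eta` (mass / force gain) control the
#' inertia of the two-step iteration. Defaults are the values used for every
#' boundary stage: `alpha = 0.5`, `beta = 1`, `gamma_d = 1`, `eta = 1`.
#' Convergence is declared when the maximum per-node displacement falls
#' below `tol` rows (default 0.01) or after `max_iter` iterations.
#'
#' @param alpha elasticity weight, `>= 0`.
#' @param beta stiffness weight, `>= 0` (not both zero).
#' @param gamma_d damping coefficient, `> 0`.
#' @param eta mass / external-force gain, `> 0`.
#' @param max_iter iteration cap.
#' @param tol convergence threshold in rows, `> 0`.
#' @return Object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.5, beta = 1, gamma_d = 1, eta = 1,
                         max_iter = 500, tol = 0.01) {
  stopifnot(alpha >= 0, beta >= 0, gamma_d > 0, eta > 0,
            max_iter >= 1, tol > 0)
  if (alpha == 0 && beta == 0)
    stop("alpha and beta must not both be zero")
  structure(list(alpha = alpha, beta = beta, gamma_d = gamma_d, eta = eta,
                 max_iter = max_iter, tol = tol),
            class = "snake_params")
}

#' Internal-force filter of the frequency-domain snake
#'
#' For a closed contour with `S` nodes the circulant internal-energy
#' operator diagonalises over the DFT bins `w_k = 2*pi*k/S` as
#' `K(w) = alpha*(2 - 2*cos w) + beta*(2 - 2*cos w)^2`. The two-step
#' iteration uses `H(w) = 1 / (gamma_d + eta + K(w))`, `a1 = gamma_d +
#' 2*eta`, `a2 = -eta`, which guarantees `H(0) * (a1 + a2) = 1` (the mean
#' node position is preserved under zero external force) and makes the
#' fixed point of the iteration the static equilibrium `K(w) U = eta *
#' Q(w) * F(w)` — i.e. the classical force balance `(alpha*D2 + beta*D4) u
#' = eta * q` in the spatial domain.
#'
#' @param params a [snake_params()].
#' @param S node count, `>= 4` (one node per image column in the pipeline).
#' @return List with `H`, `a1`, `a2`, `K`, `omega` (per-bin vectors / scalars).
#' @export
build_internal_filter <- function(params, S) {
  stopifnot(inherits(params, "snake_params"))
  if (S < 4) stop("'S' must be at least 4")
  omega <- 2 * pi * (0:(S - 1)) / S
  K <- params$alpha * (2 - 2 * cos(omega)) +
    params$beta * (2 - 2 * cos(omega))^2
  list(H = 1 / (params$gamma_d + params$eta + K),
       a1 = params$gamma_d + 2 * params$eta,
       a2 = -params$eta,
       K = K, omega = omega)
}

#' DFT of the periodic cubic B-spline shape function
#'
#' With one node per column the shape-function sampling reduces to the
#' cubic B-spline evaluated at integer offsets, `(1/6, 4/6, 1/6)`; its DFT
#' `F(w) = (4 + 2*cos w)/6` acts as a mild spectral smoothing of the
#' external-force term. `F(0) = 1`, so the force DC is passed unchanged.
#'
#' @param S node count.
#' @return Numeric vector of length `S`.
#' @export
bspline_spectrum <- function(S) {
  (4 + 2 * cos(2 * pi * (0:(S - 1)) / S)) / 6
}

#' External force field sampled at the snake nodes
#'
#' Per node `k` at column `x_k` with vertical position `u_y[k]`, the force
#' is the vertical derivative of the edge map, sampled by central
#' difference of linear interpolations at `u_y[k] +/- 0.5`, so nodes are
#' pulled toward (ridge maxima of) the edge map. Positions are clamped to
#' the image rows. Wherever `(round(u_y[k]), x_k)` lies inside the vessel
#' mask the force is zero — the contour coasts on its internal smoothness
#' across shaded columns.
#'
#' @param edge_map nonnegative ridge image (one column per node).
#' @param u_y numeric vector of node row positions.
#' @param mask optional [vessel_mask][refine_mask()] (or 0/1 matrix).
#' @return Numeric force vector, one value per node.
#' @export
external_force <- function(edge_map, u_y, mask = NULL) {
  E <- as_image_matrix(edge_map)
  S <- length(u_y)
  if (ncol(E) != S) stop("edge map width does not match node count")
  nr <- nrow(E)
  u <- pmin(nr, pmax(1, u_y))
  q <- sample_rows(E, u + 0.5) - sample_rows(E, u - 0.5)
  if (!is.null(mask)) {
    m <- if (inherits(mask, "vessel_mask")) mask$mask else
      as_image_matrix(mask * 1)
    if (!all(dim(m) == dim(E))) stop("mask shape does not match edge map")
    r <- pmin(nr, pmax(1L, as.integer(round(u))))
    q[m[cbind(r, seq_len(S))] != 0] <- 0
  }
  q
}

# linear interpolation down each column at (possibly fractional) rows y,
# clamped to the image
sample_rows <- function(E, y) {
  nr <- nrow(E)
  y <- pmin(nr, pmax(1, y))
  r0 <- pmin(nr - 1L, floor(y))
  fr <- y - r0
  k <- seq_len(ncol(E))
  E[cbind(r0, k)] * (1 - fr) + E[cbind(r0 + 1L, k)] * fr
}

#' Evolve a boundary with the frequency-domain snake
#'
#' Iterates the two-step frequency-domain update
#' `U_xi = H * (a1 * U_{xi-1} + a2 * U_{xi-2} + eta * Q_{xi-1} * F)` with
#' forward/inverse DFTs each iteration, starting from the (fully detected)
#' initial curve, until the maximum per-node displacement drops below
#' `params$tol` or `params$max_iter` is reached. The x-coordinates are
#' fixed (one node per column); the contour is closed and periodic because
#' the B-scan circle is. The edge map is pre-blurred along rows with a
#' Gaussian (`blur_sigma`, default 1 row) to widen the capture range of the
#' ridge. With zero external force the curve relaxes toward the constant at
#' the initialisation's mean, which is preserved exactly.
#'
#' @param init fully detected [boundary_curve()].
#' @param edge_map nonnegative ridge image the contour is attracted to.
#' @param params a [snake_params()].
#' @param mask optional vessel mask cancelling forces in shaded columns.
#' @param blur_sigma Gaussian blur (rows) applied to the edge map; 0 for
#'   none.
#' @param normalize scale the (blurred) edge map to unit maximum before
#'   computing forces (default `TRUE`). The explicit force step is stable
#'   only for slopes of order 1 intensity/row, so the external field is
#'   made dimensionless; the equilibrium position of each node on a ridge
#'   does not depend on the ridge's absolute height.
#' @return Subpixel [boundary_curve()] (same label as `init`). Errors if
#'   the iteration produces non-finite positions.
#' @export
snake_evolve <- function(init, edge_map, params = snake_params(),
                         mask = NULL, blur_sigma = 1, normalize = TRUE) {
  stopifnot(inherits(init, "boundary_curve"))
  E <- as_image_matrix(edge_map)
  S <- length(init$y)
  if (ncol(E) != S) stop("edge map width does not match contour length")
  if (blur_sigma > 0) E <- blur_rows(E, blur_sigma)
  if (normalize && max(E) > 0) E <- E / max(E)
  filt <- build_internal_filter(params, S)
  Fw <- bspline_spectrum(S)
  u_prev <- init$y
  U_prev <- fft(u_prev)
  U_prev2 <- U_prev
  for (it in seq_len(params$max_iter)) {
    q <- external_force(E, u_prev, mask)
    U_new <- filt$H * (filt$a1 * U_prev + filt$a2 * U_prev2 +
                         params$eta * fft(q) * Fw)
    u_new <- Re(fft(U_new, inverse = TRUE)) / S
    if (any(!is.finite(u_new)))
      rnfl_error(sprintf("snake diverged at iteration %d", it),
                 "rnflseg_snake_divergence")
    delta <- max(abs(u_new - u_prev))
    U_prev2 <- U_prev
    U_prev <- U_new
    u_prev <- u_new
    if (delta < params$tol) break
  }
  boundary_curve(u_prev, init$label)
}

# separable Gaussian blur along rows (columns convolved independently),
# edges replicated
blur_rows <- function(f, sigma) {
  if (sigma <= 0) return(f)
  k <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- dnorm(-k:k, sd = sigma)
  w <- w / sum(w)
  nr <- nrow(f)
  pad <- f[c(rep(1L, k), seq_len(nr), rep(nr, k)), , drop = FALSE]
  out <- matrix(0, nr, ncol(f))
  for (i in seq_along(w))
    out <- out + w[i] * pad[i:(i + nr - 1L), , drop = FALSE]
  out
}
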
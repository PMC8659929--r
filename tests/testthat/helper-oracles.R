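# Brute-force oracles, independent of the package's C++ morphology path.

# sliding-window minimum with out-of-bounds treated as +Inf
oracle_erode <- function(f, fp) {
  cr <- (nrow(fp) - 1) / 2; cc <- (ncol(fp) - 1) / 2
  out <- f
  for (r in seq_len(nrow(f))) for (c in seq_len(ncol(f))) {
    vals <- c()
    for (i in seq_len(nrow(fp))) for (j in seq_len(ncol(fp))) {
      if (!fp[i, j]) next
      rr <- r + (i - 1 - cr); cc2 <- c + (j - 1 - cc)
      if (rr >= 1 && rr <= nrow(f) && cc2 >= 1 && cc2 <= ncol(f))
        vals <- c(vals, f[rr, cc2])
    }
    out[r, c] <- min(vals)
  }
  out
}

# sliding-window maximum with the reflected footprint, out-of-bounds -Inf
oracle_dilate <- function(f, fp) {
  cr <- (nrow(fp) - 1) / 2; cc <- (ncol(fp) - 1) / 2
  out <- f
  for (r in seq_len(nrow(f))) for (c in seq_len(ncol(f))) {
    vals <- c()
    for (i in seq_len(nrow(fp))) for (j in seq_len(ncol(fp))) {
      if (!fp[i, j]) next
      rr <- r - (i - 1 - cr); cc2 <- c - (j - 1 - cc)
      if (rr >= 1 && rr <= nrow(f) && cc2 >= 1 && cc2 <= ncol(f))
        vals <- c(vals, f[rr, cc2])
    }
    out[r, c] <- max(vals)
  }
  out
}

oracle_open <- function(f, fp) oracle_dilate(oracle_erode(f, fp), fp)
oracle_close <- function(f, fp) oracle_erode(oracle_dilate(f, fp), fp)

# elementary geodesic dilation (3x3, 8-connectivity) iterated to stability
oracle_reconstruct <- function(marker, mask) {
  fp <- matrix(TRUE, 3, 3)
  j <- pmin(marker, mask)
  repeat {
    nxt <- pmin(oracle_dilate(j, fp), mask)
    if (all(nxt == j)) return(j)
    j <- nxt
  }
}

# full vertical forward-difference gradient
oracle_vgrad <- function(f) {
  g <- f * 0
  for (r in seq_len(nrow(f) - 1)) g[r, ] <- f[r + 1, ] - f[r, ]
  g
}

rand_img <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(as.double(sample(0:255, nr * nc, replace = TRUE)), nr, nc)
}
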
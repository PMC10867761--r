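# Shared fixtures and independent oracles for the test suite. The oracles
# here are deliberately naive (per-pixel loops, direct quadrature) so they
# stay independent of the package's vectorized implementations.

# logical matrix from a two-column (row, col) coordinate matrix
px_matrix <- function(coords, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[coords] <- TRUE
  m
}

# independent rasterizer: stamp a disc at every densely interpolated point
stamp_px <- function(pts, width, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  rad <- width / 2
  d <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(d))
  ss <- seq(0, max(s), by = 0.25)
  rr <- stats::approx(s, pts[, 1], ss)$y
  cc <- stats::approx(s, pts[, 2], ss)$y
  for (dr in -3:3) for (dc in -3:3) {
    if (dr^2 + dc^2 > rad^2) next
    ri <- round(rr + dr); ci <- round(cc + dc)
    ok <- ri >= 1 & ri <= dims[1] & ci >= 1 & ci <= dims[2]
    m[cbind(ri[ok], ci[ok])] <- TRUE
  }
  m
}

# brute-force 8-connected component count (BFS flood fill)
count_components8 <- function(img) {
  seen <- matrix(FALSE, nrow(img), ncol(img))
  ncomp <- 0
  for (idx in which(img)) {
    if (seen[idx]) next
    ncomp <- ncomp + 1
    queue <- idx
    seen[idx] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      rc <- arrayInd(cur, dim(img))
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- rc[1] + dr; c2 <- rc[2] + dc
        if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
        if (img[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue <- c(queue, (c2 - 1) * nrow(img) + r2)
        }
      }
    }
  }
  ncomp
}

# per-pixel neighbour-count oracle
degree_oracle <- function(img) {
  deg <- matrix(0L, nrow(img), ncol(img))
  for (idx in which(img)) {
    rc <- arrayInd(idx, dim(img))
    cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- rc[1] + dr; c2 <- rc[2] + dc
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img) && img[r2, c2])
        cnt <- cnt + 1L
    }
    deg[idx] <- cnt
  }
  deg
}

# 4-neighbour steps count 1, diagonal steps sqrt(2)
step_sum_oracle <- function(chain) {
  s <- 0
  for (i in seq_len(nrow(chain) - 1)) {
    d <- abs(chain[i + 1, ] - chain[i, ])
    s <- s + if (all(d <= 1) && sum(d) > 0 && all(d == round(d))) {
      if (sum(d) == 2) sqrt(2) else 1
    } else {
      sqrt(sum((chain[i + 1, ] - chain[i, ])^2))
    }
  }
  s
}

# quadrature arc/chord oracle for one period span of y = a sin(2 pi x / lambda)
sinusoid_ratio_oracle <- function(a, lambda, x_max = lambda) {
  arc <- stats::integrate(function(u) sqrt(1 + (a * 2 * pi / lambda * cos(2 * pi * u / lambda))^2),
                          0, x_max, subdivisions = 500L, rel.tol = 1e-10)$value
  chord <- sqrt(x_max^2 + (a * sin(2 * pi * x_max / lambda))^2)
  arc / chord
}

# straight 5-px-wide bar fixture, horizontal
bar_mask <- function(len = 50, width = 5, dims = c(20, len + 10)) {
  m <- matrix(FALSE, dims[1], dims[2])
  r0 <- floor(dims[1] / 2) - floor(width / 2)
  m[r0:(r0 + width - 1), 6:(5 + len)] <- TRUE
  m
}

# plus-sign of two crossing 5-px bars
plus_mask <- function(arm = 50, width = 5, dims = c(2 * arm + 21, 2 * arm + 21)) {
  m <- matrix(FALSE, dims[1], dims[2])
  ctr <- arm + 11
  half <- floor(width / 2)
  m[(ctr - half):(ctr + half), (ctr - arm):(ctr + arm)] <- TRUE
  m[(ctr - arm):(ctr + arm), (ctr - half):(ctr + half)] <- TRUE
  m
}

# pixel-wide Y: three arms meeting at one pixel
y_skeleton <- function(arm = 10) {
  ctr <- c(arm + 5, arm + 15)
  a1 <- cbind(ctr[1] - seq_len(arm), ctr[2])            # up
  a2 <- cbind(ctr[1] + seq_len(arm), ctr[2] + seq_len(arm))  # down-right diagonal
  a3 <- cbind(ctr[1] + seq_len(arm), ctr[2] - seq_len(arm))  # down-left diagonal
  coords <- rbind(ctr, a1, a2, a3)
  px_matrix(coords, c(2 * arm + 10, 2 * arm + 30))
}

# pixel-wide horizontal path with a short diagonal side spur
spur_skeleton <- function(len = 50, spur = 5) {
  dims <- c(30, len + 10)
  m <- matrix(FALSE, dims[1], dims[2])
  m[20, 6:(5 + len)] <- TRUE
  at <- 5 + floor(len / 2)
  for (k in seq_len(spur)) m[20 - k, at + k] <- TRUE
  m
}
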
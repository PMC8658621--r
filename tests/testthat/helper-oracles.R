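# Independent oracles used to validate the package implementations.

# Optimal 1-D k-partition by dynamic programming over sorted values
# (the optimal 1-D k-means solution is contiguous in sorted order).
# Returns the minimal total within-cluster sum of squares.
dp_kmeans_sse <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse_seg <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  for (j in 1:n) D[1, j] <- sse_seg(1, j)
  if (k > 1) for (kk in 2:k) for (j in kk:n) {
    best <- Inf
    for (i in kk:j) {
      v <- D[kk - 1, i - 1] + sse_seg(i, j)
      if (v < best) best <- v
    }
    D[kk, j] <- best
  }
  D[k, n]
}

# Exhaustive minimum SSE over all 2-cluster assignments of a small sample.
exhaustive_kmeans2_sse <- function(values) {
  n <- length(values)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    a <- values[grp]; b <- values[!grp]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best) best <- sse
  }
  best
}

# Brute-force GLCM homogeneity by explicit pair enumeration.
brute_glcm_homogeneity <- function(S, mask, levels = 8L,
                                   offsets = list(c(0L, 1L), c(1L, 0L),
                                                  c(1L, 1L), c(1L, -1L))) {
  q <- pmin(pmax(floor(pmin(pmax(S, 0), 1) * levels), 0), levels - 1L)
  d <- dim(S)
  per_offset <- numeric(0)
  for (off in offsets) {
    num <- 0; cnt <- 0
    for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > d[1] || c2 < 1 || c2 > d[2]) next
      if (!mask[r, cc] || !mask[r2, c2]) next
      num <- num + 1 / (1 + abs(q[r, cc] - q[r2, c2]))
      cnt <- cnt + 1
    }
    if (cnt > 0) per_offset <- c(per_offset, num / cnt)
  }
  if (!length(per_offset)) NA_real_ else mean(per_offset)
}

# Direct (non-separable) truncated-Gaussian convolution with per-pixel
# renormalisation over in-bounds weights.
direct_gaussian_smooth <- function(x, sigma_px) {
  d <- dim(x)
  r1 <- max(1L, ceiling(4 * sigma_px[1])); r2 <- max(1L, ceiling(4 * sigma_px[2]))
  k1 <- exp(-0.5 * ((-r1):r1 / sigma_px[1])^2)
  k2 <- exp(-0.5 * ((-r2):r2 / sigma_px[2])^2)
  out <- x
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ii <- (i - r1):(i + r1); jj <- (j - r2):(j + r2)
    ok1 <- ii >= 1 & ii <= d[1]; ok2 <- jj >= 1 & jj <= d[2]
    W <- outer(k1[ok1], k2[ok2])
    out[i, j] <- sum(W * x[ii[ok1], jj[ok2]]) / sum(W)
  }
  out
}

# Type-7 percentile by explicit order-statistic interpolation.
manual_quantile7 <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Small phantom used across tests.
small_phantom <- function(seed = 1L, fgf = 0.3, masses = list(), ...) {
  generate_phantom(phantom_spec(grid_shape = c(64, 64, 10),
                                breast_radius = 20,
                                fibroglandular_fraction = fgf,
                                seed = seed, masses = masses, ...))
}
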
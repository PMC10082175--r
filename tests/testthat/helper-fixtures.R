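# shared fixtures and independent oracles used across test files

random_density_matrix <- function(h, w, scale = 1) {
  matrix(runif(h * w, 0, scale), h, w)
}

# independent closed-form SSIM oracle: plain arithmetic on the five
# whole-map statistics, written without reference to the package internals
oracle_ssim <- function(x, y, c1 = 0.01, c2 = 0.03) {
  M <- length(x)
  mx <- sum(x) / M
  my <- sum(y) / M
  vx <- sum((x - mx)^2) / M
  vy <- sum((y - my)^2) / M
  cxy <- sum((x - mx) * (y - my)) / M
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# brute-force average pooling with kernel = stride = k (floor division)
oracle_avgpool <- function(m, k) {
  ho <- nrow(m) %/% k
  wo <- ncol(m) %/% k
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    out[i, j] <- mean(m[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k)])
  }
  out
}

# brute-force block SUM for density downsampling
oracle_blocksum <- function(m, k) {
  out <- matrix(0, nrow(m) %/% k, ncol(m) %/% k)
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- sum(m[((i - 1) * k + 1):(i * k), ((j - 1) * k + 1):(j * k)])
  }
  out
}

# direct summation of normalised truncated Gaussian kernels: brute force
# over the full image grid with explicit per-point window normalisation
oracle_density <- function(pts, h, w, sigma = 4, radius = 4 * sigma) {
  acc <- matrix(0, h, w)
  for (p in seq_len(nrow(pts))) {
    x <- pts$x[[p]]; y <- pts$y[[p]]
    cx <- round(x); cy <- round(y)
    win <- 0
    vals <- list()
    for (iy in (cy - radius):(cy + radius)) {
      for (ix in (cx - radius):(cx + radius)) {
        g <- exp(-((ix - x)^2 + (iy - y)^2) / (2 * sigma^2))
        win <- win + g
        vals[[length(vals) + 1L]] <- c(iy, ix, g)
      }
    }
    for (v in vals) {
      if (v[[1]] >= 0 && v[[1]] < h && v[[2]] >= 0 && v[[2]] < w)
        acc[v[[1]] + 1L, v[[2]] + 1L] <- acc[v[[1]] + 1L, v[[2]] + 1L] + v[[3]] / win
    }
  }
  acc
}

tiny_net <- function(seed = 5L, branch = c(6L, 4L)) {
  build_network(model_config("tiny", branch_channels = branch), seed = seed)
}

random_rgb <- function(h, w) array(runif(h * w * 3), c(h, w, 3))
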
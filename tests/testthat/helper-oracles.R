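# brute-force oracles, independent of the package's fast paths

# direct triple-loop harmonic convolution (sum over channels and frequencies
# of the DCT-kernel response), zero padding, CNN (cross-correlation)
# convention
oracle_harmonic_conv <- function(x, w, bank) {
  f <- bank$size
  d <- dim(x)
  D <- dim(w)[4]
  pad <- (f - 1) / 2
  y <- array(0, c(d[1], d[2], D, d[4]))
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  for (n4 in seq_len(d[4])) for (dd in seq_len(D)) for (cn in seq_len(d[3]))
    for (u in 1:f) for (v in 1:f) {
      g <- bank$kernels[, , (u - 1) + f * (v - 1) + 1]
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
        patch <- xp[i:(i + f - 1), j:(j + f - 1), cn, n4]
        y[i, j, dd, n4] <- y[i, j, dd, n4] + w[u, v, cn, dd] * sum(patch * g)
      }
    }
  y
}

# loop-based harmonic attention: GAP -> W0 (+b0, ReLU) -> W1 (+b1, sigmoid)
# -> channel-wise scaling -> residual add
oracle_ha <- function(x, W0, b0, W1, b1) {
  d <- dim(x)
  C <- d[3]
  h <- dim(W0)[4]
  W0m <- matrix(W0, C, h)
  W1m <- matrix(W1, h, C)
  y <- array(0, d)
  for (n in seq_len(d[4])) {
    tp <- sapply(seq_len(C), function(cc) mean(x[, , cc, n]))
    hid <- pmax(t(W0m) %*% tp + b0, 0)
    a <- plogis(t(W1m) %*% hid + b1)
    for (cc in seq_len(C))
      y[, , cc, n] <- x[, , cc, n] * a[cc] + x[, , cc, n]
  }
  y
}

# a filled disk mask (pixel centers, 0-based radius test)
disk_mask <- function(size, cr, cc, radius) {
  g <- expand.grid(r = 0:(size - 1), c = 0:(size - 1))
  m <- matrix(as.integer((g$r - cr)^2 + (g$c - cc)^2 <= radius^2), size, size)
  m
}

# small phantom scenes used across tests
desk_phantom <- function(seed, n = 4) {
  generate_phantom(n_follicles = n, size_px = 96, spacing_mm = 0.4,
                   seed = seed)
}
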
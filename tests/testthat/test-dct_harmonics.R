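test_that("DCT filter bank is orthonormal with the analytic DC kernel", {
  for (f in c(1L, 3L, 5L)) {
    bank <- dct_filter_bank(f)
    gram <- crossprod(bank$basis)
    expect_lt(max(abs(gram - diag(f^2))), 1e-10)
    expect_equal(as.numeric(bank$kernels[, , 1]),
                 rep(1 / f, f^2), tolerance = 1e-12)
  }
  # deterministic function of f alone
  expect_identical(dct_filter_bank(3)$kernels, dct_filter_bank(3)$kernels)
})

test_that("f = 1 bank is the identity basis", {
  bank <- dct_filter_bank(1)
  expect_equal(dim(bank$kernels), c(1L, 1L, 1L))
  expect_equal(as.numeric(bank$kernels), 1)
})

test_that("invalid bank sizes are rejected", {
  expect_error(dct_filter_bank(2), "odd")
  expect_error(dct_filter_bank(0), "odd")
  expect_error(dct_filter_bank(-3), "odd")
})

test_that("harmonic_conv matches the triple-loop direct computation", {
  set.seed(101)
  for (f in c(1L, 3L)) {
    bank <- dct_filter_bank(f)
    for (rep_i in 1:3) {
      C <- sample(1:2, 1); D <- sample(1:3, 1)
      H <- sample(f:16, 1); W <- sample(f:16, 1)
      x <- array(rnorm(H * W * C * 2), c(H, W, C, 2))
      w <- array(rnorm(f * f * C * D), c(f, f, C, D))
      fast <- harmonic_conv(x, w, bank)
      slow <- oracle_harmonic_conv(x, w, bank)
      expect_lt(max(abs(fast - slow)) / max(abs(slow)), 1e-5)
    }
  }
})

test_that("harmonic_conv is linear and honours the DC-selection identity", {
  set.seed(102)
  bank <- dct_filter_bank(3)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  y <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  lhs <- harmonic_conv(2 * x - 3 * y, w, bank)
  rhs <- 2 * harmonic_conv(x, w, bank) - 3 * harmonic_conv(y, w, bank)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # all-zero input -> all-zero output
  expect_equal(max(abs(harmonic_conv(x * 0, w, bank))), 0)
  # selecting only the (0,0) frequency gives the local 3x3 sum scaled by 1/3
  w0 <- array(0, c(3, 3, 1, 1)); w0[1, 1, 1, 1] <- 1
  x1 <- array(rnorm(36), c(6, 6, 1, 1))
  got <- harmonic_conv(x1, w0, bank)
  xp <- matrix(0, 8, 8); xp[2:7, 2:7] <- x1[, , 1, 1]
  ls <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) ls[i, j] <- sum(xp[i:(i + 2), j:(j + 2)])
  expect_equal(got[, , 1, 1], ls / 3, tolerance = 1e-12)
})

test_that("channel mismatches are rejected", {
  bank <- dct_filter_bank(3)
  x <- array(0, c(8, 8, 2, 1))
  w <- array(0, c(3, 3, 3, 1))
  expect_error(harmonic_conv(x, w, bank), "channel mismatch")
})

test_that("the filter bank is frozen: training only changes weights/biases", {
  net <- harmonic_unet(base_width = 4, seed = 5)
  bank_before <- net$bank$kernels
  tr <- lapply(1:4, function(i) {
    sc <- generate_phantom(2, size_px = 32, spacing_mm = 1.2, seed = 300 + i)
    list(image = sc$image, mask = sc$follicle_mask)
  })
  cfg <- train_config(input_size = 32, epochs = 1, augment = FALSE, seed = 1)
  fit <- train_network(net, tr, cfg = cfg)
  expect_identical(fit$net$bank$kernels, bank_before)
  for (m in fit$net$modules)
    if (m$kind == "hconv") expect_identical(m$bank$kernels, bank_before)
})
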
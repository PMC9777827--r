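test_that("forward pass preserves shape, is deterministic in eval mode", {
  net <- harmonic_unet(base_width = 8, seed = 11)
  x <- array(runif(96 * 96), c(96, 96, 1, 1))
  p1 <- predict_mask(net, x[, , 1, 1])
  expect_equal(dim(p1$prob), c(96L, 96L))
  expect_true(all(p1$prob > 0 & p1$prob < 1))
  p2 <- predict_mask(net, x[, , 1, 1])
  expect_identical(p1$prob, p2$prob)
  # indivisible input dims are rejected with the required multiple stated
  expect_error(forward_network(net, array(0, c(50, 50, 1, 1))), "16")
})

test_that("parameter count equals the hand-computed layer inventory", {
  # independent closed-form count from the architecture description
  inventory_count <- function(b, attention) {
    ch <- b * 2^(0:4)
    red <- function(C) {
      cap <- max(1, min(16, C %/% 4))
      max(which(C %% seq_len(cap) == 0))
    }
    ha_p <- function(C) {
      h <- C / red(C)
      C * h + h + h * C + C            # W0, b0, W1, b1
    }
    bn_p <- function(C) 2 * C
    n <- 0
    # encoder
    n <- n + 9 * 1 * ch[1] + bn_p(ch[1]) +
      2 * (3 * ch[1] * ch[1] + bn_p(ch[1]))                 # level 1
    n <- n + 9 * ch[1] * ch[2] + bn_p(ch[2]) +
      2 * (3 * ch[2] * ch[2] + bn_p(ch[2])) +
      if (attention) ha_p(ch[2]) else 0                     # level 2
    for (l in 3:5)
      n <- n + 9 * ch[l - 1] * ch[l] + bn_p(ch[l]) +
        if (attention) ha_p(ch[l]) else 0                   # levels 3-5
    # decoder
    for (l in 4:1) {
      n <- n + 4 * ch[l + 1] * ch[l] + bn_p(ch[l])          # upconv + bn
      n <- n + 9 * (2 * ch[l]) * ch[l] + bn_p(ch[l])        # harmonic conv
      if (l <= 2) n <- n + 2 * (3 * ch[l] * ch[l] + bn_p(ch[l]))
      if (l >= 2 && attention) n <- n + ha_p(ch[l])
    }
    n + ch[1] * 1 + 1                                       # 1x1 head + bias
  }
  for (b in c(4L, 8L)) for (att in c(TRUE, FALSE)) {
    net <- harmonic_unet(base_width = b, use_attention = att, seed = 1)
    expect_equal(n_parameters(net), inventory_count(b, att),
                 info = sprintf("base %d attention %s", b, att))
  }
})

test_that("channel widths double per level", {
  net <- harmonic_unet(base_width = 8, seed = 2)
  couts <- vapply(net$enc, function(block) block[[1]]$cout, 0)
  expect_equal(couts, 8 * 2^(0:4))
})

test_that("whole-network analytic gradients match numerical differentiation", {
  set.seed(301)
  net <- harmonic_unet(base_width = 4, seed = 42)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  cfg <- loss_config()
  lossfun <- function() {
    logits <- forward_network(net, x, train = TRUE)
    combined_loss(y, plogis(logits), cfg)
  }
  logits <- forward_network(net, x, train = TRUE)
  p <- plogis(logits)
  g <- ovaquant:::combined_grad(y, p, cfg) * p * (1 - p)
  dim(g) <- dim(logits)
  ovaquant:::zero_grads(net$modules)
  ovaquant:::backward_network(net, g)
  # check one random entry of one parameter per module kind
  kinds_seen <- character(0)
  for (m in net$modules) {
    if (!length(m$params) || m$kind %in% kinds_seen) next
    kinds_seen <- c(kinds_seen, m$kind)
    pnm <- m$params[[1]]
    P <- get(pnm, envir = m)
    i <- which.max(abs(m$g[[pnm]]))   # largest-gradient entry: stable check
    eps <- 1e-5
    p0 <- P[i]
    P[i] <- p0 + eps; assign(pnm, P, envir = m); l1 <- lossfun()
    P[i] <- p0 - eps; assign(pnm, P, envir = m); l2 <- lossfun()
    P[i] <- p0; assign(pnm, P, envir = m)
    gn <- (l1 - l2) / (2 * eps)
    ga <- m$g[[pnm]][i]
    # tolerance allows for ReLU/max-pool kinks crossed by the finite
    # difference; exact per-module gradient checks live in test-attention.R
    expect_lt(abs(gn - ga) / max(1e-8, abs(gn) + abs(ga)), 2e-2,
              label = sprintf("gradient mismatch in %s/%s", m$kind, pnm))
  }
  expect_setequal(kinds_seen, c("hconv", "bn", "conv", "upconv", "ha"))
})

test_that("threshold semantics of predict_mask", {
  net <- harmonic_unet(base_width = 4, seed = 3)
  # force constant logits via the head bias on a zeroed head weight
  head <- net$head[[1]]
  head$W[] <- 0
  head$b[] <- qlogis(0.49)
  p <- predict_mask(net, matrix(0.5, 32, 32))
  expect_equal(sum(p$mask), 0)
  head$b[] <- qlogis(0.51)
  p <- predict_mask(net, matrix(0.5, 32, 32))
  expect_equal(sum(p$mask), 32 * 32)
})

test_that("baseline flag removes every attention block", {
  bl <- harmonic_unet(base_width = 4, use_attention = FALSE, seed = 1)
  kinds <- vapply(bl$modules, function(m) m$kind, "")
  expect_false("ha" %in% kinds)
  full <- harmonic_unet(base_width = 4, use_attention = TRUE, seed = 1)
  expect_equal(sum(vapply(full$modules, function(m) m$kind, "") == "ha"), 7L)
})

test_that("checkpoints round-trip exactly", {
  net <- harmonic_unet(base_width = 4, seed = 9)
  x <- matrix(runif(32 * 32), 32, 32)
  p0 <- predict_mask(net, x)$prob
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  net2 <- load_checkpoint(path)
  expect_identical(predict_mask(net2, x)$prob, p0)
  unlink(path)
})
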
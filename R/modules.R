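# Minimal layer system with hand-written backward passes.
#
# A module is an environment holding parameters, their gradients (list `g`),
# Adam state, and per-call caches. mod_forward()/mod_backward() dispatch on
# $kind. Backward passes assume exactly one forward call per backward call
# (the usual training pattern). Gradients ACCUMULATE into $g until
# zero_grads() is called.

new_module <- function(kind, ...) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$params <- character(0)
  m$g <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  class(m) <- "ov_module"
  m
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# standard convolution, odd kernel, 'same' zero padding
mod_conv <- function(kh, kw, cin, cout, bias = FALSE) {
  m <- new_module("conv", kh = kh, kw = kw, cin = cin, cout = cout,
                  padh = (kh - 1L) %/% 2L, padw = (kw - 1L) %/% 2L,
                  first = FALSE)
  m$W <- he_init(c(kh, kw, cin, cout), fan_in = kh * kw * cin)
  m$params <- "W"
  if (bias) { m$b <- numeric(cout); m$params <- c("W", "b") }
  m
}

# harmonic convolution: learned weights over a fixed orthonormal DCT bank
mod_hconv <- function(f, cin, cout, bias = FALSE, bank = NULL) {
  if (is.null(bank)) bank <- dct_filter_bank(f)
  m <- new_module("hconv", f = f, cin = cin, cout = cout, bank = bank,
                  pad = (f - 1L) %/% 2L, first = FALSE)
  # the bank is orthonormal, so variance-scaled init on the DCT weights
  # induces the same fan-in scaling on the effective spatial kernel
  m$W <- he_init(c(f, f, cin, cout), fan_in = f * f * cin)
  m$params <- "W"
  if (bias) { m$b <- numeric(cout); m$params <- c("W", "b") }
  m
}

mod_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  m <- new_module("bn", C = C, momentum = momentum, eps = eps)
  m$gamma <- rep(1, C); m$beta <- numeric(C)
  m$running_mean <- numeric(C); m$running_var <- rep(1, C)
  m$params <- c("gamma", "beta")
  m
}

mod_relu <- function() new_module("relu")
mod_maxpool <- function() new_module("maxpool")

# transpose convolution, kernel 2, stride 2 (doubles H and W)
mod_upconv <- function(cin, cout, bias = FALSE) {
  m <- new_module("upconv", cin = cin, cout = cout)
  m$W <- he_init(c(2L, 2L, cin, cout), fan_in = cin)
  m$params <- "W"
  if (bias) { m$b <- numeric(cout); m$params <- c("W", "b") }
  m
}

# harmonic attention: channel gate from globally pooled statistics through
# two 1x1 harmonic convolutions (f = 1, where the DCT basis is the scalar 1),
# sigmoid, channel-wise scaling and a residual add.
mod_ha <- function(C, reduction = 16L) {
  r <- ha_effective_reduction(C, reduction)
  h <- C %/% r
  m <- new_module("ha", C = C, r = r, hidden = h, bank1 = dct_filter_bank(1L))
  m$W0 <- he_init(c(1L, 1L, C, h), fan_in = C)   # (f,f,C,D) with f = 1
  m$b0 <- numeric(h)
  m$W1 <- he_init(c(1L, 1L, h, C), fan_in = h)
  m$b1 <- numeric(C)
  m$params <- c("W0", "b0", "W1", "b1")
  m
}

# largest divisor of C not exceeding min(reduction, C/4); at least 1.
# Keeps the bottleneck width C/r >= 4 for narrow layers.
ha_effective_reduction <- function(C, reduction = 16L) {
  cap <- max(1L, min(as.integer(reduction), C %/% 4L))
  divs <- which(C %% seq_len(cap) == 0L)
  max(divs)
}

zero_grads <- function(mods) {
  for (m in mods) m$g <- list()
  invisible(NULL)
}

acc_grad <- function(m, name, value) {
  if (is.null(m$g[[name]])) m$g[[name]] <- value
  else m$g[[name]] <- m$g[[name]] + value
  invisible(NULL)
}

# broadcast per-channel vectors to C x N and apply y = x*a + b channel-wise
scale_shift_c <- function(x, a, b) {
  d <- dim(x)
  .cpp_scale_shift_cn(x, matrix(a, d[3], d[4]), matrix(b, d[3], d[4]))
}

mod_forward <- function(m, x, train = FALSE) {
  switch(m$kind,
    conv = {
      m$x <- x
      .cpp_conv2d_fw(x, m$W, if ("b" %in% m$params) m$b else NULL,
                     m$padh, m$padw)
    },
    hconv = {
      m$x <- x
      m$K <- harmonic_effective_kernel(m$W, m$bank)
      .cpp_conv2d_fw(x, m$K, if ("b" %in% m$params) m$b else NULL,
                     m$pad, m$pad)
    },
    bn = {
      if (train) {
        st <- .cpp_channel_stats(x)
        mu <- st$mean
        v <- st$var                        # biased (population) variance
        m$running_mean <- (1 - m$momentum) * m$running_mean + m$momentum * mu
        m$running_var <- (1 - m$momentum) * m$running_var + m$momentum * v
      } else {
        mu <- m$running_mean
        v <- m$running_var
      }
      inv <- 1 / sqrt(v + m$eps)
      xhat <- scale_shift_c(x, inv, -mu * inv)
      m$xhat <- xhat; m$inv <- inv; m$train_mode <- train
      scale_shift_c(xhat, m$gamma, m$beta)
    },
    relu = {
      m$mask <- x > 0
      x * m$mask
    },
    maxpool = {
      m$in_dim <- dim(x)
      r <- .cpp_maxpool2_fw(x)
      m$idx <- r$idx
      r$y
    },
    upconv = {
      m$x <- x
      .cpp_upconv2_fw(x, m$W, if ("b" %in% m$params) m$b else NULL)
    },
    ha = {
      d <- dim(x)
      M <- d[1] * d[2]
      Tp <- .cpp_mean_cn(x)                                # GAP, C x N
      tp4 <- array(Tp, c(1L, 1L, d[3], d[4]))
      z0 <- harmonic_conv(tp4, m$W0, m$bank1, m$b0)        # 1x1xhxN
      A0 <- matrix(z0, m$hidden, d[4])
      H0 <- pmax(A0, 0)
      z1 <- harmonic_conv(array(H0, c(1L, 1L, m$hidden, d[4])),
                          m$W1, m$bank1, m$b1)
      a <- plogis(matrix(z1, d[3], d[4]))                  # attention, (0,1)
      m$x <- x; m$Tp <- Tp; m$A0 <- A0; m$H0 <- H0; m$a <- a; m$M <- M
      .cpp_scale_shift_cn(x, 1 + a, matrix(0, d[3], d[4])) # C_t + T
    },
    stop("unknown module kind: ", m$kind)
  )
}

mod_backward <- function(m, gy) {
  switch(m$kind,
    conv = {
      r <- .cpp_conv2d_bw(m$x, m$W, gy, m$padh, m$padw,
                          need_gx = !m$first, need_gb = "b" %in% m$params)
      acc_grad(m, "W", r$gw)
      if ("b" %in% m$params) acc_grad(m, "b", r$gb)
      if (m$first) NULL else r$gx
    },
    hconv = {
      r <- .cpp_conv2d_bw(m$x, m$K, gy, m$pad, m$pad,
                          need_gx = !m$first, need_gb = "b" %in% m$params)
      f <- m$f
      # pull the spatial-kernel gradient back through the orthogonal basis
      gW <- array(crossprod(m$bank$basis, matrix(r$gw, f * f)), dim(m$W))
      acc_grad(m, "W", gW)
      if ("b" %in% m$params) acc_grad(m, "b", r$gb)
      if (m$first) NULL else r$gx
    },
    bn = {
      r <- .cpp_bn_bw(m$xhat, gy, m$gamma, m$inv, isTRUE(m$train_mode))
      acc_grad(m, "gamma", r$dgamma)
      acc_grad(m, "beta", r$dbeta)
      r$gx
    },
    relu = gy * m$mask,
    maxpool = .cpp_maxpool2_bw(m$idx, gy, m$in_dim),
    upconv = {
      r <- .cpp_upconv2_bw(m$x, m$W, gy)
      acc_grad(m, "W", r$gw)
      if ("b" %in% m$params) acc_grad(m, "b", r$gb)
      r$gx
    },
    ha = {
      d <- dim(m$x); M <- m$M; C <- d[3]; N <- d[4]
      ga <- .cpp_sum_prod_cn(gy, m$x)
      gz1 <- ga * m$a * (1 - m$a)
      W1m <- matrix(m$W1, m$hidden, C)       # (1,1,h,C) -> h x C
      acc_grad(m, "W1", array(m$H0 %*% t(gz1), dim(m$W1)))
      acc_grad(m, "b1", rowSums(gz1))
      gH0 <- W1m %*% gz1                     # h x N
      gz0 <- gH0 * (m$A0 > 0)
      W0m <- matrix(m$W0, C, m$hidden)
      acc_grad(m, "W0", array(m$Tp %*% t(gz0), dim(m$W0)))
      acc_grad(m, "b0", rowSums(gz0))
      gTp <- W0m %*% gz0                     # C x N, grad of pooled stats
      # gy*(1+a) from the scaled/residual paths, plus the pooled-path grad
      .cpp_scale_shift_cn(gy, 1 + m$a, gTp / M)
    },
    stop("unknown module kind: ", m$kind)
  )
}

seq_forward <- function(block, x, train = FALSE) {
  for (m in block) x <- mod_forward(m, x, train)
  x
}

seq_backward <- function(block, gy) {
  for (m in rev(block)) gy <- mod_backward(m, gy)
  gy
}

# deep copy / restore of learnable parameters and BN running statistics
module_state <- function(mods) {
  lapply(mods, function(m) {
    s <- lapply(m$params, function(p) get(p, envir = m))
    names(s) <- m$params
    if (m$kind == "bn") {
      s$running_mean <- m$running_mean
      s$running_var <- m$running_var
    }
    s
  })
}

restore_module_state <- function(mods, state) {
  for (i in seq_along(mods))
    for (nm in names(state[[i]]))
      assign(nm, state[[i]][[nm]], envir = mods[[i]])
  invisible(NULL)
}
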
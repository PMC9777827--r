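#' Orthonormal 2-D DCT filter bank
#'
#' Constructs the fixed bank of `f^2` two-dimensional DCT-II basis kernels
#' used by every harmonic convolution. Kernel `(u, v)` evaluated at pixel
#' `(i, j)` (0-based) is
#' \deqn{\sqrt{\beta_u/f}\,\sqrt{\beta_v/f}\,
#'       \cos\!\big(\pi (i + 1/2) u / f\big)\,
#'       \cos\!\big(\pi (j + 1/2) v / f\big),}
#' with \eqn{\beta_0 = 1} and \eqn{\beta_{u>0} = 2}. Under this normalization
#' the flattened kernels form an orthonormal basis of the space of
#' \eqn{f \times f} kernels; the `(0, 0)` kernel is the constant `1/f`.
#' The bank is a deterministic function of `f` and carries no learned content.
#'
#' @param f odd positive integer, the kernel side length.
#' @return An object of class `dct_filter_bank`: a list with elements
#'   `size` (`f`), `kernels` (array `f x f x f^2`; slice `u + f*v + 1` is the
#'   `(u, v)` kernel), `freq` (data frame of the `(u, v)` pair per slice) and
#'   `basis` (the `f^2 x f^2` matrix whose column `k` is the flattened `k`-th
#'   kernel; orthogonal by construction).
#' @examples
#' bank <- dct_filter_bank(3)
#' bank$kernels[, , 1]                     # constant 1/3
#' round(crossprod(bank$basis), 12)        # identity
#' @export
dct_filter_bank <- function(f) {
  if (length(f) != 1L || !is.finite(f) || f < 1 || f != round(f) || f %% 2 == 0)
    stop("'f' must be a positive odd integer (e.g. 1 or 3)")
  f <- as.integer(f)
  beta <- c(1, rep(2, f - 1L))
  # 1-D basis: column u (0-based) over sample points i = 0..f-1
  u1 <- sapply(0:(f - 1L), function(u)
    sqrt(beta[u + 1L] / f) * cos(pi * ((0:(f - 1L)) + 0.5) * u / f))
  u1 <- matrix(u1, nrow = f)
  kernels <- array(0, c(f, f, f * f))
  freq <- data.frame(u = integer(f * f), v = integer(f * f))
  for (v in 0:(f - 1L)) {
    for (u in 0:(f - 1L)) {
      k <- u + f * v + 1L
      kernels[, , k] <- outer(u1[, u + 1L], u1[, v + 1L])
      freq$u[k] <- u; freq$v[k] <- v
    }
  }
  structure(list(size = f, kernels = kernels, freq = freq,
                 basis = matrix(kernels, f * f, f * f)),
            class = "dct_filter_bank")
}

#' @export
print.dct_filter_bank <- function(x, ...) {
  cat(sprintf("<dct_filter_bank> %dx%d, %d orthonormal kernels\n",
              x$size, x$size, x$size^2))
  invisible(x)
}

# effective spatial kernel (f, f, C, D) from harmonic weights (f, f, C, D)
# weights[u+1, v+1, n, d] multiplies DCT kernel (u, v); because the basis is
# complete and orthonormal this is an orthogonal reparametrization of a
# standard convolution kernel.
harmonic_effective_kernel <- function(weights, bank) {
  d <- dim(weights)
  f <- bank$size
  if (length(d) != 4L || d[1] != f || d[2] != f)
    stop("weights must have dim (f, f, C, D) matching the bank")
  array(bank$basis %*% matrix(weights, f * f), d)
}

#' Harmonic convolution
#'
#' Convolves a feature array with a learned linear combination of the fixed
#' DCT filter bank: output channel `d` is
#' \deqn{\sum_{n}\sum_{u,v} w^{d}_{n,u,v}\; \gamma(u,v) * x_n,}
#' i.e. each input channel is decomposed onto the `f^2` DCT kernels and the
#' responses are recombined with learned weights. Zero padding of
#' `(f-1)/2` preserves the spatial size. Convolution follows the CNN
#' convention (cross-correlation); DCT kernels are flip-symmetric up to sign,
#' so the choice is absorbed by the learned weights.
#'
#' Implemented as a single spatial convolution with the effective kernel
#' \eqn{K = \sum_{u,v} w_{u,v}\gamma(u,v)}, which is algebraically identical
#' to summing per-frequency responses.
#'
#' @param x feature array `(H, W, C, N)`; rank-2/3 inputs are promoted.
#' @param weights array `(f, f, C, D)`; entry `[u+1, v+1, n, d]` is the weight
#'   of frequency `(u, v)` of input channel `n` for output channel `d`.
#' @param bank a [dct_filter_bank()]; its size must match `weights`.
#' @param bias optional numeric vector of length `D`.
#' @return feature array `(H, W, D, N)`.
#' @examples
#' bank <- dct_filter_bank(3)
#' x <- array(rnorm(64), c(8, 8, 1, 1))
#' w <- array(0, c(3, 3, 1, 1)); w[1, 1, 1, 1] <- 1   # select DC kernel
#' y <- harmonic_conv(x, w, bank)                     # 3x3 local sum / 3
#' @export
harmonic_conv <- function(x, weights, bank, bias = NULL) {
  x <- as_feature_array(x)
  f <- bank$size
  d <- dim(weights)
  if (length(d) != 4L) stop("weights must have dim (f, f, C, D)")
  if (d[3] != dim(x)[3])
    stop(sprintf("channel mismatch: input has %d channels, weights expect %d",
                 dim(x)[3], d[3]))
  if (dim(x)[1] < f || dim(x)[2] < f)
    stop("spatial dimensions must be at least the kernel size")
  K <- harmonic_effective_kernel(weights, bank)
  pad <- (f - 1L) %/% 2L
  .cpp_conv2d_fw(x, K, bias, pad, pad)
}
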
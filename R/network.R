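#' Harmonic attention U-Net for ultrasound segmentation
#'
#' Builds the encoder-decoder segmentation network. Five encoder levels with
#' channel widths `base_width * c(1, 2, 4, 8, 16)`:
#' \itemize{
#'   \item level 1: harmonic convolution + 1-D factorized pair (3x1 then 1x3
#'     standard convolutions), each convolution followed by batch
#'     normalization and ReLU;
#'   \item level 2: harmonic convolution + factorized pair + harmonic
#'     attention (HA) block;
#'   \item levels 3-5: harmonic convolution + HA block.
#' }
#' 2x2 max pooling between levels. The decoder mirrors the encoder: 2x2
#' transpose convolutions for upsampling, concatenation with the same-level
#' encoder features, then the level's block with harmonic convolutions.
#' A final 1x1 convolution produces one logit map; the sigmoid is applied at
#' prediction time. With `use_attention = FALSE` every HA block is dropped,
#' giving the harmonic-convolution baseline ("BL") used for the attention
#' ablation.
#'
#' Input height and width must be divisible by `2^4 = 16`.
#'
#' @param base_width channels at the first level (64 for the full model;
#'   8 is convenient for CPU-scale experiments).
#' @param in_channels input image channels (1 for B-mode ultrasound).
#' @param f DCT kernel size of the harmonic convolutions (odd, default 3).
#' @param ha_reduction channel-reduction ratio of the HA blocks; clamped per
#'   layer so the bottleneck keeps at least 4 channels and divides the width.
#' @param use_attention include the HA blocks (`FALSE` = baseline model).
#' @param seed optional seed for weight initialization.
#' @return an object of class `harmonic_unet`.
#' @examples
#' net <- harmonic_unet(base_width = 8, seed = 1)
#' n_parameters(net)
#' @export
harmonic_unet <- function(base_width = 64L, in_channels = 1L, f = 3L,
                          ha_reduction = 16L, use_attention = TRUE,
                          seed = NULL) {
  cfg <- list(base_width = as.integer(base_width),
              in_channels = as.integer(in_channels), f = as.integer(f),
              depth = 5L, ha_reduction = as.integer(ha_reduction),
              use_attention = isTRUE(use_attention))
  with_seed(seed, {
    bank <- dct_filter_bank(cfg$f)
    ch <- cfg$base_width * 2L^(0:4)
    enc_block <- function(cin, cout, fact, ha) {
      mods <- list(mod_hconv(cfg$f, cin, cout, bank = bank), mod_bn(cout),
                   mod_relu())
      if (fact)
        mods <- c(mods, list(mod_conv(3L, 1L, cout, cout), mod_bn(cout),
                             mod_relu(), mod_conv(1L, 3L, cout, cout),
                             mod_bn(cout), mod_relu()))
      if (ha && cfg$use_attention)
        mods <- c(mods, list(mod_ha(cout, cfg$ha_reduction)))
      mods
    }
    net <- new.env(parent = emptyenv())
    net$cfg <- cfg
    net$bank <- bank
    net$enc <- list(
      enc_block(cfg$in_channels, ch[1], fact = TRUE, ha = FALSE),
      enc_block(ch[1], ch[2], fact = TRUE, ha = TRUE),
      enc_block(ch[2], ch[3], fact = FALSE, ha = TRUE),
      enc_block(ch[3], ch[4], fact = FALSE, ha = TRUE),
      enc_block(ch[4], ch[5], fact = FALSE, ha = TRUE))
    net$enc[[1]][[1]]$first <- TRUE   # no input gradient needed at level 1
    net$pools <- lapply(1:4, function(i) mod_maxpool())
    net$ups <- lapply(4:1, function(l)
      list(mod_upconv(ch[l + 1], ch[l]), mod_bn(ch[l]), mod_relu()))
    net$decs <- lapply(4:1, function(l)
      enc_block(2L * ch[l], ch[l], fact = l <= 2, ha = l >= 2))
    net$head <- list(mod_conv(1L, 1L, ch[1], 1L, bias = TRUE))
    net$modules <- c(unlist(net$enc, recursive = FALSE),
                     net$pools,
                     unlist(net$ups, recursive = FALSE),
                     unlist(net$decs, recursive = FALSE),
                     net$head)
    class(net) <- "harmonic_unet"
    net
  })
}

#' @export
print.harmonic_unet <- function(x, ...) {
  cat(sprintf(paste0("<harmonic_unet> base_width=%d, f=%d, depth=%d, ",
                     "attention=%s, %s parameters\n"),
              x$cfg$base_width, x$cfg$f, x$cfg$depth,
              x$cfg$use_attention, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of learnable parameters
#'
#' Counts all learnable entries: convolution weights and biases, batch-norm
#' scale/shift pairs, and attention-block weights. Running batch-norm
#' statistics are not learnable and are excluded.
#'
#' @param net a `harmonic_unet`.
#' @return integer count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$modules, function(m)
    sum(vapply(m$params, function(p) length(get(p, envir = m)), 0)), 0))
}

check_input_dims <- function(net, d) {
  div <- 2L^(net$cfg$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("input height and width must be divisible by %d (got %dx%d)",
                 div, d[1], d[2]))
  if (d[3] != net$cfg$in_channels)
    stop(sprintf("input has %d channels; network expects %d",
                 d[3], net$cfg$in_channels))
}

#' Network forward pass
#'
#' Runs the encoder-decoder and returns the logit map (no sigmoid).
#' With `train = TRUE` batch statistics are used for batch normalization and
#' intermediate activations are cached for [backward_network()].
#'
#' @param net a `harmonic_unet`.
#' @param x feature array `(H, W, C, N)` (rank-2/3 inputs promoted); `H` and
#'   `W` divisible by 16.
#' @param train logical; training mode.
#' @return logits, array `(H, W, 1, N)`.
#' @export
forward_network <- function(net, x, train = FALSE) {
  x <- as_feature_array(x)
  check_input_dims(net, dim(x))
  e <- vector("list", 5L)
  h <- x
  for (l in 1:5) {
    h <- seq_forward(net$enc[[l]], h, train)
    e[[l]] <- h
    if (l < 5) h <- mod_forward(net$pools[[l]], h, train)
  }
  net$.enc_out <- e
  d <- e[[5]]
  for (k in 1:4) {                 # k = 1..4 corresponds to levels 4..1
    u <- seq_forward(net$ups[[k]], d, train)
    d <- seq_forward(net$decs[[k]], cat_channels(u, e[[5L - k]]), train)
  }
  seq_forward(net$head, d, train)
}

# Backward pass through the whole network; gradients accumulate in the
# modules. `glogits` is dLoss/dlogits with the same shape as the forward
# output. Must follow a forward_network(..., train = TRUE) call.
backward_network <- function(net, glogits) {
  ch <- net$cfg$base_width * 2L^(0:4)
  g <- seq_backward(net$head, glogits)
  gskip <- vector("list", 5L)      # gradient w.r.t. encoder outputs
  for (k in 4:1) {                 # decoder blocks in reverse (levels 1..4)
    l <- 5L - k
    gc <- seq_backward(net$decs[[k]], g)
    cu <- ch[l]                    # up-path channels at this level
    gu <- gc[, , seq_len(cu), , drop = FALSE]
    gs <- gc[, , cu + seq_len(cu), , drop = FALSE]
    gskip[[l]] <- if (is.null(gskip[[l]])) gs else gskip[[l]] + gs
    g <- seq_backward(net$ups[[k]], gu)
  }
  ge <- g                          # gradient w.r.t. e5
  for (l in 5:1) {
    if (!is.null(gskip[[l]])) ge <- ge + gskip[[l]]
    ge <- seq_backward(net$enc[[l]], ge)
    if (l > 1) ge <- mod_backward(net$pools[[l - 1L]], ge)
  }
  invisible(NULL)
}

#' Predict a binary mask for one image
#'
#' Normalized image in, binary mask out. If the image dimensions are not
#' divisible by 16 the image is resized (bilinear) to the nearest admissible
#' size for the forward pass and the outputs are resized back (nearest
#' neighbour for the mask). Pixels with probability strictly above
#' `threshold` are foreground.
#'
#' @param net a `harmonic_unet`.
#' @param image 2-D matrix with values in `[0, 1]`.
#' @param threshold probability cut for the mask (default 0.5).
#' @return list with `mask` (integer 0/1 matrix, input resolution) and
#'   `prob` (probability map at input resolution).
#' @export
predict_mask <- function(net, image, threshold = 0.5) {
  if (is.null(dim(image)) || length(dim(image)) != 2L)
    stop("'image' must be a 2-D matrix")
  d0 <- dim(image)
  div <- 2L^(net$cfg$depth - 1L)
  dn <- pmax(div, as.integer(round(d0 / div)) * div)
  x <- if (all(dn == d0)) image else resize_image(image, dn[1], dn[2])
  logits <- forward_network(net, x, train = FALSE)
  prob <- matrix(plogis(logits), dn[1], dn[2])
  if (!all(dn == d0)) prob <- resize_image(prob, d0[1], d0[2])
  mask <- matrix(as.integer(prob > threshold), d0[1], d0[2])
  list(mask = mask, prob = prob)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the architecture configuration together with all
#' learnable parameters and batch-norm running statistics, so
#' [load_checkpoint()] reconstructs a functionally identical model.
#'
#' @param net a `harmonic_unet`.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `harmonic_unet`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, state = module_state(net$modules)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- harmonic_unet(base_width = ck$cfg$base_width,
                       in_channels = ck$cfg$in_channels, f = ck$cfg$f,
                       ha_reduction = ck$cfg$ha_reduction,
                       use_attention = ck$cfg$use_attention, seed = 0L)
  restore_module_state(net$modules, ck$state)
  net
}
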
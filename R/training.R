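# preprocessing, augmentation and the training loop

#' Resize helpers
#'
#' `resize_image` uses bilinear interpolation; `resize_mask` uses nearest
#' neighbour so mask values stay binary.
#'
#' @param x 2-D matrix.
#' @param h,w target size.
#' @return resized matrix.
#' @export
resize_image <- function(x, h, w) {
  as.matrix(EBImage::resize(EBImage::Image(x), w = h, h = w))
}

#' @rdname resize_image
#' @export
resize_mask <- function(x, h, w) {
  out <- as.matrix(EBImage::resize(EBImage::Image(x), w = h, h = w,
                                   filter = "none"))
  matrix(as.integer(out > 0.5), h, w)
}

#' Preprocess an image for the network
#'
#' Resizes to `size x size` (bilinear) and normalizes pixel values to
#' `[0, 1]`. Inputs with a maximum above 1 are taken to be 8-bit (0-255)
#' and divided by 255; inputs already in `[0, 1]` are left on that scale.
#'
#' @param image 2-D grayscale matrix.
#' @param size target side length (default 384, divisible by 16).
#' @return `size x size` matrix in `[0, 1]`.
#' @export
preprocess_image <- function(image, size = 384L) {
  if (is.null(dim(image)) || length(dim(image)) != 2L || length(image) == 0L)
    stop("'image' must be a non-empty 2-D matrix")
  if (max(image) > 1) image <- image / 255
  image <- pmin(pmax(image, 0), 1)
  if (!all(dim(image) == c(size, size))) image <- resize_image(image, size, size)
  image
}

#' Paired geometric transform of image and mask
#'
#' Applies the same horizontal flip and rotation to an image and its mask.
#' The image is rotated with bilinear interpolation, the mask with nearest
#' neighbour; both keep their original size (corners introduced by rotation
#' are filled with 0).
#'
#' @param image 2-D matrix.
#' @param mask binary matrix of the same shape.
#' @param angle rotation angle in degrees.
#' @param flip logical, horizontal (left-right) flip.
#' @return list with transformed `image` and `mask`.
#' @export
transform_pair <- function(image, mask, angle = 0, flip = FALSE) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have identical shapes")
  if (flip) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (angle != 0) {
    d <- dim(image)
    image <- as.matrix(EBImage::rotate(EBImage::Image(image), angle,
                                       output.dim = d, bg.col = 0))
    mask <- as.matrix(EBImage::rotate(EBImage::Image(mask), angle,
                                      filter = "none", output.dim = d,
                                      bg.col = 0))
  }
  list(image = pmin(pmax(image, 0), 1),
       mask = matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask)))
}

#' Random training augmentation
#'
#' Draws a rotation angle uniformly in `[-max_rotate, max_rotate]` degrees
#' and a horizontal flip with probability `flip_prob`, and applies both to
#' the image/mask pair via [transform_pair()]. With a `seed` the draw is
#' reproducible and the caller's RNG state is untouched.
#'
#' @param image 2-D matrix.
#' @param mask binary matrix of the same shape.
#' @param max_rotate maximal absolute rotation in degrees (default 15).
#' @param flip_prob horizontal-flip probability (default 0.5).
#' @param seed optional integer seed.
#' @return list with `image`, `mask`, `angle`, `flip`.
#' @export
augment_pair <- function(image, mask, max_rotate = 15, flip_prob = 0.5,
                         seed = NULL) {
  with_seed(seed, {
    angle <- runif(1, -max_rotate, max_rotate)
    flip <- runif(1) < flip_prob
    out <- transform_pair(image, mask, angle, flip)
    out$angle <- angle
    out$flip <- flip
    out
  })
}

#' Training configuration
#'
#' Defaults follow the published recipe: 384x384 inputs normalized to
#' `[0, 1]`, Adam with \eqn{\beta_1 = 0.5}, \eqn{\beta_2 = 0.999} and
#' learning rate 2e-4, batch size 4, 50 epochs, augmentation by random
#' 15-degree rotations and horizontal flips, and a step decay of the
#' learning rate when the validation Dice plateaus for two consecutive
#' epochs. The decay factor (0.5) is a package choice.
#'
#' @param input_size network input side length, divisible by 16.
#' @param lr initial learning rate.
#' @param adam_beta1,adam_beta2 Adam moment coefficients.
#' @param epochs training epochs.
#' @param batch_size images per batch.
#' @param augment enable augmentation.
#' @param max_rotate,flip_prob augmentation parameters.
#' @param plateau_patience epochs without validation-Dice improvement before
#'   a learning-rate decay.
#' @param decay_factor multiplicative learning-rate decay.
#' @param loss a [loss_config()].
#' @param threshold probability threshold for validation masks.
#' @param seed optional seed controlling shuffling and augmentation.
#' @return a `train_config` list.
#' @export
train_config <- function(input_size = 384L, lr = 2e-4, adam_beta1 = 0.5,
                         adam_beta2 = 0.999, epochs = 50L, batch_size = 4L,
                         augment = TRUE, max_rotate = 15, flip_prob = 0.5,
                         plateau_patience = 2L, decay_factor = 0.5,
                         loss = loss_config(), threshold = 0.5, seed = NULL) {
  stopifnot(input_size > 0, input_size %% 16 == 0, lr > 0, epochs > 0,
            batch_size > 0, plateau_patience > 0, decay_factor > 0,
            adam_beta1 > 0, adam_beta2 > 0)
  structure(list(input_size = as.integer(input_size), lr = lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), augment = augment,
                 max_rotate = max_rotate, flip_prob = flip_prob,
                 plateau_patience = as.integer(plateau_patience),
                 decay_factor = decay_factor, loss = loss,
                 threshold = threshold, seed = seed),
            class = "train_config")
}

# one Adam update over all module parameters; state lives in the modules
adam_step <- function(mods, lr, beta1, beta2, t, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (m in mods) {
    for (p in m$params) {
      g <- m$g[[p]]
      if (is.null(g)) next
      mk <- paste0(".m_", p); vk <- paste0(".v_", p)
      mo <- if (is.null(m[[mk]])) g * 0 else m[[mk]]
      vo <- if (is.null(m[[vk]])) g * 0 else m[[vk]]
      mo <- beta1 * mo + (1 - beta1) * g
      vo <- beta2 * vo + (1 - beta2) * g * g
      assign(mk, mo, envir = m)
      assign(vk, vo, envir = m)
      assign(p, get(p, envir = m) - lr * (mo / bc1) / (sqrt(vo / bc2) + eps),
             envir = m)
    }
  }
  invisible(NULL)
}

# stack a list of (image, mask) pairs into batch arrays
stack_batch <- function(pairs) {
  h <- nrow(pairs[[1]]$image); w <- ncol(pairs[[1]]$image)
  n <- length(pairs)
  x <- array(0, c(h, w, 1L, n)); y <- array(0, c(h, w, 1L, n))
  for (i in seq_len(n)) {
    x[, , 1L, i] <- pairs[[i]]$image
    y[, , 1L, i] <- pairs[[i]]$mask
  }
  list(x = x, y = y)
}

validation_dice <- function(net, data, threshold) {
  mean(vapply(data, function(d) {
    pr <- predict_mask(net, d$image, threshold)
    unname(segmentation_metrics(d$mask, pr$mask)["dice"])
  }, 0))
}

#' Train a segmentation network
#'
#' Mini-batch training with Adam, optional augmentation, validation-Dice
#' tracking with a plateau learning-rate scheduler, and best-checkpoint
#' selection. Each dataset element is a list with `image` (matrix in
#' `[0, 1]`, already at the network input size) and `mask` (binary matrix of
#' the same size); see [phantom_pairs()] for building such lists from
#' generated phantoms.
#'
#' The learning rate is multiplied by `cfg$decay_factor` whenever the
#' validation Dice has not improved for `cfg$plateau_patience` consecutive
#' epochs. The returned model carries the parameters of the epoch with the
#' best validation Dice (or the final parameters if no validation data is
#' given).
#'
#' @param net a [harmonic_unet()].
#' @param train_data list of `(image, mask)` pairs.
#' @param val_data optional validation list in the same format.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `net` (trained model), `log` (data frame: epoch,
#'   train_loss, val_dice, lr, decayed), `best_val_dice`, `best_epoch`.
#' @export
train_network <- function(net, train_data, val_data = NULL,
                          cfg = train_config(), verbose = FALSE) {
  if (length(train_data) == 0L) stop("empty training dataset")
  with_seed(cfg$seed, {
    lr <- cfg$lr
    t <- 0L
    best <- -Inf; best_epoch <- NA_integer_; best_state <- NULL
    stall <- 0L
    log <- data.frame(epoch = integer(), train_loss = double(),
                      val_dice = double(), lr = double(), decayed = logical())
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(length(train_data))
      losses <- c()
      for (b in seq(1L, length(perm), by = cfg$batch_size)) {
        sel <- perm[b:min(b + cfg$batch_size - 1L, length(perm))]
        pairs <- lapply(train_data[sel], function(d) {
          if (cfg$augment)
            augment_pair(d$image, d$mask, cfg$max_rotate, cfg$flip_prob)
          else d
        })
        batch <- stack_batch(pairs)
        logits <- forward_network(net, batch$x, train = TRUE)
        p <- plogis(logits)
        loss <- combined_loss(batch$y, p, cfg$loss)
        if (!is.finite(loss)) stop("non-finite training loss at step ", t + 1L)
        losses <- c(losses, loss)
        glogits <- combined_grad(batch$y, p, cfg$loss) * p * (1 - p)
        dim(glogits) <- dim(logits)
        zero_grads(net$modules)
        backward_network(net, glogits)
        t <- t + 1L
        adam_step(net$modules, lr, cfg$adam_beta1, cfg$adam_beta2, t)
      }
      vd <- NA_real_
      decayed <- FALSE
      if (!is.null(val_data) && length(val_data)) {
        vd <- validation_dice(net, val_data, cfg$threshold)
        if (vd > best + 1e-6) {
          best <- vd; best_epoch <- epoch
          best_state <- module_state(net$modules)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$plateau_patience) {
            lr <- lr * cfg$decay_factor
            decayed <- TRUE
            stall <- 0L
          }
        }
      }
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_dice = vd, lr = lr, decayed = decayed))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %s  lr %.2e%s",
                        epoch, mean(losses),
                        ifelse(is.na(vd), "-", sprintf("%.4f", vd)), lr,
                        if (decayed) "  [lr decay]" else ""))
    }
    if (!is.null(best_state)) restore_module_state(net$modules, best_state)
    list(net = net, log = log,
         best_val_dice = if (is.finite(best)) best else NA_real_,
         best_epoch = best_epoch)
  })
}
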
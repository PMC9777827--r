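#' Training objectives
#'
#' Pixel-wise losses between a binary target mask `y` and a predicted
#' probability map `p` (values in (0, 1); inputs are clipped to
#' `[eps, 1 - eps]` with `eps = 1e-7`). All losses use the mean over pixels.
#'
#' \describe{
#'   \item{focal}{\eqn{-y (1-p)^\gamma \log p - (1-y) p^\gamma \log(1-p)};
#'     for \eqn{\gamma = 0} this is exactly binary cross-entropy.}
#'   \item{bce}{binary cross-entropy.}
#'   \item{dice}{\eqn{1 - (2\sum yp + s) / (\sum y + \sum p + s)} with
#'     smoothing `s = 1` (soft Dice).}
#' }
#'
#' The compound objective used for training is
#' \eqn{L = L_{BCE} + \eta L_{F}} with weighting factor \eqn{\eta = 0.6} and
#' focal exponent \eqn{\gamma = 2} by default; the `variant` field of
#' [loss_config()] selects the ablation alternatives `"bce"`, `"dice"`,
#' `"bce+dice"` and `"bce+focal"`.
#'
#' @param y binary target array.
#' @param p predicted probabilities, same shape as `y`.
#' @param gamma focal exponent (\eqn{\gamma \ge 0}).
#' @param smooth Dice smoothing constant.
#' @return a non-negative scalar.
#' @examples
#' focal_loss(1, 0.5, gamma = 2)          # 0.25 * log(2)
#' combined_loss(1, 0.5, loss_config())   # log(2) + 0.6 * 0.25 * log(2)
#' @name losses
NULL

.loss_eps <- 1e-7

clip_prob <- function(p) pmin(pmax(p, .loss_eps), 1 - .loss_eps)

check_loss_args <- function(y, p) {
  if (length(y) != length(p)) stop("'y' and 'p' must have the same shape")
  if (!is_binary(y)) stop("'y' must be binary (0/1)")
}

#' @rdname losses
#' @export
bce_loss <- function(y, p) {
  check_loss_args(y, p)
  p <- clip_prob(p)
  mean(-y * log(p) - (1 - y) * log(1 - p))
}

#' @rdname losses
#' @export
focal_loss <- function(y, p, gamma = 2) {
  check_loss_args(y, p)
  stopifnot(gamma >= 0)
  p <- clip_prob(p)
  mean(-y * (1 - p)^gamma * log(p) - (1 - y) * p^gamma * log(1 - p))
}

#' @rdname losses
#' @export
dice_loss <- function(y, p, smooth = 1) {
  check_loss_args(y, p)
  p <- clip_prob(p)
  1 - (2 * sum(y * p) + smooth) / (sum(y) + sum(p) + smooth)
}

#' Loss configuration
#'
#' @param variant one of `"bce"`, `"dice"`, `"bce+dice"`, `"bce+focal"`.
#' @param eta weight of the focal (or Dice) term added to BCE (default 0.6).
#' @param gamma focal exponent (default 2).
#' @return a `loss_config` list.
#' @export
loss_config <- function(variant = c("bce+focal", "bce", "dice", "bce+dice"),
                        eta = 0.6, gamma = 2) {
  variant <- match.arg(variant)
  stopifnot(eta >= 0, gamma >= 0)
  structure(list(variant = variant, eta = eta, gamma = gamma),
            class = "loss_config")
}

#' @rdname losses
#' @param cfg a [loss_config()].
#' @export
combined_loss <- function(y, p, cfg = loss_config()) {
  if (!inherits(cfg, "loss_config")) stop("'cfg' must be a loss_config()")
  switch(cfg$variant,
    "bce" = bce_loss(y, p),
    "dice" = dice_loss(y, p),
    "bce+dice" = bce_loss(y, p) + cfg$eta * dice_loss(y, p),
    "bce+focal" = bce_loss(y, p) + cfg$eta * focal_loss(y, p, cfg$gamma),
    stop("unknown loss variant: ", cfg$variant))
}

# dLoss/dp (mean reduction included), same shape as p
bce_grad <- function(y, p) {
  p <- clip_prob(p)
  (-y / p + (1 - y) / (1 - p)) / length(p)
}

focal_grad <- function(y, p, gamma = 2) {
  p <- clip_prob(p)
  gpos <- gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p
  gneg <- -gamma * p^(gamma - 1) * log(1 - p) + p^gamma / (1 - p)
  if (gamma == 0) { gpos <- -1 / p; gneg <- 1 / (1 - p) }
  (y * gpos + (1 - y) * gneg) / length(p)
}

dice_grad <- function(y, p, smooth = 1) {
  p <- clip_prob(p)
  den <- sum(y) + sum(p) + smooth
  num <- 2 * sum(y * p) + smooth
  -(2 * y * den - num) / den^2
}

combined_grad <- function(y, p, cfg = loss_config()) {
  switch(cfg$variant,
    "bce" = bce_grad(y, p),
    "dice" = dice_grad(y, p),
    "bce+dice" = bce_grad(y, p) + cfg$eta * dice_grad(y, p),
    "bce+focal" = bce_grad(y, p) + cfg$eta * focal_grad(y, p, cfg$gamma))
}
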
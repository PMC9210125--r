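# Training objectives: pixel-wise MSE content loss, the adversarial
# generator loss -log D(G(X)) and the discriminator's binary cross-entropy,
# combined as total = a1 * content + a2 * adversarial.

#' Loss weights
#'
#' Weighting of the content (MSE) and adversarial terms in the generator's
#' total loss.  The defaults (1 and 0.001) follow the standard SR-GAN
#' weighting; both are configurable.
#'
#' @param a1 Non-negative weight of the content term.
#' @param a2 Non-negative weight of the adversarial term.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(a1 = 1, a2 = 0.001) {
  if (a1 < 0 || a2 < 0 || a1 + a2 <= 0)
    stop("weights must be non-negative with a1 + a2 > 0")
  structure(list(a1 = a1, a2 = a2), class = "loss_weights")
}

#' Content loss (mean squared error)
#'
#' Mean squared pixel difference between the super-resolved and the
#' ground-truth HR image; the `1/(r^2 W H)` normalisation over the
#' `rW x rH` pixels is exactly the mean.
#'
#' @param sr,hr [grayscale_image]s (or matrices) of identical dimensions.
#' @return Non-negative scalar.
#' @export
content_loss <- function(sr, hr) {
  a <- as_image_matrix(sr); b <- as_image_matrix(hr)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch: %d x %d vs %d x %d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  mean((a - b)^2)
}

check_scores <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop("discriminator scores must lie strictly inside (0, 1)")
  s
}

#' Adversarial generator loss
#'
#' `-log D(G(X))` summed over the batch and divided by the batch size, so
#' the loss magnitude is batch-invariant.  Small when the generator fools
#' the discriminator (scores near 1).
#'
#' @param scores Discriminator probabilities on generated images, each in
#'   `(0, 1)`.
#' @return Non-negative scalar.
#' @export
adversarial_generator_loss <- function(scores) {
  -mean(log(check_scores(as.numeric(scores))))
}

#' Discriminator loss
#'
#' The negation of the adversarial value function, for minimisation:
#' `-mean(log(real)) - mean(log(1 - fake))`.
#'
#' @param real_scores,fake_scores Probabilities in `(0, 1)` on real HR and
#'   generated SR images.
#' @return Non-negative scalar; approaches 0 under perfect discrimination.
#' @export
discriminator_loss <- function(real_scores, fake_scores) {
  r <- check_scores(as.numeric(real_scores))
  f <- check_scores(as.numeric(fake_scores))
  -mean(log(r)) - mean(log(1 - f))
}

#' Total generator loss
#'
#' @param content Content (MSE) loss value.
#' @param adversarial Adversarial loss value.
#' @param weights A [loss_weights].
#' @return A `loss_breakdown` list with `content`, `adversarial`, `total`
#'   (`= a1 * content + a2 * adversarial`, exactly) and the weights used.
#' @export
total_loss <- function(content, adversarial, weights = loss_weights()) {
  if (!is.finite(content) || !is.finite(adversarial))
    stop("loss components must be finite")
  structure(list(content = content, adversarial = adversarial,
                 total = weights$a1 * content + weights$a2 * adversarial,
                 weights = weights),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss: total %.6g = %.3g * content %.6g + %.3g * adversarial %.6g>\n",
              x$total, x$weights$a1, x$content, x$weights$a2, x$adversarial))
  invisible(x)
}
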
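# Binary discriminator distinguishing real HR images from generated SR
# images: eight 3x3 convolutional layers with channels rising from 64 to 512
# and stride-2 convolutions (no pooling anywhere) halving the resolution
# four times, batch normalisation after layers 2-8, two dense layers and a
# sigmoid probability output.  The activation is plain ReLU.

#' Discriminator architecture specification
#'
#' @param channels Eight convolution channel counts, non-decreasing
#'   (default 64, 64, 128, 128, 256, 256, 512, 512).
#' @param strides Eight strides; the four stride-2 layers halve the spatial
#'   size (default 1, 2, 1, 2, 1, 2, 1, 2).
#' @param dense_width Width of the first dense layer.
#' @param use_batchnorm Batch-normalise after convolutions 2-8.
#' @param activation `"relu"` (default) or `"leaky_relu"` is not offered:
#'   plain ReLU is the pinned choice.
#' @return A validated `discriminator_spec`.
#' @export
discriminator_spec <- function(channels = c(64L, 64L, 128L, 128L, 256L, 256L,
                                            512L, 512L),
                               strides = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
                               dense_width = 1024L, use_batchnorm = TRUE,
                               activation = "relu") {
  channels <- as.integer(channels)
  strides <- as.integer(strides)
  if (length(channels) != 8L || any(channels < 1L))
    stop("exactly 8 convolution layers are required")
  if (any(diff(channels) < 0L))
    stop("channel counts must be non-decreasing")
  if (length(strides) != 8L || !all(strides %in% c(1L, 2L)))
    stop("strides must be 8 values in {1, 2}")
  if (sum(strides == 2L) != 4L)
    stop("exactly four stride-2 layers are required (16x total reduction)")
  if (!identical(activation, "relu")) stop("activation must be 'relu'")
  if (dense_width < 1L) stop("dense_width must be >= 1")
  structure(list(channels = channels, strides = strides,
                 dense_width = as.integer(dense_width),
                 use_batchnorm = isTRUE(use_batchnorm),
                 activation = activation),
            class = "discriminator_spec")
}

#' Build a discriminator
#'
#' @param spec A [discriminator_spec].
#' @param input_side Input image side in pixels; must be divisible by 16
#'   (four stride-2 layers).  The dense layers operate on the flattened
#'   final feature maps, so the input side is fixed at build time.
#' @param seed Seed for weight initialisation.
#' @return A `medsr_discriminator` handle; see [discriminator_forward()].
#' @export
build_discriminator <- function(spec, input_side, seed = 0L) {
  if (!inherits(spec, "discriminator_spec"))
    stop("spec must be a discriminator_spec")
  input_side <- as.integer(input_side)
  if (input_side < 16L || input_side %% 16L != 0L)
    stop(sprintf("input_side %d must be divisible by 16", input_side))
  mod <- new_module()
  disc <- new.env(parent = emptyenv())
  disc$spec <- spec
  disc$input_side <- input_side
  disc$mod <- mod
  disc$final_side <- input_side %/% 16L
  disc$final_channels <- spec$channels[8L]
  with_seed(seed, {
    convs <- lapply(1:8, function(i)
      layer_conv(mod, sprintf("conv%d", i),
                 if (i == 1L) 1L else spec$channels[i - 1L],
                 spec$channels[i], k = 3L, stride = spec$strides[i],
                 act = FALSE))
    bns <- lapply(1:8, function(i) {
      if (spec$use_batchnorm && i > 1L)
        layer_batchnorm(mod, sprintf("bn%d", i), spec$channels[i])
    })
    fin <- disc$final_side^2 * spec$channels[8L]
    d1 <- layer_dense(mod, "dense1", fin, spec$dense_width)
    d2 <- layer_dense(mod, "dense2", spec$dense_width, 1L)
    disc$forward_node <- function(x, train = FALSE) {
      for (i in 1:8) {
        x <- convs[[i]](x)
        if (!is.null(bns[[i]])) x <- bns[[i]](x, train = train)
        x <- nd_relu(x)
      }
      s <- nd_sigmoid(d2(nd_relu(d1(nd_flatten(x)))))
      nd_clamp(s, 1e-7, 1 - 1e-7)
    }
  })
  class(disc) <- "medsr_discriminator"
  disc
}

#' @export
print.medsr_discriminator <- function(x, ...) {
  cat(sprintf("<discriminator: channels %s, input %dx%d, final maps %d @ %dx%d, %d parameters>\n",
              paste(x$spec$channels, collapse = "/"), x$input_side,
              x$input_side, x$final_channels, x$final_side, x$final_side,
              n_params(x)))
  invisible(x)
}

#' Score images with a discriminator
#'
#' Returns the probability (sigmoid output, clamped into the open interval
#' `(0, 1)` by `1e-7` for finite log-losses) that each input is a real HR
#' image.  Deterministic for fixed parameters and input.
#'
#' @param disc A `medsr_discriminator` handle.
#' @param imgs A [grayscale_image] or list of them, each of the handle's
#'   `input_side`.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
discriminator_forward <- function(disc, imgs) {
  if (!is.list(imgs)) imgs <- list(imgs)
  x <- batch_from_images(imgs, disc$input_side)
  as.numeric(disc$forward_node(nd_const(x), train = FALSE)$value)
}

#' Fit a discriminator on labelled image sets
#'
#' Trains the discriminator alone with Adam on a fixed batch of real and
#' fake images, minimising [discriminator_loss()].  Used to verify that the
#' adversarial half of the model is trainable (e.g. separating two toy
#' image classes) and for discriminator warm-up experiments.
#'
#' @param disc A `medsr_discriminator` handle (updated in place).
#' @param real,fake Lists of [grayscale_image]s of the handle's input side.
#' @param steps Number of update steps.
#' @param rate Learning rate.
#' @param betas Adam moment parameters.
#' @return The handle, invisibly.
#' @export
fit_discriminator <- function(disc, real, fake, steps = 100L, rate = 1e-3,
                              betas = c(0.9, 0.999)) {
  # real and fake are scored in one mixed batch so batch-normalisation
  # statistics retain the between-class contrast
  x <- batch_from_images(c(real, fake), disc$input_side)
  nr <- length(real)
  idx_fake <- nr + seq_along(fake)
  for (s in seq_len(steps)) {
    sc <- disc$forward_node(nd_const(x), train = TRUE)
    dl <- new_node(-mean(log(sc$value[seq_len(nr)])) -
                     mean(log(1 - sc$value[idx_fake])),
                   list(sc), function(n) {
      g <- numeric(length(sc$value))
      g[seq_len(nr)] <- -1 / (nr * sc$value[seq_len(nr)])
      g[idx_fake] <- 1 / (length(idx_fake) * (1 - sc$value[idx_fake]))
      accum_grad(sc, n$grad * matrix(g, ncol = 1L))
    })
    if (!is.finite(dl$value)) stop("non-finite discriminator loss")
    nd_backward(dl)
    adam_step(disc$mod, ensure_optimizer(disc), rate, betas[1], betas[2])
  }
  invisible(disc)
}

batch_from_images <- function(imgs, side = NULL) {
  mats <- lapply(imgs, as_image_matrix)
  h <- nrow(mats[[1L]]); w <- ncol(mats[[1L]])
  if (!is.null(side) && (h != side || w != side))
    stop(sprintf("image size %d x %d does not match expected side %d", h, w, side))
  x <- array(0, c(h, w, 1L, length(mats)))
  for (i in seq_along(mats)) {
    if (nrow(mats[[i]]) != h || ncol(mats[[i]]) != w)
      stop("all images in a batch must share dimensions")
    x[, , 1L, i] <- mats[[i]]
  }
  x
}
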
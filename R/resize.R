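# Separable polynomial resampling.
#
# Both the degradation operator (bicubic downscale) and all upsampling in
# the package are separable linear maps: out = Wr %*% img %*% t(Wc), where
# Wr/Wc are 1-D resampling weight matrices.  The cubic kernel is the Keys
# kernel with a = -0.5 (the convention used throughout the super-resolution
# literature); downscaling applies an antialiasing prefilter by widening the
# kernel support by the inverse scale, and sampling uses the
# align-corners-false grid (output pixel i maps to input coordinate
# (i + 0.5)/scale - 0.5).  Edges are handled by clamping source indices
# (replicate padding) and each output row of weights is normalised to sum
# to one, so constant images are resampled exactly.

cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

linear_kernel <- function(t) {
  t <- abs(t)
  ifelse(t < 1, 1 - t, 0)
}

# Weight matrix mapping a length-`n_in` signal to length `n_out`.
resample_matrix <- function(n_in, n_out, kernel = c("cubic", "linear"),
                            antialias = TRUE) {
  kernel <- match.arg(kernel)
  kfun <- if (kernel == "cubic") cubic_kernel else linear_kernel
  support <- if (kernel == "cubic") 2 else 1
  scale <- n_out / n_in
  kscale <- 1
  if (antialias && scale < 1) {
    kscale <- scale
    support <- support / scale
  }
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    center <- (i - 0.5) / scale - 0.5          # 0-based input coordinate
    lo <- floor(center - support + 1)
    hi <- ceiling(center + support - 1)
    idx <- lo:hi
    w <- kfun((center - idx) * kscale)
    keep <- w != 0
    if (!any(keep)) {
      idx <- round(center)
      w <- 1
    } else {
      idx <- idx[keep]
      w <- w[keep]
    }
    idx <- pmin(pmax(idx, 0), n_in - 1)        # replicate edges
    w <- w / sum(w)
    for (j in seq_along(idx)) W[i, idx[j] + 1L] <- W[i, idx[j] + 1L] + w[j]
  }
  W
}

resample_2d <- function(m, h_out, w_out, kernel = "cubic", antialias = TRUE) {
  Wr <- resample_matrix(nrow(m), h_out, kernel, antialias)
  Wc <- resample_matrix(ncol(m), w_out, kernel, antialias)
  Wr %*% m %*% t(Wc)
}

#' Bicubic downscaling (the degradation operator)
#'
#' Produces the low-resolution counterpart of a high-resolution image by
#' bicubic resampling with an antialiasing prefilter, the degradation model
#' under which all training pairs are constructed.
#'
#' @param hr A [grayscale_image] (or numeric matrix in \[0, 1\]) whose height
#'   and width are both divisible by `scale`.
#' @param scale Integer downsampling factor, one of 2, 4, 8.
#' @return A `grayscale_image` of size `dim(hr) / scale`, clipped to \[0, 1\].
#' @seealso [upsample_bicubic()], [make_pairs()]
#' @examples
#' hr <- generate_phantom(phantom_spec(size = 64, seed = 1))
#' lr <- downscale_bicubic(hr, 4)
#' dim(lr)
#' @export
downscale_bicubic <- function(hr, scale) {
  r <- scale_factor(scale)
  m <- as_image_matrix(hr)
  if (nrow(m) %% r != 0L || ncol(m) %% r != 0L)
    stop(sprintf("image size %d x %d is not divisible by scale %d (no implicit cropping)",
                 nrow(m), ncol(m), r))
  grayscale_image(clip01(resample_2d(m, nrow(m) %/% r, ncol(m) %/% r,
                                     "cubic", antialias = TRUE)))
}

#' Bicubic upsampling
#'
#' Bicubic interpolation to `scale` times the input size; used both as the
#' weakest baseline method and to lift the low-resolution input to target
#' size before the generator's stem.
#'
#' @param lr A [grayscale_image] or numeric matrix in \[0, 1\].
#' @param scale Integer upsampling factor, one of 2, 4, 8.
#' @return A `grayscale_image` of size `dim(lr) * scale`, clipped to \[0, 1\].
#' @export
upsample_bicubic <- function(lr, scale) {
  r <- scale_factor(scale)
  m <- as_image_matrix(lr)
  grayscale_image(clip01(resample_2d(m, nrow(m) * r, ncol(m) * r,
                                     "cubic", antialias = FALSE)))
}
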
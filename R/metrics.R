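# Image-quality metrics on [0, 1] intensities: PSNR with peak 1 and SSIM
# with the standard 11x11 Gaussian window (sigma 1.5), K1 = 0.01,
# K2 = 0.03, computed on fully interior windows and averaged.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(1 / MSE)` in decibels, with peak intensity 1.  Identical
#' images (zero MSE) report `Inf`.
#'
#' @param a,b [grayscale_image]s (or matrices) of identical dimensions.
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0.5, 16, 16), matrix(0.6, 16, 16))  # 20 dB
#' @export
psnr <- function(a, b) {
  a <- as_image_matrix(a); b <- as_image_matrix(b)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch: %d x %d vs %d x %d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

gaussian_band <- function(n, win = 11L, sigma = 1.5) {
  if (n < win) stop(sprintf("image side %d is smaller than the %d-pixel window", n, win))
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  B <- matrix(0, n - win + 1L, n)
  for (i in seq_len(nrow(B))) B[i, i:(i + win - 1L)] <- g
  B
}

#' Structural similarity index
#'
#' Mean local SSIM over all fully interior 11x11 Gaussian windows
#' (sigma = 1.5), with stabilisers `C1 = (0.01)^2` and `C2 = (0.03)^2` for
#' dynamic range 1.
#'
#' @param a,b [grayscale_image]s (or matrices) of identical dimensions, with
#'   both sides at least 11.
#' @return SSIM in \[-1, 1\]; exactly 1 for identical images.
#' @export
ssim <- function(a, b) {
  a <- as_image_matrix(a); b <- as_image_matrix(b)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("dimension mismatch: %d x %d vs %d x %d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  Gr <- gaussian_band(nrow(a))
  Gc <- gaussian_band(ncol(a))
  filt <- function(m) Gr %*% m %*% t(Gc)
  C1 <- 0.01^2
  C2 <- 0.03^2
  mu_a <- filt(a); mu_b <- filt(b)
  va <- filt(a * a) - mu_a^2
  vb <- filt(b * b) - mu_b^2
  cab <- filt(a * b) - mu_a * mu_b
  m <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(m)
}
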
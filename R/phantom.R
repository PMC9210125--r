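# Synthetic anatomy-like phantoms.
#
# Ellipse-based grayscale phantoms (a large body ellipse, nested interior
# ellipses, small bright/dark circular lesions and a low-amplitude sinusoidal
# texture) give the super-resolution task sharp boundaries and small blobs to
# recover without shipping any imaging data.  They mimic CT slices only at
# the level of edges and blob-like lesions; no clinical realism is claimed.

#' Phantom specification
#'
#' @param size Square image side in pixels; at least 32 and divisible by 8
#'   (the stride of the deepest generator stream).
#' @param n_ellipses Number of nested interior ellipses.
#' @param n_lesions Number of small circular bright/dark lesions.
#' @param texture_amplitude Amplitude of the sinusoidal texture, in
#'   \[0, 0.5\] intensity units.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including the seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 256L, n_ellipses = 4L, n_lesions = 6L,
                         texture_amplitude = 0.06, seed = 0L) {
  size <- as.integer(size)
  if (is.na(size) || size < 32L || size %% 8L != 0L)
    stop("size must be >= 32 and divisible by 8")
  if (n_ellipses < 0L || n_lesions < 0L)
    stop("n_ellipses and n_lesions must be non-negative")
  if (texture_amplitude < 0 || texture_amplitude > 0.5)
    stop("texture_amplitude must lie in [0, 0.5]")
  if (seed < 0) stop("seed must be >= 0")
  structure(list(size = size, n_ellipses = as.integer(n_ellipses),
                 n_lesions = as.integer(n_lesions),
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(size, cx, cy, ax, ay, angle) {
  xs <- matrix(rep(seq_len(size) - cx, each = size), size, size)
  ys <- matrix(rep(seq_len(size) - cy, times = size), size, size)
  u <- cos(angle) * ys + sin(angle) * xs
  v <- -sin(angle) * ys + cos(angle) * xs
  (u / ay)^2 + (v / ax)^2 <= 1
}

#' Generate one phantom image
#'
#' Deterministic in `spec$seed`; the composited image always contains at
#' least one intensity step of magnitude >= 0.2 (the body boundary), so the
#' super-resolution task on phantoms is never trivial.
#'
#' @param spec A [phantom_spec].
#' @return A [grayscale_image] of side `spec$size`.
#' @examples
#' img <- generate_phantom(phantom_spec(size = 64, seed = 7))
#' range(img)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  S <- spec$size
  with_seed(spec$seed, {
    img <- matrix(stats::runif(1, 0.05, 0.15), S, S)
    any_feature <- spec$n_ellipses > 0L || spec$n_lesions > 0L ||
      spec$texture_amplitude > 0
    if (any_feature) {
      # body ellipse: fixed contrast >= 0.3 against the background
      body <- ellipse_mask(S, S / 2 + stats::runif(1, -S / 16, S / 16),
                           S / 2 + stats::runif(1, -S / 16, S / 16),
                           S * stats::runif(1, 0.32, 0.42),
                           S * stats::runif(1, 0.32, 0.42),
                           stats::runif(1, 0, pi))
      img[body] <- img[body] + stats::runif(1, 0.3, 0.45)
      if (spec$n_ellipses > 0L) {
        for (i in seq_len(spec$n_ellipses)) {
          m <- ellipse_mask(S, S / 2 + stats::runif(1, -S / 6, S / 6),
                            S / 2 + stats::runif(1, -S / 6, S / 6),
                            S * stats::runif(1, 0.05, 0.25),
                            S * stats::runif(1, 0.05, 0.25),
                            stats::runif(1, 0, pi))
          img[m] <- img[m] + stats::runif(1, -0.15, 0.25)
        }
      }
      if (spec$n_lesions > 0L) {
        for (i in seq_len(spec$n_lesions)) {
          rad <- stats::runif(1, max(1, S / 64), S / 16)
          m <- ellipse_mask(S, stats::runif(1, S / 4, 3 * S / 4),
                            stats::runif(1, S / 4, 3 * S / 4),
                            rad, rad, 0)
          img[m] <- img[m] + sample(c(-1, 1), 1) * stats::runif(1, 0.15, 0.35)
        }
      }
      if (spec$texture_amplitude > 0) {
        fx <- stats::runif(1, 2, 6)
        fy <- stats::runif(1, 2, 6)
        ph <- stats::runif(2, 0, 2 * pi)
        xs <- matrix(rep(seq_len(S) / S, each = S), S, S)
        ys <- matrix(rep(seq_len(S) / S, times = S), S, S)
        img <- img + spec$texture_amplitude *
          sin(2 * pi * fx * xs + ph[1]) * sin(2 * pi * fy * ys + ph[2])
      }
    }
    grayscale_image(clip01(img))
  })
}

#' Generate a phantom dataset
#'
#' Per-image seeds are a fixed hash of `(seed, index)` so datasets are
#' order-stable and reproducible.
#'
#' @param n Number of images (>= 1).
#' @param base_spec A [phantom_spec] whose fields (except seed) are shared
#'   by all images.
#' @param seed Dataset-level seed.
#' @return List of `n` [grayscale_image]s.
#' @export
generate_dataset <- function(n, base_spec, seed = 0L) {
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be >= 1")
  if (!inherits(base_spec, "phantom_spec")) stop("base_spec must be a phantom_spec")
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$seed <- as.integer(derive_seed(seed, i))
    generate_phantom(sp)
  })
}
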
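#' Validate a scale factor
#'
#' Supported linear downsampling factors between the high- and
#' low-resolution grids.
#'
#' @param r Integer scale factor; must be 2, 4 or 8.
#' @return The validated integer scale.
#' @export
scale_factor <- function(r) {
  if (length(r) != 1L || is.na(r) || r != as.integer(r) || !(r %in% c(2L, 4L, 8L)))
    stop("scale must be one of 2, 4, 8")
  as.integer(r)
}

#' Paired low-/high-resolution sample
#'
#' Binds an LR image to its HR counterpart at a given scale; the HR
#' dimensions must be exactly `scale` times the LR dimensions.
#'
#' @param lr,hr [grayscale_image]s.
#' @param scale Integer scale factor (2, 4 or 8).
#' @return A `paired_sample` list with elements `lr`, `hr`, `scale`.
#' @export
paired_sample <- function(lr, hr, scale) {
  r <- scale_factor(scale)
  lr <- grayscale_image(as_image_matrix(lr))
  hr <- grayscale_image(as_image_matrix(hr))
  if (nrow(hr) != r * nrow(lr) || ncol(hr) != r * ncol(lr))
    stop(sprintf("hr size %d x %d is not %d x lr size %d x %d",
                 nrow(hr), ncol(hr), r, nrow(lr), ncol(lr)))
  structure(list(lr = lr, hr = hr, scale = r), class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample: lr %d x %d -> hr %d x %d (scale %d)>\n",
              nrow(x$lr), ncol(x$lr), nrow(x$hr), ncol(x$hr), x$scale))
  invisible(x)
}

#' Dihedral data augmentation
#'
#' Expands one image into its 8-member dihedral orbit: the original, its 90,
#' 180 and 270 degree rotations, and the horizontal (left-right) flip of
#' each — i.e. seven additional augmented versions per original image.
#'
#' @param img A [grayscale_image] or numeric matrix.
#' @return A list of 8 `grayscale_image`s:
#'   `original, rot90, rot180, rot270, flip, flip(rot90), flip(rot180),
#'   flip(rot270)`.
#' @examples
#' length(augment(generate_phantom(phantom_spec(size = 32, seed = 1))))
#' @export
augment <- function(img) {
  m <- as_image_matrix(grayscale_image(as_image_matrix(img)))
  rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]   # counter-clockwise
  fliplr <- function(x) x[, ncol(x):1, drop = FALSE]
  r1 <- rot90(m)
  r2 <- rot90(r1)
  r3 <- rot90(r2)
  lapply(list(m, r1, r2, r3, fliplr(m), fliplr(r1), fliplr(r2), fliplr(r3)),
         grayscale_image)
}

#' Construct LR/HR training pairs by bicubic degradation
#'
#' Each HR image is (optionally) expanded into its 8-member dihedral orbit
#' and bicubically downscaled to produce the paired LR input.
#'
#' @param hrs List of HR [grayscale_image]s, each with dimensions divisible
#'   by `scale`.
#' @param scale Integer scale factor (2, 4 or 8).
#' @param augment_flag If `TRUE`, apply [augment()] first (8 pairs per
#'   input image).
#' @return List of [paired_sample]s.
#' @examples
#' hrs <- generate_dataset(2, phantom_spec(size = 32), seed = 1)
#' length(make_pairs(hrs, 2, augment_flag = TRUE))
#' @export
make_pairs <- function(hrs, scale, augment_flag = FALSE) {
  r <- scale_factor(scale)
  if (!is.list(hrs)) hrs <- list(hrs)
  if (augment_flag) hrs <- do.call(c, lapply(hrs, augment))
  lapply(hrs, function(hr) paired_sample(downscale_bicubic(hr, r), hr, r))
}

#' Extract aligned LR/HR patch pairs
#'
#' Tiles the HR image with `hr_patch`-sized crops on a `stride` grid and
#' takes the exactly aligned LR crop (side `hr_patch / scale` at the
#' corresponding position) for each.  When more than `max_patches` positions
#' exist, a seeded subsample is drawn.
#'
#' @param pair A [paired_sample].
#' @param hr_patch HR patch side in pixels; divisible by `pair$scale` and at
#'   most the HR image side.
#' @param stride Step between patch origins on the HR grid (default:
#'   `hr_patch`, non-overlapping tiling).
#' @param max_patches Maximum number of patches to keep (default all).
#' @param seed Seed for the subsample when `max_patches` truncates.
#' @return List of [paired_sample]s of patch geometry.
#' @export
extract_patches <- function(pair, hr_patch, stride = hr_patch,
                            max_patches = Inf, seed = 0L) {
  r <- pair$scale
  H <- nrow(pair$hr)
  W <- ncol(pair$hr)
  if (hr_patch %% r != 0L) stop("hr_patch must be divisible by the scale factor")
  if (hr_patch > H || hr_patch > W)
    stop(sprintf("hr_patch %d exceeds image size %d x %d", hr_patch, H, W))
  if (stride < 1L) stop("stride must be >= 1")
  # patch origins are snapped to the LR grid so every HR crop at (r*i, r*j)
  # has an exactly aligned LR crop at (i, j)
  align <- function(p) unique((p - 1L) %/% r * r + 1L)
  tops <- align(seq(1L, H - hr_patch + 1L, by = stride))
  lefts <- align(seq(1L, W - hr_patch + 1L, by = stride))
  grid <- expand.grid(top = tops, left = lefts)
  if (nrow(grid) > max_patches) {
    keep <- with_seed(seed, sample.int(nrow(grid), max_patches))
    grid <- grid[sort(keep), , drop = FALSE]
  }
  lp <- hr_patch %/% r
  lapply(seq_len(nrow(grid)), function(i) {
    ti <- grid$top[i]
    le <- grid$left[i]
    lt <- (ti - 1L) %/% r + 1L
    ll <- (le - 1L) %/% r + 1L
    paired_sample(
      as_image_matrix(pair$lr)[lt:(lt + lp - 1L), ll:(ll + lp - 1L)],
      as_image_matrix(pair$hr)[ti:(ti + hr_patch - 1L), le:(le + hr_patch - 1L)],
      r)
  })
}
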
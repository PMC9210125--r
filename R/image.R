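#' Grayscale image container
#'
#' A grayscale image is a plain numeric matrix of intensities in \[0, 1\]
#' (rows = image height, columns = width) carrying the class
#' `"grayscale_image"`.  All functions in the package accept and return this
#' representation; the constructor only validates and tags.
#'
#' @param pixels Numeric matrix with all values in \[0, 1\].
#' @return A `grayscale_image` (numeric matrix).
#' @examples
#' img <- grayscale_image(matrix(runif(64), 8, 8))
#' dim(img)
#' @export
grayscale_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1] and contain no NA")
  structure(pixels, class = c("grayscale_image", "matrix"))
}

as_image_matrix <- function(img) {
  m <- unclass(img)
  attr(m, "class") <- NULL
  m
}

clip01 <- function(m) pmin(pmax(m, 0), 1)

#' @export
print.grayscale_image <- function(x, ...) {
  cat(sprintf("<grayscale_image %d x %d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All seeded operations in the package go
# through this helper so library calls never perturb user RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stable per-item seed derivation (kept below 2^31).
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 11) %% 2147483647
}
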
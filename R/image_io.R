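#' Read a grayscale image from PNG or TIFF
#'
#' Intensities are scaled by the source bit depth's maximum (255 or 65535)
#' into \[0, 1\].  Multi-channel inputs are collapsed to grayscale by the
#' mean of the colour channels (an alpha channel, if present, is dropped).
#'
#' @param path Path to an existing `.png`, `.tif` or `.tiff` file.
#' @return A [grayscale_image].
#' @seealso [write_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop(sprintf("unsupported image format '.%s' (PNG/TIFF only)", ext)))
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3L]
    if (nc %in% c(2L, 4L)) nc <- nc - 1L     # drop alpha
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1L, 2L), mean)
  }
  grayscale_image(clip01(a))
}

#' Write a grayscale image to PNG or TIFF
#'
#' Intensities are quantised to the nearest code value
#' (round-half-away-from-zero) at the requested bit depth, so a
#' write-then-read cycle changes no pixel by more than `1 / (2^bit_depth - 1)`.
#' 16-bit output requires TIFF (the PNG writer is 8-bit).
#'
#' @param img A [grayscale_image].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  m <- as_image_matrix(grayscale_image(as_image_matrix(img)))
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  ext <- tolower(tools::file_ext(path))
  peak <- 2^bit_depth - 1
  q <- floor(m * peak + 0.5) / peak
  if (ext == "png") {
    if (bit_depth != 8L)
      stop("PNG output is 8-bit; use TIFF for 16-bit images")
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = as.integer(bit_depth),
                    compression = "none")
  } else {
    stop(sprintf("unsupported image format '.%s' (PNG/TIFF only)", ext))
  }
  invisible(path)
}

list_image_files <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir))
  f <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                  full.names = TRUE)
  if (length(f) == 0L) stop(sprintf("no PNG/TIFF images in %s", dir))
  sort(f)
}

#' Timestamped key=value log line
#'
#' Structured logging used by the training loop and the command-line
#' interface: one line per event, `key=value` fields separated by spaces.
#'
#' @param ... Named atomic values to log.
#' @param file Optional path to append to; the line is always emitted with
#'   `message()` when `verbose` is `TRUE`.
#' @param verbose Emit to the console.
#' @return The formatted line, invisibly.
#' @export
log_line <- function(..., file = NULL, verbose = TRUE) {
  kv <- list(...)
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ",
                 paste(names(kv), vapply(kv, format, ""), sep = "=",
                       collapse = " "))
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  if (verbose) message(line)
  invisible(line)
}
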
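# End-to-end inference and benchmarking: super-resolve a directory of LR
# images with a checkpoint, score SR/HR directories with PSNR/SSIM, and
# compute the bicubic down-up baseline.

#' Super-resolve a directory of LR images
#'
#' Writes one SR PNG per LR input, named after the input's file stem, with
#' dimensions `scale` times the input and intensities clipped to \[0, 1\].
#' Output is deterministic for a fixed checkpoint and inputs.
#'
#' @param checkpoint Path to a file from [save_checkpoint()], or a
#'   `medsr_generator` handle.
#' @param lr_dir Directory of LR PNG/TIFF images.
#' @param scale Expected scale factor; must match the checkpoint's.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
super_resolve <- function(checkpoint, lr_dir, scale, out_dir) {
  gen <- if (inherits(checkpoint, "medsr_generator")) checkpoint
         else load_checkpoint(checkpoint)
  r <- scale_factor(scale)
  if (gen$scale != r)
    stop(sprintf("checkpoint was trained for scale %d, not %d", gen$scale, r))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list_image_files(lr_dir)) {
    sr <- generator_forward(gen, read_image(f))
    write_image(sr, file.path(out_dir,
                              paste0(tools::file_path_sans_ext(basename(f)),
                                     ".png")))
  }
  invisible(out_dir)
}

eval_result <- function(per_image) {
  summary <- do.call(rbind, lapply(split(per_image, per_image$method),
                                   function(d) {
    f <- d[is.finite(d$psnr), , drop = FALSE]
    data.frame(method = d$method[1L],
               psnr = if (nrow(f)) mean(f$psnr) else Inf,
               ssim = mean(d$ssim))
  }))
  rownames(summary) <- NULL
  structure(list(per_image = per_image, summary = summary,
                 n_infinite = sum(!is.finite(per_image$psnr))),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result: %d images", nrow(x$per_image)))
  if (x$n_infinite > 0)
    cat(sprintf(" (%d exact pairs excluded from means)", x$n_infinite))
  cat(">\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Evaluate SR images against HR ground truth
#'
#' Pairs files by identical name stem and reports per-image PSNR/SSIM plus
#' dataset means.  Exact pairs (infinite PSNR) are excluded from the means
#' and counted, so a single identical pair cannot dominate the average.
#'
#' @param sr_dir,hr_dir Directories with matching file stems and matching
#'   image dimensions.
#' @param method Label recorded in the result rows.
#' @return An `eval_result`: `per_image` data frame, `summary` of means and
#'   `n_infinite`.
#' @export
evaluate_pairs <- function(sr_dir, hr_dir, method = "model") {
  srf <- list_image_files(sr_dir)
  hrf <- list_image_files(hr_dir)
  stem <- function(f) tools::file_path_sans_ext(basename(f))
  hr_map <- stats::setNames(hrf, stem(hrf))
  rows <- lapply(srf, function(f) {
    hp <- hr_map[[stem(f)]]
    if (is.null(hp)) stop(sprintf("no HR counterpart for '%s'", basename(f)))
    a <- read_image(f)
    b <- read_image(hp)
    data.frame(name = stem(f), method = method,
               psnr = psnr(a, b), ssim = ssim(a, b))
  })
  missing <- setdiff(names(hr_map), vapply(srf, stem, ""))
  if (length(missing))
    stop(sprintf("HR images without SR counterpart: %s",
                 paste(missing, collapse = ", ")))
  eval_result(do.call(rbind, rows))
}

#' Bicubic degradation/restoration baseline
#'
#' For each HR image, computes PSNR/SSIM of
#' `upsample_bicubic(downscale_bicubic(hr))` against the original — the
#' weakest baseline every trained model is expected to beat.
#'
#' @param hr HR images: a directory path or a list of [grayscale_image]s.
#' @param scale Integer scale factor.
#' @return An `eval_result` with method `"bicubic"`.
#' @export
baseline_bicubic <- function(hr, scale) {
  r <- scale_factor(scale)
  if (is.character(hr)) {
    files <- list_image_files(hr)
    imgs <- lapply(files, read_image)
    names(imgs) <- tools::file_path_sans_ext(basename(files))
  } else {
    imgs <- hr
    if (is.null(names(imgs)))
      names(imgs) <- sprintf("img%03d", seq_along(imgs))
  }
  rows <- lapply(names(imgs), function(nm) {
    h <- imgs[[nm]]
    rec <- upsample_bicubic(downscale_bicubic(h, r), r)
    data.frame(name = nm, method = "bicubic",
               psnr = psnr(rec, h), ssim = ssim(rec, h))
  })
  eval_result(do.call(rbind, rows))
}
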
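# The super-resolution generator.
#
# Architecture: a stem of bottleneck residual units feeds a 4-stage trunk of
# parallel multi-resolution streams (full, 1/2, 1/4 and 1/8 resolution with
# channel widths doubling as resolution halves).  Each stage adds one lower
# stream; within a stage, groups of basic residual blocks per stream are
# followed by a cross-resolution fusion in which every stream receives
# information from all others.  The aggregation head restores the three
# lower streams to full resolution with transposed convolutions (kernels
# 5/7/11 at strides 2/4/8), concatenates all four streams channel-wise and
# predicts the residual image with a 1x1 convolution.  The low-resolution
# input is bicubically upsampled to target size before the stem, so the top
# stream lives at high resolution throughout.

.resize_cache <- new.env(parent = emptyenv())

cached_resample_matrix <- function(n_in, n_out, kernel, antialias) {
  key <- paste(n_in, n_out, kernel, antialias, sep = "_")
  m <- .resize_cache[[key]]
  if (is.null(m)) {
    m <- resample_matrix(n_in, n_out, kernel, antialias)
    .resize_cache[[key]] <- m
  }
  m
}

#' Transposed-convolution output geometry
#'
#' Solves for the padding `p` and extra output amount `op` such that a
#' transposed convolution with the given kernel and stride maps a stream of
#' side `in_side` to exactly `in_side * stride`:
#' `(in_side - 1) * stride - 2p + kernel + op = in_side * stride`.
#'
#' @param in_side Input spatial side in pixels.
#' @param kernel Kernel size (must exceed `stride`).
#' @param stride Upsampling stride.
#' @return List with `padding`, `extra_output`, `out_side`.
#' @examples
#' deconv_geometry(32, 11, 8)   # padding 2, extra output 1, out 256
#' @export
deconv_geometry <- function(in_side, kernel, stride) {
  if (kernel <= stride) stop("kernel must exceed stride")
  op <- (kernel - stride) %% 2L
  p <- (kernel - stride + op) %/% 2L
  if (op < 0L || op >= stride || p < 0L)
    stop(sprintf("no valid geometry for kernel %d, stride %d", kernel, stride))
  out <- (in_side - 1L) * stride - 2L * p + kernel + op
  stopifnot(out == in_side * stride)
  list(padding = as.integer(p), extra_output = as.integer(op),
       out_side = as.integer(out))
}

#' Generator architecture specification
#'
#' Defaults follow the reference architecture: four streams of widths
#' 32/64/128/256 (width doubles as resolution halves), a stem of four
#' 64-channel bottleneck units reduced to 32 channels by a 3x3 convolution,
#' stages 2-4 holding 1, 4 and 3 exchange units of 4 residual blocks each,
#' and deconvolution kernels 5/7/11 at strides 2/4/8 in the aggregation
#' head.  Smaller widths (e.g. 8/16/32/64) give desk-scale models with the
#' same structure.
#'
#' @param widths Four stream channel counts; each must double the previous.
#' @param stem_units Number of bottleneck residual units in the stem.
#' @param stem_width Bottleneck internal width (output is 4x this).
#' @param stage_module_counts Exchange-unit counts for stages 2-4.
#' @param blocks_per_module Residual blocks per stream per exchange unit.
#' @param deconv_kernels Kernel sizes for the three aggregation
#'   deconvolutions (strides are fixed at 2, 4, 8).
#' @param aggregation Feature-aggregation head: `"deconv"` (transposed
#'   convolutions), `"bilinear"` (bilinear upsampling), or `"hr_only"`
#'   (top stream only).
#' @param trunk `"multires"` for the multi-resolution trunk, or `"plain"`
#'   for a single-stream residual baseline of `plain_blocks` blocks at
#'   `widths[1]` channels (the simple-generator baseline in the ablation).
#' @param plain_blocks Residual blocks in the plain trunk.
#' @return A validated `generator_spec`.
#' @export
generator_spec <- function(widths = c(32L, 64L, 128L, 256L),
                           stem_units = 4L, stem_width = 64L,
                           stage_module_counts = c(1L, 4L, 3L),
                           blocks_per_module = 4L,
                           deconv_kernels = c(5L, 7L, 11L),
                           aggregation = c("deconv", "bilinear", "hr_only"),
                           trunk = c("multires", "plain"),
                           plain_blocks = 8L) {
  aggregation <- match.arg(aggregation)
  trunk <- match.arg(trunk)
  widths <- as.integer(widths)
  if (length(widths) != 4L || any(widths < 1L))
    stop("widths must be 4 positive channel counts")
  if (any(widths[2:4] != 2L * widths[1:3]))
    stop("stream widths must double as resolution halves (got ",
         paste(widths, collapse = ", "), ")")
  stage_module_counts <- as.integer(stage_module_counts)
  if (length(stage_module_counts) != 3L || any(stage_module_counts < 1L))
    stop("stage_module_counts must give >= 1 exchange unit for stages 2-4")
  deconv_kernels <- as.integer(deconv_kernels)
  strides <- c(2L, 4L, 8L)
  if (length(deconv_kernels) != 3L)
    stop("deconv_kernels must have length 3 (one per lower stream)")
  if (any(deconv_kernels <= strides))
    stop("each deconvolution kernel must exceed its stride (strides 2, 4, 8)")
  if (stem_units < 1L || stem_width < 1L || blocks_per_module < 1L ||
      plain_blocks < 1L)
    stop("stem_units, stem_width, blocks_per_module, plain_blocks must be >= 1")
  structure(list(widths = widths, stem_units = as.integer(stem_units),
                 stem_width = as.integer(stem_width),
                 stage_module_counts = stage_module_counts,
                 blocks_per_module = as.integer(blocks_per_module),
                 deconv_kernels = deconv_kernels, deconv_strides = strides,
                 aggregation = aggregation, trunk = trunk,
                 plain_blocks = as.integer(plain_blocks)),
            class = "generator_spec")
}

# ---- cross-resolution fusion ----------------------------------------------

# Fusion unit over `s` active streams of the given widths: output stream k is
# ReLU(sum_j convert(stream j -> resolution k)).  Downward paths (j < k) are
# chains of stride-2 3x3 convolutions; upward paths (j > k) are bilinear
# upsampling followed by a 1x1 convolution; j = k is the identity.
make_fusion <- function(mod, prefix, widths_active) {
  s <- length(widths_active)
  convert <- vector("list", s * s)
  dim(convert) <- c(s, s)
  for (k in seq_len(s)) {
    for (j in seq_len(s)) {
      if (j == k) next
      nm <- sprintf("%s.j%dk%d", prefix, j, k)
      if (j < k) {
        steps <- k - j
        layers <- lapply(seq_len(steps), function(t) {
          cin <- if (t == 1L) widths_active[j] else widths_active[j]
          cout <- if (t == steps) widths_active[k] else widths_active[j]
          layer_conv(mod, sprintf("%s.d%d", nm, t), cin, cout, k = 3L,
                     stride = 2L, act = (t != steps))
        })
        convert[[j, k]] <- local({
          layers <- layers
          function(x) Reduce(function(v, l) l(v), layers, x)
        })
      } else {
        cv <- layer_conv(mod, paste0(nm, ".u"), widths_active[j],
                         widths_active[k], k = 1L, act = FALSE)
        fac <- 2L^(j - k)
        convert[[j, k]] <- local({
          cv <- cv; fac <- fac
          function(x) {
            d <- dim(x$value)
            Mr <- cached_resample_matrix(d[1L], d[1L] * fac, "linear", FALSE)
            Mc <- cached_resample_matrix(d[2L], d[2L] * fac, "linear", FALSE)
            cv(nd_resize_sep(x, Mr, Mc))
          }
        })
      }
    }
  }
  function(pyramid) {
    lapply(seq_len(s), function(k) {
      terms <- lapply(seq_len(s), function(j) {
        if (j == k) pyramid[[j]] else convert[[j, k]](pyramid[[j]])
      })
      nd_relu(nd_sum_nodes(terms))
    })
  }
}

# ---- aggregation heads -----------------------------------------------------

make_aggregation <- function(mod, prefix, widths, kernels, strides, type) {
  if (type == "hr_only") {
    out <- layer_conv(mod, paste0(prefix, ".out"), widths[1L], 1L, k = 1L,
                      act = FALSE)
    return(list(concat_channels = widths[1L],
                forward = function(pyramid) out(pyramid[[1L]])))
  }
  if (type == "deconv") {
    ups <- lapply(2:4, function(k)
      layer_convt(mod, sprintf("%s.d%d", prefix, k), widths[k], widths[k],
                  kernels[k - 1L], strides[k - 1L], act = TRUE))
  } else {
    ups <- lapply(2:4, function(k) {
      fac <- strides[k - 1L]
      function(x) {
        d <- dim(x$value)
        Mr <- cached_resample_matrix(d[1L], d[1L] * fac, "linear", FALSE)
        Mc <- cached_resample_matrix(d[2L], d[2L] * fac, "linear", FALSE)
        nd_resize_sep(x, Mr, Mc)
      }
    })
  }
  out <- layer_conv(mod, paste0(prefix, ".out"), sum(widths), 1L, k = 1L,
                    act = FALSE)
  # damp the prediction layer so the initial output is near mid-grey rather
  # than at He-init scale (speeds up early optimisation markedly)
  pw <- mod$params[[paste0(prefix, ".out.w")]]
  pw$value <- pw$value * 0.1
  mod$params[[paste0(prefix, ".out.b")]]$value <- 0.5
  list(concat_channels = sum(widths),
       forward = function(pyramid) {
         full <- c(pyramid[1L],
                   lapply(1:3, function(i) ups[[i]](pyramid[[i + 1L]])))
         sides <- vapply(full, function(x) dim(x$value)[1L], 0)
         if (length(unique(sides)) != 1L)
           stop("aggregation contract violated: upsampled stream sizes differ")
         out(nd_concat_c(full))
       })
}

# ---- generator handle ------------------------------------------------------

#' Build a generator
#'
#' Constructs the network with seeded He initialisation and returns a
#' handle exposing the forward pass and parameter queries.
#'
#' @param spec A [generator_spec].
#' @param scale Integer scale factor (2, 4 or 8).
#' @param seed Seed for weight initialisation.
#' @return A `medsr_generator` handle with fields `spec`, `scale`, and
#'   methods used by [generator_forward()], [train_sr()] and the ablation
#'   harness.
#' @examples
#' gen <- build_generator(generator_spec(widths = c(8, 16, 32, 64),
#'                                       stage_module_counts = c(1, 1, 1),
#'                                       blocks_per_module = 1,
#'                                       stem_units = 1, stem_width = 8),
#'                        scale = 4, seed = 1)
#' stream_widths(gen)
#' @export
build_generator <- function(spec, scale, seed = 0L) {
  if (!inherits(spec, "generator_spec")) stop("spec must be a generator_spec")
  r <- scale_factor(scale)
  mod <- new_module()
  gen <- new.env(parent = emptyenv())
  gen$spec <- spec
  gen$scale <- r
  gen$mod <- mod
  gen$seed <- as.integer(seed)
  with_seed(seed, {
    if (spec$trunk == "plain") {
      w <- spec$widths[1L]
      head_conv <- layer_conv(mod, "stem.in", 1L, w, k = 3L)
      blocks <- lapply(seq_len(spec$plain_blocks), function(i)
        layer_basic_block(mod, sprintf("trunk.b%d", i), w))
      tail_conv <- layer_conv(mod, "trunk.tail", w, w, k = 3L, act = FALSE)
      out_conv <- layer_conv(mod, "agg.out", w, 1L, k = 1L, act = FALSE)
      gen$concat_channels <- w
      gen$forward_pre <- function(x) {
        f0 <- head_conv(x)
        f <- Reduce(function(v, b) b(v), blocks, f0)
        out_conv(nd_relu(nd_add(tail_conv(f), f0)))
      }
    } else {
      widths <- spec$widths
      exp_out <- 4L * spec$stem_width
      stem <- lapply(seq_len(spec$stem_units), function(i)
        layer_bottleneck(mod, sprintf("stem.u%d", i),
                         if (i == 1L) 1L else exp_out, spec$stem_width))
      stem_out <- layer_conv(mod, "stem.reduce", exp_out, widths[1L], k = 3L)
      new_stream <- lapply(2:4, function(s)
        layer_conv(mod, sprintf("s%d.new", s), widths[s - 1L], widths[s],
                   k = 3L, stride = 2L))
      stages <- lapply(2:4, function(s) {
        lapply(seq_len(spec$stage_module_counts[s - 1L]), function(m) {
          blocks <- lapply(seq_len(s), function(k)
            lapply(seq_len(spec$blocks_per_module), function(b)
              layer_basic_block(mod, sprintf("s%d.m%d.k%d.b%d", s, m, k, b),
                                widths[k])))
          fuse <- make_fusion(mod, sprintf("s%d.m%d.fuse", s, m), widths[1:s])
          list(blocks = blocks, fuse = fuse)
        })
      })
      agg <- make_aggregation(mod, "agg", widths, spec$deconv_kernels,
                              spec$deconv_strides, spec$aggregation)
      gen$concat_channels <- agg$concat_channels
      gen$forward_pre <- function(x) {
        f <- Reduce(function(v, u) u(v), stem, x)
        pyramid <- list(stem_out(f))
        for (si in 1:3) {                       # stages 2..4
          pyramid <- c(pyramid, list(new_stream[[si]](pyramid[[si]])))
          for (unit in stages[[si]]) {
            pyramid <- lapply(seq_along(pyramid), function(k)
              Reduce(function(v, b) b(v), unit$blocks[[k]], pyramid[[k]]))
            pyramid <- unit$fuse(pyramid)
          }
        }
        agg$forward(pyramid)
      }
    }
  })
  class(gen) <- "medsr_generator"
  gen
}

#' @export
print.medsr_generator <- function(x, ...) {
  cat(sprintf("<generator: %s trunk, widths %s, x%d, %s aggregation, %d parameters>\n",
              x$spec$trunk, paste(x$spec$widths, collapse = "/"), x$scale,
              x$spec$aggregation, n_params(x)))
  invisible(x)
}

#' Stream widths of a generator
#' @param gen A `medsr_generator` handle.
#' @return Integer vector of the four stream channel counts.
#' @export
stream_widths <- function(gen) gen$spec$widths

#' Number of learnable parameters
#'
#' @param handle A generator or discriminator handle.
#' @param prefix Optional parameter-name prefix, e.g. `"agg."` to count only
#'   the feature-aggregation head.
#' @return Integer parameter count.
#' @export
n_params <- function(handle, prefix = NULL) module_n_params(handle$mod, prefix)

# Pre-upsample a batch of LR matrices to the HR grid (plain arrays, no
# gradient flows through the fixed bicubic lift).
pre_upsample_batch <- function(lr_list, r) {
  ups <- lapply(lr_list, function(m) {
    m <- as_image_matrix(m)
    Mr <- cached_resample_matrix(nrow(m), nrow(m) * r, "cubic", FALSE)
    Mc <- cached_resample_matrix(ncol(m), ncol(m) * r, "cubic", FALSE)
    clip01(Mr %*% m %*% t(Mc))
  })
  h <- nrow(ups[[1L]]); w <- ncol(ups[[1L]])
  x <- array(0, c(h, w, 1L, length(ups)))
  for (i in seq_along(ups)) x[, , 1L, i] <- ups[[i]]
  x
}

# Forward pass on a batch of LR matrices, returning the graph node.
generator_forward_node <- function(gen, lr_list) {
  x <- pre_upsample_batch(lr_list, gen$scale)
  if (dim(x)[1L] %% 8L != 0L || dim(x)[2L] %% 8L != 0L)
    stop(sprintf("pre-upsampled size %d x %d is not divisible by 8 (the deepest stream's stride)",
                 dim(x)[1L], dim(x)[2L]))
  gen$forward_pre(nd_const(x))
}

#' Super-resolve one image with a generator
#'
#' The LR input is bicubically upsampled to `scale` times its size, passed
#' through the network, and (at inference) clipped to \[0, 1\].
#'
#' @param gen A `medsr_generator` handle.
#' @param lr A [grayscale_image] (its size times `gen$scale` must be
#'   divisible by 8).
#' @param clip Clip the output into \[0, 1\] (default; disable to inspect the
#'   raw prediction).
#' @return A `grayscale_image` of `scale` times the input size.
#' @export
generator_forward <- function(gen, lr, clip = TRUE) {
  y <- generator_forward_node(gen, list(lr))
  m <- y$value[, , 1L, 1L]
  if (clip) m <- clip01(m)
  grayscale_image(m)
}

# ---- standalone fusion / aggregation (exercised directly in tests) ---------

#' Build a standalone cross-resolution fusion unit
#'
#' @param widths Channel widths of the active streams (2 to 4 entries, each
#'   double the previous).
#' @param seed Seed for weight initialisation.
#' @return Handle with `$mod` and `$forward`; see [fuse_pyramid()].
#' @export
build_fusion_unit <- function(widths, seed = 0L) {
  widths <- as.integer(widths)
  if (length(widths) < 2L || any(widths[-1L] != 2L * widths[-length(widths)]))
    stop("widths must double along the pyramid")
  mod <- new_module()
  fwd <- with_seed(seed, make_fusion(mod, "fuse", widths))
  structure(list(mod = mod, widths = widths, forward = fwd),
            class = "medsr_fusion")
}

#' Apply a fusion unit to a feature pyramid
#'
#' Every output stream is the ReLU of the sum of all (resolution- and
#' width-converted) input streams; the output has the same shape signature
#' as the input.
#'
#' @param unit Handle from [build_fusion_unit()].
#' @param pyramid List of feature arrays `[H, W, C, N]`, spatial size halving
#'   and widths matching the unit.
#' @return List of arrays with the same shape signature.
#' @export
fuse_pyramid <- function(unit, pyramid) {
  nodes <- lapply(pyramid, nd_const)
  lapply(unit$forward(nodes), function(n) n$value)
}

#' Build a standalone feature-aggregation head
#'
#' @param widths Four stream widths.
#' @param type `"deconv"`, `"bilinear"` or `"hr_only"`.
#' @param kernels Deconvolution kernels (type `"deconv"`).
#' @param seed Seed for weight initialisation.
#' @return Handle with `$mod`, `$concat_channels` and `$forward`.
#' @export
build_aggregation_head <- function(widths, type = "deconv",
                                   kernels = c(5L, 7L, 11L), seed = 0L) {
  widths <- as.integer(widths)
  mod <- new_module()
  agg <- with_seed(seed,
                   make_aggregation(mod, "agg", widths, as.integer(kernels),
                                    c(2L, 4L, 8L), type))
  structure(list(mod = mod, widths = widths, type = type,
                 concat_channels = agg$concat_channels, forward = agg$forward),
            class = "medsr_aggregation")
}

#' Aggregate a feature pyramid to a full-resolution prediction map
#'
#' Lower streams are restored to the top stream's spatial size (transposed
#' convolution or bilinear upsampling according to the head type), all
#' streams are concatenated channel-wise and reduced by a 1x1 convolution.
#'
#' @param head Handle from [build_aggregation_head()].
#' @param pyramid List of 4 feature arrays `[H, W, C, N]`.
#' @return Array `[H, W, 1, N]` at the top stream's resolution.
#' @export
aggregate_pyramid <- function(head, pyramid) {
  head$forward(lapply(pyramid, nd_const))$value
}
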
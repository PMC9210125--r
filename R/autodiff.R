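# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# A node is an environment holding `value` (an array, matrix or numeric),
# `grad` (same shape, filled during the backward pass), its `parents` and a
# `backward` closure that routes the node's gradient to them.  Activations
# use the layout [H, W, C, N] shared with the compiled kernels.

.nd_counter <- new.env(parent = emptyenv())
.nd_counter$n <- 0L

new_node <- function(value, parents = list(), backward = NULL,
                     requires_grad = FALSE) {
  n <- new.env(parent = emptyenv())
  .nd_counter$n <- .nd_counter$n + 1L
  n$id <- .nd_counter$n
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) isTRUE(p$requires_grad), logical(1)))
  class(n) <- "medsr_node"
  n
}

nd_const <- function(value) new_node(value)
nd_param <- function(value) new_node(value, requires_grad = TRUE)

nd_is <- function(x) inherits(x, "medsr_node")

accum_grad <- function(node, g) {
  if (!isTRUE(node$requires_grad)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar-valued node: topologically order the subgraph
# that requires gradients, clear stale gradients, then run backward closures
# in reverse order.
nd_backward <- function(root) {
  if (length(root$value) != 1L)
    stop("nd_backward() expects a scalar-valued node")
  order <- vector("list", 64L)
  k <- 0L
  seen <- new.env(parent = emptyenv())
  visit <- function(n) {
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    for (p in n$parents) if (isTRUE(p$requires_grad)) visit(p)
    k <<- k + 1L
    if (k > length(order)) length(order) <<- 2L * k
    order[[k]] <<- n
    invisible(NULL)
  }
  visit(root)
  for (i in seq_len(k)) order[[i]]$grad <- NULL
  root$grad <- 1
  for (i in rev(seq_len(k))) {
    n <- order[[i]]
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n)
  }
  invisible(root)
}

# ---- tensor ops ------------------------------------------------------------

nd_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  y <- cpp_conv2d_fw(x$value, w$value, b$value, as.integer(stride),
                     as.integer(pad))
  new_node(y, list(x, w, b), function(n) {
    g <- cpp_conv2d_bw(x$value, w$value, n$grad, as.integer(stride),
                       as.integer(pad), isTRUE(x$requires_grad))
    if (isTRUE(x$requires_grad)) accum_grad(x, g$gx)
    accum_grad(w, g$gw)
    accum_grad(b, g$gb)
  })
}

nd_convt2d <- function(x, w, b, stride, pad, opad) {
  y <- cpp_convt2d_fw(x$value, w$value, b$value, as.integer(stride),
                      as.integer(pad), as.integer(opad))
  new_node(y, list(x, w, b), function(n) {
    g <- cpp_convt2d_bw(x$value, w$value, n$grad, as.integer(stride),
                        as.integer(pad), as.integer(opad),
                        isTRUE(x$requires_grad))
    if (isTRUE(x$requires_grad)) accum_grad(x, g$gx)
    accum_grad(w, g$gw)
    accum_grad(b, g$gb)
  })
}

nd_relu <- function(x) {
  mask <- x$value > 0
  new_node(x$value * mask, list(x), function(n) accum_grad(x, n$grad * mask))
}

nd_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(s, list(x), function(n) accum_grad(x, n$grad * s * (1 - s)))
}

# Clamp with zero gradient outside [lo, hi] (keeps log-losses finite).
nd_clamp <- function(x, lo, hi) {
  inside <- x$value >= lo & x$value <= hi
  new_node(pmin(pmax(x$value, lo), hi), list(x),
           function(n) accum_grad(x, n$grad * inside))
}

nd_add <- function(a, b) {
  new_node(a$value + b$value, list(a, b), function(n) {
    accum_grad(a, n$grad)
    accum_grad(b, n$grad)
  })
}

nd_sum_nodes <- function(xs) {
  v <- xs[[1L]]$value
  for (i in seq_along(xs)[-1L]) v <- v + xs[[i]]$value
  new_node(v, xs, function(n) for (x in xs) accum_grad(x, n$grad))
}

# Channel-wise concatenation of [H, W, C, N] tensors.
nd_concat_c <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  cs <- vapply(dims, `[`, 0, 3L)
  d1 <- dims[[1L]]
  out <- array(0, c(d1[1L], d1[2L], sum(cs), d1[4L]))
  hi <- cumsum(cs)
  lo <- hi - cs + 1L
  for (i in seq_along(xs)) out[, , lo[i]:hi[i], ] <- xs[[i]]$value
  new_node(out, xs, function(n) {
    for (i in seq_along(xs))
      accum_grad(xs[[i]], n$grad[, , lo[i]:hi[i], , drop = FALSE])
  })
}

# Separable linear resampling: out[,,c,n] = Mr %*% x[,,c,n] %*% t(Mc).
# Covers bilinear/bicubic up- and downsampling inside the network; the
# backward pass is the transposed operator.
nd_resize_sep <- function(x, Mr, Mc) {
  d <- dim(x$value)
  out <- array(0, c(nrow(Mr), nrow(Mc), d[3L], d[4L]))
  tMc <- t(Mc)
  for (n in seq_len(d[4L]))
    for (c in seq_len(d[3L]))
      out[, , c, n] <- Mr %*% x$value[, , c, n] %*% tMc
  new_node(out, list(x), function(nn) {
    if (!isTRUE(x$requires_grad)) return(invisible(NULL))
    g <- array(0, d)
    tMr <- t(Mr)
    for (n in seq_len(d[4L]))
      for (c in seq_len(d[3L]))
        g[, , c, n] <- tMr %*% nn$grad[, , c, n] %*% Mc
    accum_grad(x, g)
  })
}

nd_flatten <- function(x) {
  d <- dim(x$value)
  nf <- prod(d[1:3])
  v <- t(matrix(x$value, nf, d[4L]))
  new_node(v, list(x), function(n) accum_grad(x, array(t(n$grad), d)))
}

# x: N x F matrix node; w: F x K; b: length K.
nd_dense <- function(x, w, b) {
  v <- x$value %*% w$value
  v <- sweep(v, 2L, b$value, `+`)
  new_node(v, list(x, w, b), function(n) {
    if (isTRUE(x$requires_grad)) accum_grad(x, n$grad %*% t(w$value))
    accum_grad(w, crossprod(x$value, n$grad))
    accum_grad(b, colSums(n$grad))
  })
}

# Batch normalisation over (H, W, N) per channel; training mode (batch
# statistics).  Returns the node plus the batch statistics for running
# averages.
nd_batchnorm_train <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3L]
  m <- d[1L] * d[2L] * d[4L]
  xm <- matrix(aperm(x$value, c(1L, 2L, 4L, 3L)), ncol = C)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, `-`), 2L, sd_, `/`)
  ym <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  back_perm <- function(mat) aperm(array(mat, c(d[1L], d[2L], d[4L], C)),
                                   c(1L, 2L, 4L, 3L))
  node <- new_node(back_perm(ym), list(x, gamma, beta), function(n) {
    gm <- matrix(aperm(n$grad, c(1L, 2L, 4L, 3L)), ncol = C)
    accum_grad(gamma, colSums(gm * xhat))
    accum_grad(beta, colSums(gm))
    if (isTRUE(x$requires_grad)) {
      gxh <- sweep(gm, 2L, gamma$value, `*`)
      t1 <- sweep(gxh, 2L, colMeans(gxh), `-`)
      t2 <- sweep(xhat, 2L, colMeans(gxh * xhat), `*`)
      gx <- sweep(t1 - t2, 2L, sd_, `/`)
      accum_grad(x, back_perm(gx))
    }
  })
  list(node = node, mean = mu, var = va * m / max(1, m - 1))
}

# Inference-mode batch norm with fixed running statistics.
nd_batchnorm_eval <- function(x, gamma, beta, mean_, var_, eps = 1e-5) {
  d <- dim(x$value)
  C <- d[3L]
  sc <- gamma$value / sqrt(var_ + eps)
  sh <- beta$value - mean_ * sc
  scale_arr <- array(rep(sc, each = d[1L] * d[2L]), d[1:3])
  shift_arr <- array(rep(sh, each = d[1L] * d[2L]), d[1:3])
  v <- x$value
  for (n in seq_len(d[4L])) v[, , , n] <- v[, , , n] * scale_arr + shift_arr
  new_node(v, list(x, gamma, beta), function(nn) {
    if (isTRUE(x$requires_grad)) {
      g <- nn$grad
      for (n in seq_len(d[4L])) g[, , , n] <- g[, , , n] * scale_arr
      accum_grad(x, g)
    }
    gm <- matrix(aperm(nn$grad, c(1L, 2L, 4L, 3L)), ncol = C)
    xm <- matrix(aperm(x$value, c(1L, 2L, 4L, 3L)), ncol = C)
    xhat <- sweep(sweep(xm, 2L, mean_, `-`), 2L, sqrt(var_ + eps), `/`)
    accum_grad(gamma, colSums(gm * xhat))
    accum_grad(beta, colSums(gm))
  })
}

# ---- scalar reductions -----------------------------------------------------

nd_mse <- function(x, target) {
  if (nd_is(target)) target <- target$value
  diff <- x$value - target
  new_node(mean(diff^2), list(x),
           function(n) accum_grad(x, n$grad * 2 * diff / length(diff)))
}

# mean over the batch of -log(p); p must already be inside (0, 1).
nd_mean_neglog <- function(p) {
  m <- length(p$value)
  new_node(-mean(log(p$value)), list(p),
           function(n) accum_grad(p, -n$grad / (m * p$value)))
}

nd_mean_neglog1m <- function(p) {
  m <- length(p$value)
  new_node(-mean(log(1 - p$value)), list(p),
           function(n) accum_grad(p, n$grad / (m * (1 - p$value))))
}

# Weighted sum of scalar nodes with constant weights.
nd_wsum <- function(xs, weights) {
  v <- sum(vapply(xs, function(x) x$value, 0) * weights)
  new_node(v, xs, function(n) {
    for (i in seq_along(xs)) accum_grad(xs[[i]], n$grad * weights[i])
  })
}
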
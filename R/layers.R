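# Layer constructors.
#
# A "module" is an environment collecting named parameter nodes (and batch
# norm running statistics); layer constructors register their parameters in
# the module and return a closure building the forward graph.  Weights use
# He fan-in initialisation (suited to ReLU networks); biases start at zero.

new_module <- function() {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$buffers <- list()
  m
}

add_param <- function(mod, name, value) {
  p <- nd_param(value)
  mod$params[[name]] <- p
  p
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

module_n_params <- function(mod, prefix = NULL) {
  ps <- mod$params
  if (!is.null(prefix)) ps <- ps[startsWith(names(ps), prefix)]
  sum(vapply(ps, function(p) length(p$value), 0))
}

# 2-D convolution layer; `act` appends ReLU.
layer_conv <- function(mod, name, cin, cout, k = 3L, stride = 1L,
                       pad = (k - 1L) %/% 2L, act = TRUE) {
  w <- add_param(mod, paste0(name, ".w"), he_init(c(k, k, cin, cout), k * k * cin))
  b <- add_param(mod, paste0(name, ".b"), numeric(cout))
  force(stride); force(pad); force(act)
  function(x) {
    y <- nd_conv2d(x, w, b, stride, pad)
    if (act) nd_relu(y) else y
  }
}

# Transposed convolution restoring a stream downsampled by `stride` to full
# resolution; padding/output-padding from deconv_geometry() guarantee
# out_side = in_side * stride exactly.
layer_convt <- function(mod, name, cin, cout, k, stride, act = TRUE) {
  if (k <= stride) stop("deconvolution kernel must exceed its stride")
  geo <- deconv_geometry(16L, k, stride)   # padding depends only on (k, stride)
  w <- add_param(mod, paste0(name, ".w"),
                 he_init(c(k, k, cout, cin), k * k * cin / stride^2))
  b <- add_param(mod, paste0(name, ".b"), numeric(cout))
  force(act)
  function(x) {
    y <- nd_convt2d(x, w, b, stride, geo$padding, geo$extra_output)
    if (act) nd_relu(y) else y
  }
}

layer_dense <- function(mod, name, fin, fout) {
  w <- add_param(mod, paste0(name, ".w"),
                 matrix(stats::rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout))
  b <- add_param(mod, paste0(name, ".b"), numeric(fout))
  function(x) nd_dense(x, w, b)
}

# Batch normalisation with running statistics (momentum as in common DL
# frameworks); training mode uses batch statistics.
layer_batchnorm <- function(mod, name, C, momentum = 0.1) {
  gamma <- add_param(mod, paste0(name, ".gamma"), rep(1, C))
  beta <- add_param(mod, paste0(name, ".beta"), numeric(C))
  buf <- new.env(parent = emptyenv())
  buf$mean <- numeric(C)
  buf$var <- rep(1, C)
  mod$buffers[[name]] <- buf
  function(x, train = FALSE) {
    if (train) {
      r <- nd_batchnorm_train(x, gamma, beta)
      buf$mean <- (1 - momentum) * buf$mean + momentum * r$mean
      buf$var <- (1 - momentum) * buf$var + momentum * r$var
      r$node
    } else {
      nd_batchnorm_eval(x, gamma, beta, buf$mean, buf$var)
    }
  }
}

# Bottleneck residual unit (1x1 -> 3x3 -> 1x1, expansion 4) used in the stem.
layer_bottleneck <- function(mod, name, cin, width, expansion = 4L) {
  cout <- width * expansion
  c1 <- layer_conv(mod, paste0(name, ".c1"), cin, width, k = 1L)
  c2 <- layer_conv(mod, paste0(name, ".c2"), width, width, k = 3L)
  c3 <- layer_conv(mod, paste0(name, ".c3"), width, cout, k = 1L, act = FALSE)
  proj <- if (cin != cout)
    layer_conv(mod, paste0(name, ".proj"), cin, cout, k = 1L, act = FALSE)
  function(x) {
    skip <- if (is.null(proj)) x else proj(x)
    nd_relu(nd_add(c3(c2(c1(x))), skip))
  }
}

# Basic residual block (two 3x3 convolutions, identity skip) used in the
# multi-resolution trunk.
layer_basic_block <- function(mod, name, width) {
  c1 <- layer_conv(mod, paste0(name, ".c1"), width, width, k = 3L)
  c2 <- layer_conv(mod, paste0(name, ".c2"), width, width, k = 3L, act = FALSE)
  function(x) nd_relu(nd_add(c2(c1(x)), x))
}

# Adam optimiser state attached to a module.
adam_init <- function(mod) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(mod$params, function(p) p$value * 0)
  st$v <- lapply(mod$params, function(p) p$value * 0)
  st
}

adam_step <- function(mod, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      grad_clip = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(mod$params)) {
    p <- mod$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (!is.null(grad_clip)) g <- pmin(pmax(g, -grad_clip), grad_clip)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    p$value <- p$value - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
    p$grad <- NULL
  }
  invisible(state)
}
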
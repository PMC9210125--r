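# Shared fixtures: desk-scale network specs, a seeded phantom pair, a naive
# independently coded bicubic resampler and a numeric differentiator used as
# oracles.

tiny_gen_spec <- function(widths = c(4L, 8L, 16L, 32L), ...) {
  generator_spec(widths = widths, stem_units = 1L, stem_width = 4L,
                 stage_module_counts = c(1L, 1L, 1L), blocks_per_module = 1L,
                 ...)
}

tiny_disc_spec <- function() {
  discriminator_spec(channels = c(8L, 8L, 16L, 16L, 32L, 32L, 64L, 64L),
                     dense_width = 32L)
}

random_image <- function(side, seed = 1L) {
  set.seed(seed)
  grayscale_image(matrix(runif(side * side), side, side))
}

# Independently coded bicubic resampler: direct per-output-pixel double loop
# (no weight matrices), Keys kernel a = -0.5, replicate edges, normalised
# weights, align-corners-false grid.
naive_bicubic <- function(m, h_out, w_out, antialias = TRUE) {
  keys <- function(t) {
    t <- abs(t)
    if (t <= 1) 1.5 * t^3 - 2.5 * t^2 + 1
    else if (t < 2) -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2
    else 0
  }
  axis_weights <- function(n_in, n_out) {
    scale <- n_out / n_in
    ks <- if (antialias && scale < 1) scale else 1
    supp <- 2 / ks
    lapply(seq_len(n_out), function(i) {
      center <- (i - 0.5) / scale - 0.5
      idx <- floor(center - supp + 1):ceiling(center + supp - 1)
      w <- vapply(idx, function(j) keys((center - j) * ks), 0)
      idx <- pmin(pmax(idx, 0), n_in - 1) + 1
      list(idx = idx, w = w / sum(w))
    })
  }
  rw <- axis_weights(nrow(m), h_out)
  cw <- axis_weights(ncol(m), w_out)
  out <- matrix(0, h_out, w_out)
  for (i in seq_len(h_out)) {
    for (j in seq_len(w_out)) {
      acc <- 0
      for (a in seq_along(rw[[i]]$idx))
        for (b in seq_along(cw[[j]]$idx))
          acc <- acc + rw[[i]]$w[a] * cw[[j]]$w[b] *
            m[rw[[i]]$idx[a], cw[[j]]$idx[b]]
      out[i, j] <- acc
    }
  }
  out
}

# Central-difference gradient of scalar f at x.
numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
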
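test_that("spec validation enforces width doubling and kernel/stride cover", {
  expect_identical(generator_spec()$widths, c(32L, 64L, 128L, 256L))
  expect_silent(generator_spec(widths = c(8, 16, 32, 64)))
  expect_error(generator_spec(widths = c(32, 64, 100, 256)), "double")
  expect_error(generator_spec(deconv_kernels = c(5, 7, 8)), "exceed")
  expect_error(generator_spec(deconv_kernels = c(5, 7)), "length 3")
})

test_that("deconvolution geometry restores exactly the internal drops", {
  g <- deconv_geometry(32, 11, 8)
  expect_equal(g, list(padding = 2L, extra_output = 1L, out_side = 256L))
  expect_equal(deconv_geometry(64, 7, 4),
               list(padding = 2L, extra_output = 1L, out_side = 256L))
  expect_equal(deconv_geometry(128, 5, 2),
               list(padding = 2L, extra_output = 1L, out_side = 256L))
  expect_error(deconv_geometry(32, 8, 8), "exceed")
})

test_that("the default generator reports the reference stream widths", {
  gen <- build_generator(generator_spec(), 4, seed = 0)
  expect_identical(stream_widths(gen), c(32L, 64L, 128L, 256L))
  expect_identical(gen$concat_channels, 480L)   # 32 + 64 + 128 + 256
})

test_that("forward pass maps LR inputs to r-times-larger outputs", {
  gen8 <- build_generator(tiny_gen_spec(), 8, seed = 1)
  out <- generator_forward(gen8, random_image(32, seed = 1))
  expect_identical(dim(out), c(256L, 256L))
  expect_true(all(out >= 0 & out <= 1))
  gen4 <- build_generator(tiny_gen_spec(), 4, seed = 1)
  expect_identical(dim(generator_forward(gen4, random_image(24, seed = 1))),
                   c(96L, 96L))
  # r * side must be divisible by 8
  expect_error(generator_forward(gen4, grayscale_image(matrix(0.5, 5, 5))),
               "divisible by 8")
})

test_that("the forward pass is deterministic", {
  gen <- build_generator(tiny_gen_spec(), 4, seed = 7)
  lr <- random_image(16, seed = 2)
  expect_identical(generator_forward(gen, lr), generator_forward(gen, lr))
  gen2 <- build_generator(tiny_gen_spec(), 4, seed = 7)
  expect_identical(generator_forward(gen, lr), generator_forward(gen2, lr))
})

test_that("shape algebra holds over a grid of sizes and scales", {
  for (S in c(32L, 48L, 64L)) {       # HR sides divisible by 8 and by r
    for (r in c(2L, 4L, 8L)) {
      gen <- build_generator(tiny_gen_spec(), r, seed = 1)
      out <- generator_forward(gen, random_image(S %/% r, seed = S + r))
      expect_identical(dim(out), c(S, S))
    }
  }
})

test_that("fusion propagates information to every stream and keeps shapes", {
  unit <- build_fusion_unit(c(4, 8, 16), seed = 3)
  pyr <- list(array(0, c(16, 16, 4, 1)), array(0, c(8, 8, 8, 1)),
              array(0, c(4, 4, 16, 1)))
  outz <- fuse_pyramid(unit, pyr)
  for (k in 1:3) {
    expect_identical(dim(outz[[k]]), dim(pyr[[k]]))
    expect_equal(max(abs(outz[[k]])), 0)       # zero in, zero out (zero biases)
  }
  pyr[[2]][, , , 1] <- abs(array(rnorm(8 * 8 * 8), c(8, 8, 8)))
  outn <- fuse_pyramid(unit, pyr)
  for (k in 1:3) expect_gt(max(abs(outn[[k]])), 0)
})

test_that("aggregation heads meet the concatenation contract", {
  head <- build_aggregation_head(c(4, 8, 16, 32), "deconv", seed = 2)
  expect_identical(head$concat_channels, 60L)
  pyr <- list(array(0, c(32, 32, 4, 1)), array(0, c(16, 16, 8, 1)),
              array(0, c(8, 8, 16, 1)), array(0, c(4, 4, 32, 1)))
  out <- aggregate_pyramid(head, pyr)
  expect_identical(dim(out), c(32L, 32L, 1L, 1L))
  # zero pyramid with zero biases gives a zero map
  head$mod$params[["agg.out.b"]]$value <- 0
  expect_equal(max(abs(aggregate_pyramid(head, pyr))), 0)
  expect_identical(build_aggregation_head(c(32, 64, 128, 256),
                                          "bilinear")$concat_channels, 480L)
})

test_that("deconvolution aggregation strictly adds parameters over bilinear", {
  for (w in list(c(4, 8, 16, 32), c(32, 64, 128, 256))) {
    hd <- build_aggregation_head(w, "deconv", seed = 1)
    hb <- build_aggregation_head(w, "bilinear", seed = 1)
    expect_gt(module_n_params(hd$mod, "agg."), module_n_params(hb$mod, "agg."))
  }
})

test_that("every learnable tensor receives gradient from the output loss", {
  gen <- build_generator(tiny_gen_spec(), 8, seed = 3)
  sr <- generator_forward_node(gen, list(random_image(4, seed = 11)))
  loss <- nd_mse(sr, array(0.5, dim(sr$value)))
  nd_backward(loss)
  gmax <- vapply(gen$mod$params,
                 function(p) if (is.null(p$grad)) 0 else max(abs(p$grad)), 0)
  expect_gt(length(gmax), 50)
  expect_true(all(gmax > 0))
})
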
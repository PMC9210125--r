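test_that("content loss is the mean squared pixel difference", {
  a <- matrix(0.5, 8, 8)
  expect_equal(content_loss(a, a), 0)
  expect_equal(content_loss(matrix(0.6, 8, 8), a), 0.01, tolerance = 1e-12)
  # brute-force double-loop oracle on a random pair
  x <- as_image_matrix(random_image(7, seed = 1))
  y <- as_image_matrix(random_image(7, seed = 2))
  acc <- 0
  for (i in 1:7) for (j in 1:7) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(content_loss(x, y), acc / 49, tolerance = 1e-10)
  expect_error(content_loss(matrix(0, 4, 4), matrix(0, 5, 5)), "mismatch")
})

test_that("adversarial losses match scalar log oracles", {
  expect_equal(adversarial_generator_loss(0.5), 0.6931, tolerance = 1e-4)
  s <- c(0.21, 0.77, 0.5)
  expect_equal(adversarial_generator_loss(s),
               -(log(0.21) + log(0.77) + log(0.5)) / 3, tolerance = 1e-10)
  expect_equal(adversarial_generator_loss(rep(1 - 1e-12, 4)), 0,
               tolerance = 1e-9)
  expect_equal(discriminator_loss(0.5, 0.5), 1.3863, tolerance = 1e-4)
  r <- c(0.9, 0.8); f <- c(0.15, 0.4)
  expect_equal(discriminator_loss(r, f),
               -mean(log(r)) - mean(log(1 - f)), tolerance = 1e-10)
  expect_equal(discriminator_loss(1 - 1e-12, 1e-12), 0, tolerance = 1e-9)
  expect_error(adversarial_generator_loss(c(0.5, 1)), "strictly inside")
  expect_error(discriminator_loss(0.5, 0), "strictly inside")
})

test_that("total loss is the stated weighted sum and linear in each weight", {
  expect_equal(total_loss(0.01, 0.5, loss_weights(1, 0))$total, 0.01)
  expect_equal(total_loss(0.01, 0.6931, loss_weights(1, 0.001))$total,
               0.0106931, tolerance = 1e-12)
  expect_equal(total_loss(0.3, 0.7, loss_weights(0, 1))$total, 0.7)
  for (a1 in c(0.5, 2)) for (a2 in c(0.25, 3)) {
    base <- total_loss(0.2, 0.4, loss_weights(1, 1))$total
    expect_equal(total_loss(0.2, 0.4, loss_weights(a1, a2))$total,
                 a1 * 0.2 + a2 * 0.4, tolerance = 1e-12)
  }
  expect_error(loss_weights(-1, 1), "non-negative")
  expect_error(loss_weights(0, 0), "non-negative")
})

test_that("PSNR follows its closed form with peak 1", {
  a <- matrix(0.5, 16, 16)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, matrix(0.6, 16, 16)), 20, tolerance = 1e-9)
  expect_equal(psnr(matrix(0, 16, 16), matrix(0.5, 16, 16)), 6.0206,
               tolerance = 1e-4)
  expect_error(psnr(a, matrix(0, 4, 4)), "mismatch")
})

test_that("PSNR is symmetric and decreases with noise amplitude", {
  a <- as_image_matrix(random_image(16, seed = 1))
  b <- as_image_matrix(random_image(16, seed = 2))
  expect_identical(psnr(a, b), psnr(b, a))
  set.seed(3)
  noise <- matrix(rnorm(256), 16, 16)
  base <- matrix(0.5, 16, 16)
  vals <- vapply(c(0.01, 0.05, 0.1, 0.2),
                 function(amp) psnr(base, pmin(pmax(base + amp * noise, 0), 1)),
                 0)
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM matches the closed form on constants and is bounded", {
  a <- matrix(0.3, 16, 16)
  expect_identical(ssim(a, a), 1)
  # constant pair: contrast/structure terms are 1, luminance term remains
  lum <- (2 * 0.2 * 0.4 + 1e-4) / (0.2^2 + 0.4^2 + 1e-4)
  expect_equal(ssim(matrix(0.2, 16, 16), matrix(0.4, 16, 16)), lum,
               tolerance = 1e-12)
  expect_equal(lum, 0.8001, tolerance = 1e-4)
  for (seed in 1:3) {
    x <- as_image_matrix(random_image(14, seed = seed))
    y <- as_image_matrix(random_image(14, seed = seed + 10))
    expect_lte(abs(ssim(x, y)), 1)
    expect_identical(ssim(x, x), 1)
  }
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("SSIM agrees with an independent windowed-loop oracle", {
  x <- as_image_matrix(random_image(16, seed = 4))
  y <- pmin(pmax(x + 0.1 * as_image_matrix(random_image(16, seed = 5)) - 0.05,
                 0), 1)
  g <- exp(-((1:11 - 6)^2) / (2 * 1.5^2))
  wmat <- outer(g, g) / sum(outer(g, g))
  vals <- c()
  for (i in 1:6) {
    for (j in 1:6) {
      wx <- x[i:(i + 10), j:(j + 10)]
      wy <- y[i:(i + 10), j:(j + 10)]
      mx <- sum(wmat * wx); my <- sum(wmat * wy)
      vx <- sum(wmat * wx^2) - mx^2
      vy <- sum(wmat * wy^2) - my^2
      cxy <- sum(wmat * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + 1e-4) * (2 * cxy + 9e-4)) /
                  ((mx^2 + my^2 + 1e-4) * (vx + vy + 9e-4)))
    }
  }
  expect_equal(ssim(x, y), mean(vals), tolerance = 1e-6)
})

test_that("PSNR inverts the content loss", {
  for (seed in 1:3) {
    a <- as_image_matrix(random_image(12, seed = seed))
    b <- as_image_matrix(random_image(12, seed = seed + 20))
    cl <- content_loss(a, b)
    expect_equal(psnr(a, b), 10 * log10(1 / cl), tolerance = 1e-12)
  }
})
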
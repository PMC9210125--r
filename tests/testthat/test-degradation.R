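test_that("bicubic downscale obeys the size contract and rejects ragged input", {
  img <- random_image(256, seed = 1)
  expect_identical(dim(downscale_bicubic(img, 8)), c(32L, 32L))
  odd <- grayscale_image(matrix(0.5, 33, 33))
  expect_error(downscale_bicubic(odd, 8), "divisible")
})

test_that("resampling a constant image is exact", {
  for (r in c(2L, 4L, 8L)) {
    flat <- grayscale_image(matrix(0.3, 32, 32))
    expect_lt(max(abs(as_image_matrix(downscale_bicubic(flat, r)) - 0.3)), 1e-6)
    expect_lt(max(abs(as_image_matrix(upsample_bicubic(flat, r)) - 0.3)), 1e-6)
  }
})

test_that("resampling matches an independently coded bicubic oracle", {
  ramp <- grayscale_image(matrix(rep((0:31) / 31, each = 32), 32, 32,
                                 byrow = FALSE))
  got <- as_image_matrix(downscale_bicubic(ramp, 2))
  expect_lt(max(abs(got - naive_bicubic(as_image_matrix(ramp), 16, 16))), 1e-4)
  img <- random_image(16, seed = 9)
  up <- as_image_matrix(upsample_bicubic(img, 2))
  oracle <- naive_bicubic(as_image_matrix(img), 32, 32, antialias = FALSE)
  expect_lt(max(abs(up - pmin(pmax(oracle, 0), 1))), 1e-10)
})

test_that("a smooth image survives a x2 degradation cycle above 30 dB", {
  xs <- matrix(rep(seq_len(64) / 64, each = 64), 64, 64)
  smooth <- grayscale_image(0.5 + 0.3 * sin(2 * pi * xs) * cos(2 * pi * t(xs)))
  rec <- upsample_bicubic(downscale_bicubic(smooth, 2), 2)
  expect_gt(psnr(rec, smooth), 30)
})

test_that("augmentation yields the original plus seven dihedral versions", {
  img <- random_image(16, seed = 2)
  orbit <- augment(img)
  expect_length(orbit, 8)
  expect_identical(orbit[[1]], img)
  # rotation swaps axes
  rect <- grayscale_image(matrix(runif(64 * 32), 64, 32))
  expect_identical(dim(augment(rect)[[2]]), c(32L, 64L))
  # every member is a permutation of the input's pixel values
  for (m in orbit)
    expect_identical(sort(as.numeric(as_image_matrix(m))),
                     sort(as.numeric(as_image_matrix(img))))
  # a 180-degree symmetric image maps member rot180 onto the original
  sym <- as_image_matrix(img) + as_image_matrix(img)[16:1, 16:1]
  sym <- grayscale_image(sym / 2)
  expect_equal(augment(sym)[[3]], sym)
})

test_that("the dihedral orbit is closed under augmentation", {
  img <- random_image(12, seed = 5)
  orbit <- lapply(augment(img), as_image_matrix)
  for (m in orbit) {
    for (mm in augment(grayscale_image(m))) {
      hits <- vapply(orbit, function(o) identical(o, as_image_matrix(mm)),
                     logical(1))
      expect_true(any(hits))
    }
  }
})

test_that("pair construction applies the seven-additional-versions rule", {
  hrs <- lapply(1:175, function(i) random_image(16, seed = i))
  pairs <- make_pairs(hrs, 2, augment_flag = TRUE)
  expect_length(pairs, 1400)            # 175 x 8
  expect_length(make_pairs(hrs[1], 2, augment_flag = FALSE), 1)
  p <- pairs[[1]]
  expect_identical(dim(p$hr), 2L * dim(p$lr))
  expect_error(make_pairs(list(grayscale_image(matrix(0.5, 33, 33))), 8),
               "divisible")
})

test_that("patch extraction tiles and aligns LR/HR crops", {
  hr <- random_image(256, seed = 4)
  pair <- make_pairs(list(hr), 8)[[1]]
  tiles <- extract_patches(pair, 128, 128)
  expect_length(tiles, 4)
  expect_identical(dim(tiles[[1]]$lr), c(16L, 16L))
  whole <- extract_patches(pair, 256, 256)
  expect_length(whole, 1)
  expect_equal(whole[[1]]$hr, pair$hr)
  small <- extract_patches(pair, 96, 96)
  expect_identical(dim(small[[1]]$lr), c(12L, 12L))
  # alignment: each HR crop downscales to a crop of the LR image
  t2 <- tiles[[2]]
  expect_identical(dim(t2$hr), c(128L, 128L))
  expect_error(extract_patches(pair, 512), "exceeds")
  # upsampled LR always matches HR dimensions
  for (tl in tiles)
    expect_identical(dim(upsample_bicubic(tl$lr, 8)), dim(tl$hr))
})

test_that("scale factors outside {2,4,8} are rejected", {
  expect_error(scale_factor(3), "2, 4, 8")
  expect_error(paired_sample(random_image(8), random_image(24), 3), "2, 4, 8")
  expect_error(paired_sample(random_image(8), random_image(24), 2), "not 2 x")
})
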
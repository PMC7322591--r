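test_that("unsharp masking matches a dense-convolution oracle and honours its identities", {
  const <- matrix(88, 16, 16)
  expect_equal(unsharp_mask(const, sigma = 1.5, amount = 1), const)

  set.seed(21)
  p <- matrix(sample(0:255, 256, TRUE), 16, 16)
  expect_identical(unsharp_mask(p, sigma = 2, amount = 0), p)
  for (sigma in c(0.5, 1, 2)) {
    expect_equal(unsharp_mask(p, sigma = sigma, amount = 1),
                 unsharp_oracle(p, sigma, 1))
  }

  # a hard step overshoots on both sides before clipping
  step <- matrix(rep(c(0, 255), each = 8), 16, 16, byrow = TRUE)
  um_raw <- {
    g <- gaussian_blur(step, 1)
    step + 1 * (step - g)
  }
  edge_lo <- um_raw[, 8]; edge_hi <- um_raw[, 9]
  expect_true(all(edge_lo < 0))    # undershoot below the step
  expect_true(all(edge_hi > 255))  # overshoot above it
  um <- unsharp_mask(step, sigma = 1, amount = 1)
  expect_true(all(um >= 0 & um <= 255))
  expect_equal(um, unsharp_oracle(step, 1, 1))

  expect_error(unsharp_mask(p, sigma = 0), "sigma")
  expect_error(unsharp_mask(p, sigma = 1, amount = -1), "amount")
})

test_that("local entropy matches closed forms and the naive histogram oracle", {
  expect_true(all(local_entropy(matrix(42, 12, 12), 9) == 0))

  # 81 distinct intensities in a 9x9 window -> log2(81) bits at the centre
  m <- matrix(0:80, 9, 9)
  expect_equal(unclass(local_entropy(m, 9))[5, 5], log2(81), tolerance = 1e-12)

  # two-intensity window, 40 vs 41 pixels
  m2 <- matrix(c(rep(10, 40), rep(200, 41)), 9, 9)
  expect_equal(unclass(local_entropy(m2, 9))[5, 5],
               -(40 / 81) * log2(40 / 81) - (41 / 81) * log2(41 / 81),
               tolerance = 1e-12)

  set.seed(31)
  for (n in c(3L, 5L, 9L)) {
    p <- matrix(sample(0:255, 400, TRUE), 20, 20)
    expect_lt(max(abs(unclass(local_entropy(p, n)) - entropy_oracle(p, n))), 1e-9)
  }

  expect_error(local_entropy(matrix(0, 5, 5), 9), "at least")
  expect_error(local_entropy(matrix(0, 12, 12), 4), "odd")
  expect_error(local_entropy(matrix(0, 12, 12), 9, bins = 300), "bins")
})

test_that("entropy is bounded, zero only on constant windows, and label-permutation invariant", {
  set.seed(41)
  for (rep in 1:3) {
    p <- matrix(sample(0:255, 225, TRUE), 15, 15)
    e <- local_entropy(p, 5)
    expect_true(all(e >= 0 & e <= log2(25) + 1e-12))

    # remap intensities bijectively: entropies unchanged
    perm <- sample(0:255)
    p2 <- matrix(perm[p + 1L], 15, 15)
    expect_equal(unclass(local_entropy(p2, 5)), unclass(e), tolerance = 1e-12)
  }
  # zero iff constant window
  flat <- matrix(9, 11, 11); flat[6, 6] <- 10
  e <- unclass(local_entropy(flat, 3))
  nonzero <- e > 0
  # exactly the 3x3 neighbourhood of the bump sees two intensities
  expect_equal(which(nonzero, arr.ind = TRUE),
               which(outer(abs(1:11 - 6) <= 1, abs(1:11 - 6) <= 1, "&"), arr.ind = TRUE))
})

test_that("unit rescaling divides by the fixed theoretical maximum", {
  z <- local_entropy(matrix(0, 12, 12), 9)
  expect_true(all(rescale_unit(z) == 0))

  m <- matrix(0:80, 9, 9)
  e <- rescale_unit(local_entropy(m, 9))
  expect_equal(unclass(e)[5, 5], 1, tolerance = 1e-12)

  m2 <- matrix(c(rep(1, 9), rep(2, 9), rep(3, 63)), 9, 9)
  e2 <- local_entropy(m2, 9)
  expect_equal(unclass(rescale_unit(e2))[5, 5],
               unclass(e2)[5, 5] / log2(81), tolerance = 1e-12)
  expect_error(rescale_unit(rescale_unit(local_entropy(m2, 9))), "already")

  # with few bins the maximum is log2(bins)
  eb <- local_entropy(matrix(c(0, 128), 10, 10), 3, bins = 2)
  expect_true(max(rescale_unit(eb)) <= 1)
})

test_that("channel input composition equals manual chaining and handles constants", {
  flatg <- as_rgb_image(array(rep(c(0, 255, 0), each = 64), c(8, 8, 3)))
  # wide-enough constant image: both channel paths give all-zero entropy
  img0 <- as_rgb_image(array(120, c(12, 12, 3)))
  expect_true(all(make_channel_input(img0, "gray", block_size = 9) == 0))
  expect_true(all(make_channel_input(img0, "green", block_size = 9) == 0))

  phantom <- generate_phantom(phantom_spec(side = 48, grade = 3, seed = 2))$image
  for (ch in c("gray", "green")) {
    manual <- rescale_unit(local_entropy(unsharp_mask(
      if (ch == "gray") to_luminance(phantom) else extract_green(phantom),
      sigma = 2, amount = 1), 9, 256))
    expect_equal(unclass(make_channel_input(phantom, ch)), unclass(manual))
  }
})

test_that("contrast stretching never lowers mean local entropy on lesion phantoms", {
  # a noise-free full-range stretch maps distinct 8-bit levels to distinct
  # levels, so by label-permutation invariance local entropy cannot drop
  set.seed(51)
  mean_entropy <- function(p) mean(unclass(local_entropy(p, 9)))
  for (rep in 1:5) {
    ph <- generate_phantom(phantom_spec(side = 64, grade = 3,
                                        seed = sample.int(1e6, 1)))$image
    g <- extract_green(ph)
    stretched <- round((g - min(g)) * 255 / (max(g) - min(g)))
    expect_gte(mean_entropy(stretched), mean_entropy(g) - 1e-9)
  }
})

test_that("entropy images export as 8-bit PNGs", {
  ph <- generate_phantom(phantom_spec(side = 48, grade = 2, seed = 9))$image
  e <- make_channel_input(ph, "green")
  path <- withr::local_tempfile(fileext = ".png")
  export_entropy_png(e, path)
  back <- png::readPNG(path)
  expect_equal(round(back * 255), round(unclass(e) * 255), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(export_entropy_png(local_entropy(matrix(0, 12, 12), 9), path),
               "rescaled")
})
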
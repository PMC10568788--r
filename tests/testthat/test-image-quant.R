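test_that("segmentation keeps the largest above-threshold component, hole-filled", {
  img <- matrix(0, 30, 30)
  img[5:14, 5:14] <- 1
  mask <- segment_mask(img)
  expect_equal(sum(mask), 100)
  expect_true(all(mask[5:14, 5:14]))

  # two blobs: only the larger is kept
  img2 <- matrix(0, 40, 40)
  img2[2:11, 2:11] <- 1      # 100 px
  img2[25:32, 25:29] <- 1    # 40 px
  mask2 <- segment_mask(img2)
  expect_equal(sum(mask2), 100)
  expect_false(any(mask2[25:32, 25:29]))

  # holes inside the kept blob are filled
  img3 <- matrix(0, 20, 20)
  img3[4:15, 4:15] <- 1
  img3[8:10, 8:10] <- 0
  expect_equal(sum(segment_mask(img3, method = "fixed", level = 0.5)), 144)

  expect_error(segment_mask(img, method = "fixed", level = 2), "no cell")
  expect_error(segment_mask(matrix(1, 10, 10)), "constant")
})

test_that("coalescence index matches its closed forms", {
  # two-point case: values {0, 1} -> mean 0.5, sample SD sqrt(0.5)
  img <- matrix(c(0, 1, 5, 5), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  res <- coalescence_index(img, mask)
  expect_equal(res$ci, 0.5 / sqrt(0.5))
  expect_equal(res$n_pixels, 2L)

  # binary case: fraction p above threshold on n pixels
  n <- 100
  p <- 0.5
  imgb <- matrix(0, 10, 10)
  imgb[seq_len(p * n)] <- 1
  resb <- coalescence_index(imgb, matrix(TRUE, 10, 10), preprocess = "binary")
  expect_equal(resb$ci, p / sqrt(p * (1 - p) * n / (n - 1)))
  expect_equal(resb$ci, 0.5 / sqrt(0.2525252525252525), tolerance = 1e-12)

  for (pn in list(c(0.3, 100), c(0.7, 400))) {
    nn <- pn[2]
    k <- round(pn[1] * nn)
    im <- matrix(0, sqrt(nn), sqrt(nn))
    im[seq_len(k)] <- 1
    got <- coalescence_index(im, matrix(TRUE, sqrt(nn), sqrt(nn)), "binary")$ci
    pp <- k / nn
    expect_equal(got, pp / sqrt(pp * (1 - pp) * nn / (nn - 1)))
  }
})

test_that("coalescence index is affine-invariant and mask-restricted", {
  withr::with_seed(99, {
    for (i in 1:10) {
      img <- matrix(runif(400), 20, 20)
      mask <- matrix(runif(400) < 0.6, 20, 20)
      base <- coalescence_index(img, mask)$ci
      a <- runif(1, 0.1, 10); b <- runif(1, 0, 5)
      expect_equal(coalescence_index(a * img + b, mask)$ci, base,
                   tolerance = 1e-9)
      # pixels outside the mask are irrelevant
      img2 <- img
      img2[!mask] <- runif(sum(!mask), 0, 100)
      expect_equal(coalescence_index(img2, mask)$ci, base)
    }
  })
})

test_that("degenerate coalescence inputs error informatively", {
  flat <- matrix(3, 5, 5)
  expect_error(coalescence_index(flat, matrix(TRUE, 5, 5)), "spread")
  img <- matrix(runif(25), 5, 5)
  one_px <- matrix(FALSE, 5, 5); one_px[1] <- TRUE
  expect_error(coalescence_index(img, one_px), "2 pixels")
  expect_error(coalescence_index(matrix(-1, 5, 5), matrix(TRUE, 5, 5)),
               "non-negative")
})

test_that("intensity ratio is the quotient of in-mask integrals", {
  a <- matrix(1:9, 3, 3)
  mask <- matrix(TRUE, 3, 3)
  expect_equal(intensity_ratio(a, a, mask), 1.0)
  expect_equal(intensity_ratio(2 * a, a, mask), 2.0)

  # hand-summed 3x3 grid with a partial mask
  b <- matrix(c(2, 0, 1, 3, 5, 2, 0, 1, 4), 3, 3)
  m <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE), 3, 3)
  # in-mask a: 1 + 2 + 4 + 6 + 7 + 9 = 29; in-mask b: 2 + 0 + 3 + 2 + 0 + 4 = 11
  expect_equal(intensity_ratio(a, b, m), 29 / 11)

  # equivariance: scaling a scales the ratio, scaling b divides it
  expect_equal(intensity_ratio(3 * a, b, m), 3 * 29 / 11)
  expect_equal(intensity_ratio(a, 2 * b, m), 29 / 22)
  expect_error(intensity_ratio(a, matrix(0, 3, 3), mask), "zero")
  expect_error(intensity_ratio(a, matrix(1, 4, 4), mask), "differ")
})

test_that("normalized mean intensity divides by the maximum", {
  expect_equal(normalized_mean_intensity(c(2, 4, 8)), c(0.25, 0.5, 1.0))
  expect_equal(normalized_mean_intensity(5), 1.0)
  v <- c(3, 1, 7, 2)
  perm <- c(4, 2, 1, 3)
  expect_equal(normalized_mean_intensity(v[perm]),
               normalized_mean_intensity(v)[perm])
  expect_error(normalized_mean_intensity(numeric(0)), "nonempty")
  expect_error(normalized_mean_intensity(c(0, 0)), "positive")
})

test_that("contraction fractions exclude ambiguous cells and flag empty frames", {
  one <- contraction_fraction(data.frame(contracted = 3, relaxed = 7,
                                         ambiguous = 1))
  expect_equal(tidy(one)$fraction, 0.3)
  expect_equal(glance(one)$pooled_fraction, 0.3)

  two <- contraction_fraction(data.frame(contracted = c(0, 10),
                                         relaxed = c(10, 0),
                                         ambiguous = c(0, 0)))
  expect_equal(tidy(two)$fraction, c(0.0, 1.0))
  expect_equal(two$pooled, 0.5)

  amb <- contraction_fraction(data.frame(contracted = 0, relaxed = 0,
                                         ambiguous = 5))
  expect_true(is.na(tidy(amb)$fraction))
  expect_true(tidy(amb)$undefined)
  expect_equal(glance(amb)$n_undefined_frames, 1)

  expect_error(contraction_fraction(data.frame(contracted = -1, relaxed = 2)),
               "non-negative")
  # missing ambiguous column defaults to zero
  noamb <- contraction_fraction(data.frame(contracted = 1, relaxed = 3))
  expect_equal(noamb$pooled, 0.25)
})
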
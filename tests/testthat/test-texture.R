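# Brightness and Haralick texture features.

test_that("brightness statistics come from in-mask pixels only", {
  ct <- contour(c(1, 8, 8, 1), c(1, 1, 8, 8))
  uniform <- image_patch(matrix(100L, 12, 12), origin = c(-1, -1))
  b <- patch_brightness(uniform, ct)
  expect_equal(unname(b), c(100, 0))

  # checkerboard of 0 / 200 inside the mask -> mean 100, population SD 100
  vals <- matrix(0L, 12, 12)
  vals[(row(vals) + col(vals)) %% 2 == 0] <- 200L
  checker <- image_patch(vals, origin = c(-1, -1))
  b2 <- patch_brightness(checker, ct)
  expect_equal(b2[["mean"]], 100, tolerance = 3)  # parity imbalance in mask
  expect_equal(b2[["sd"]], 100, tolerance = 1)

  # brute-force mask oracle: pixels outside the contour do not contribute;
  # half-integer contour keeps every pixel center off the boundary
  ct_half <- contour(c(0.5, 8.5, 8.5, 0.5), c(0.5, 0.5, 8.5, 8.5))
  set.seed(5)
  noisy <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  patch <- image_patch(noisy, origin = c(-1, -1))
  # matrix element [r, c] sits at (x, y) = (c - 2, r - 2)
  xs <- col(noisy) - 2; ys <- row(noisy) - 2
  in_mask <- xs > 0.5 & xs < 8.5 & ys > 0.5 & ys < 8.5
  b3 <- patch_brightness(patch, ct_half)
  expect_equal(b3[["mean"]], mean(noisy[in_mask]))
})

test_that("empty mask errors", {
  ct <- contour(c(100, 101, 101), c(100, 100, 101))
  patch <- image_patch(matrix(1L, 4, 4))
  expect_error(patch_brightness(patch, ct), "inside the contour")
})

test_that("uniform texture gives ASM 1 and zero entropy", {
  ct <- contour(c(0, 9, 9, 0), c(0, 0, 9, 9))
  patch <- image_patch(matrix(77L, 10, 10))
  h <- patch_haralick(patch, ct)
  expect_length(h, 13)
  expect_equal(h[["asm"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)
})

test_that("GLCM equals the brute-force pairwise oracle exactly", {
  set.seed(11)
  vals <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  ct <- contour(c(-0.5, 7.5, 7.5, -0.5), c(-0.5, -0.5, 7.5, 7.5))
  patch <- image_patch(vals, origin = c(0, 0))
  mask <- matrix(TRUE, 8, 8)
  expect_equal(rtdcstats:::glcm(patch, ct, n_levels = 16),
               glcm_oracle(vals, mask, n_levels = 16), tolerance = 1e-12)

  # direct-formula check of representative features from the oracle matrix
  p <- glcm_oracle(vals, mask, 16)
  h <- patch_haralick(patch, ct, n_levels = 16)
  expect_equal(h[["asm"]], sum(p^2), tolerance = 1e-12)
  expect_equal(h[["contrast"]], sum((row(p) - col(p))^2 * p),
               tolerance = 1e-12)
  expect_equal(h[["entropy"]], -sum(p[p > 0] * log2(p[p > 0])),
               tolerance = 1e-12)
})

test_that("masking restricts co-occurrence pairs to the cell interior", {
  set.seed(12)
  vals <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  ct <- contour(c(2, 7, 7, 2), c(2, 2, 7, 7))
  patch <- image_patch(vals, origin = c(0, 0))
  # pair counting must respect the mask: feed the package's even-odd mask
  # to the brute-force pair enumerator and compare matrices
  mask_pkg <- rtdcstats:::patch_mask(patch, ct)
  expect_lt(sum(mask_pkg), 100)  # the mask is a proper subset of the patch
  expect_equal(rtdcstats:::glcm(patch, ct, 16),
               glcm_oracle(vals, mask_pkg, 16), tolerance = 1e-12)
})

test_that("too-small masks error and the feature vector length is fixed", {
  ct <- contour(c(0, 0.2, 0.2, 0), c(0, 0, 0.2, 0.2))
  patch <- image_patch(matrix(5L, 3, 3))
  expect_error(patch_haralick(patch, ct))
  ct2 <- contour(c(0, 5, 5, 0), c(0, 0, 5, 5))
  expect_length(patch_haralick(image_patch(matrix(5L, 6, 6)), ct2), 13)
})

test_that("textured synthetic patches separate by haralick features", {
  fine <- gen_contour("circle", r = 8, with_patch = TRUE, patch_sd = 40,
                      seed = 1)
  smooth <- gen_contour("circle", r = 8, with_patch = TRUE, patch_sd = 2,
                        seed = 2)
  h_fine <- patch_haralick(fine$patch, fine$contour)
  h_smooth <- patch_haralick(smooth$patch, smooth$contour)
  expect_gt(h_fine[["entropy"]], h_smooth[["entropy"]])
  expect_lt(h_fine[["asm"]], h_smooth[["asm"]])
})
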
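# small rectangular phantom: 40 normal myocardial pixels at 100 with a
# textured remote region, 10 hyperenhanced pixels at 200
make_block_slice <- function(intensity_infarct = 200, remote_sd = 5,
                             pixel_area = 1, thickness = 8) {
  img <- matrix(0, 10, 10)
  myo <- matrix(FALSE, 10, 10)
  myo[1:5, 1:10] <- TRUE                  # 50 myocardial pixels
  img[myo] <- 100
  rem <- matrix(FALSE, 10, 10)
  rem[1:2, 1:10] <- TRUE                  # 20 remote pixels
  img[rem] <- 100 + remote_sd * rep_len(c(-1, 1), 20)
  inf <- matrix(FALSE, 10, 10)
  inf[5, 1:10] <- TRUE                    # 10 planted infarct pixels
  img[inf] <- intensity_infarct
  list(slice = lge_slice(img, myo, rem, pixel_area, thickness),
       planted = inf)
}

test_that("threshold is remote mean + k SD and the planted mass is recovered", {
  bs <- make_block_slice()
  res <- segment_infarct(bs$slice)
  remote_vals <- bs$slice$pixel_intensities[bs$slice$remote_mask]
  expect_equal(res$threshold, mean(remote_vals) + 2 * stats::sd(remote_vals))
  expect_equal(res$infarct_mask, bs$planted)
  # 10 pixels x 1 mm^2 x 8 mm x 1.05 g/mL = 0.084 g
  expect_equal(res$infarct_mass_g, 10 * 1 * 8 * 1.05 / 1000)
  expect_equal(res$lv_mass_g, 50 * 1 * 8 * 1.05 / 1000)
  expect_equal(res$infarct_pct_lv, 100 * res$infarct_mass_g / res$lv_mass_g)
})

test_that("random phantom mask equals brute-force per-pixel comparison", {
  set.seed(9)
  img <- matrix(stats::rnorm(400, 100, 15), 20, 20)
  myo <- matrix(stats::runif(400) < 0.6, 20, 20)
  rem <- myo & matrix(stats::runif(400) < 0.3, 20, 20)
  while (sum(rem) < 2) rem[which(myo)[1:2]] <- TRUE
  sl <- lge_slice(img, myo, rem, 1.2, 6)
  res <- segment_infarct(sl, k_sd = 2)
  manual <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20)
    manual[i, j] <- myo[i, j] && img[i, j] >= res$threshold
  expect_equal(res$infarct_mask, manual)
})

test_that("raising k_sd never grows the infarct mask", {
  set.seed(21)
  img <- matrix(stats::rnorm(400, 100, 20), 20, 20)
  myo <- matrix(TRUE, 20, 20)
  rem <- matrix(FALSE, 20, 20); rem[1:4, ] <- TRUE
  sl <- lge_slice(img, myo, rem, 1, 8)
  sizes <- vapply(c(0, 1, 2, 3, 4), function(k)
    sum(segment_infarct(sl, k_sd = k)$infarct_mask), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("mask is invariant under affine intensity maps and pct under rescale", {
  bs <- make_block_slice()
  res <- segment_infarct(bs$slice)
  img2 <- 2.5 * bs$slice$pixel_intensities + 40
  sl2 <- lge_slice(img2, bs$slice$myocardial_mask, bs$slice$remote_mask, 1, 8)
  res2 <- segment_infarct(sl2)
  expect_equal(res2$infarct_mask, res$infarct_mask)

  # uniform pixel-size rescaling conserves the percentage, not the grams
  sl3 <- lge_slice(bs$slice$pixel_intensities, bs$slice$myocardial_mask,
                   bs$slice$remote_mask, 4, 8)
  res3 <- segment_infarct(sl3)
  expect_equal(res3$infarct_pct_lv, res$infarct_pct_lv)
  expect_equal(res3$infarct_mass_g, 4 * res$infarct_mass_g)
})

test_that("degenerate remote region and invalid geometry are rejected", {
  img <- matrix(100, 6, 6)
  myo <- matrix(TRUE, 6, 6)
  rem <- matrix(FALSE, 6, 6); rem[1:2, 1] <- TRUE
  sl <- lge_slice(img, myo, rem, 1, 8)
  expect_error(segment_infarct(sl), "zero intensity SD")

  expect_error(lge_slice(img, myo, matrix(FALSE, 6, 6), 1, 8), "at least 2")
  rem_out <- matrix(FALSE, 6, 6); rem_out[1:2, 1] <- TRUE
  myo_small <- matrix(FALSE, 6, 6); myo_small[4:6, ] <- TRUE
  expect_error(lge_slice(img, myo_small, rem_out, 1, 8), "subset")
})

test_that("LV mass is additive over slices and matches enumeration", {
  bs <- make_block_slice()
  one <- lv_mass(bs$slice)
  expect_equal(one, 50 * 8 * 1.05 / 1000)
  expect_equal(lv_mass(list(bs$slice, bs$slice)), 2 * one)

  set.seed(4)
  slices <- lapply(1:3, function(i) {
    myo <- matrix(stats::runif(100) < 0.5, 10, 10)
    myo[1:2, 1] <- TRUE
    img <- matrix(stats::rnorm(100, 100, 5), 10, 10)
    rem <- matrix(FALSE, 10, 10); rem[1:2, 1] <- TRUE
    lge_slice(img, myo, rem, 1.5, 7)
  })
  total <- 0
  for (s in slices) {
    npix <- 0
    for (i in 1:10) for (j in 1:10) if (s$myocardial_mask[i, j]) npix <- npix + 1
    total <- total + npix * 1.5 * 7 * 1.05 / 1000
  }
  expect_equal(lv_mass(slices), total)
})
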
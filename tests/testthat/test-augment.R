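# The five mixed-sample operators and the Gaussian mask smoothing they share.

test_that("mix_params enforces its invariants", {
  p <- mix_params()
  expect_equal(p$alpha + p$beta, 1)
  expect_equal(p$alpha, 0.8)
  expect_error(mix_params(alpha = 0.8, beta = 0.3), "equal 1")
  expect_error(mix_params(alpha = 1.2), "\\[0, 1\\]")
  expect_error(mix_params(sigma = 0), "positive")
})

test_that("smooth_mask preserves constants and matches the kernel oracle", {
  ones <- matrix(1, 16, 16)
  expect_equal(smooth_mask(ones, 3), ones, ignore_attr = TRUE)
  zeros <- matrix(0, 16, 16)
  expect_equal(smooth_mask(zeros, 3), zeros, ignore_attr = TRUE)
  # single pixel at the center of 33x33, sigma 2: the smoothed center value
  # is the peak of the discrete 2-D Gaussian kernel
  m <- matrix(0, 33, 33); m[17, 17] <- 1
  sm <- smooth_mask(m, 2)
  expect_equal(sm[17, 17], oracle_gauss_peak(2))
  expect_true(all(sm >= 0 & sm <= 1))
  # mass conservation away from borders
  expect_equal(sum(sm), 1, tolerance = 1e-10)
  expect_error(smooth_mask(m, -1), "positive")
})

test_that("smooth_mask approaches the hard mask as sigma shrinks", {
  m <- rand_mask(24, 24)
  expect_equal(smooth_mask(m, 0.01), m, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("pixmix obeys its closed form", {
  withr::local_seed(1)
  lab <- rand_labeled()
  unl <- rand_image()
  # identity case
  expect_identical(pixmix(lab, unl, mix_params(alpha = 1))$image, lab$image)
  # constant arithmetic: 0.8 * 1 + 0.2 * 0.5 = 0.9
  clab <- labeled_sample(matrix(1, 8, 8), rand_mask(8, 8), "c")
  out <- pixmix(clab, matrix(0.5, 8, 8), mix_params(alpha = 0.8))
  expect_equal(out$image, matrix(0.8 * 1 + 0.2 * 0.5, 8, 8))
  # brute-force per-pixel oracle, exact
  p <- mix_params(alpha = 0.8)
  aug <- pixmix(lab, unl, p)
  expect_identical(aug$image, oracle_pixmix(lab$image, unl, p$alpha, p$beta))
  expect_error(pixmix(lab, rand_image(8, 8)), "mismatch")
})

test_that("segmix2 follows its equation and degenerate cases", {
  withr::local_seed(2)
  unl <- rand_image()
  # all-zero mask: output is the unlabeled image
  lab0 <- labeled_sample(rand_image(), matrix(0, 16, 16), "z")
  expect_identical(segmix2(lab0, unl)$image, unl)
  # gamma = 1, all-ones mask: output is the labeled image
  lab1 <- labeled_sample(rand_image(), matrix(1, 16, 16), "o")
  out <- segmix2(lab1, unl, mix_params(gamma = 1, sigma = 2))
  expect_equal(out$image, lab1$image, tolerance = 1e-12)
  # random inputs vs composition of smoothing and the per-pixel formula
  lab <- rand_labeled()
  tlp <- smooth_mask(lab$mask, 2)
  aug <- segmix2(lab, unl, mix_params(gamma = 0.5, sigma = 2))
  expect_identical(aug$image, oracle_segmix2(tlp, lab$image, unl, 0.5))
})

test_that("lesionblend/lesionblend2 are exact complements", {
  withr::local_seed(3)
  unl <- rand_image()
  lab1 <- labeled_sample(rand_image(), matrix(1, 16, 16), "o")
  expect_equal(lesionblend(lab1, unl)$image, lab1$image, tolerance = 1e-12)
  expect_equal(lesionblend2(lab1, unl)$image, unl, tolerance = 1e-12)
  lab0 <- labeled_sample(rand_image(), matrix(0, 16, 16), "z")
  expect_identical(lesionblend(lab0, unl)$image, unl)
  expect_identical(lesionblend2(lab0, unl)$image, lab0$image)
  # per-pixel oracles and the swap identity (lesionblend2 == lesionblend
  # with soft mask complemented)
  lab <- rand_labeled()
  tlp <- smooth_mask(lab$mask, 5)
  expect_identical(lesionblend(lab, unl)$image,
                   oracle_lesionblend(tlp, lab$image, unl))
  expect_identical(lesionblend2(lab, unl)$image,
                   oracle_lesionblend2(tlp, lab$image, unl))
  expect_equal(lesionblend2(lab, unl)$image,
               oracle_lesionblend(1 - tlp, lab$image, unl),
               tolerance = 1e-12)
})

test_that("pixmix2 sums and renormalizes", {
  withr::local_seed(4)
  # unlabeled all zero, labeled spanning [0, 1]: rescaled sum is the input
  il <- rand_image(); il[1, 1] <- 0; il[2, 2] <- 1
  lab <- labeled_sample(il, rand_mask(), "s")
  expect_identical(pixmix2(lab, matrix(0, 16, 16))$image, il)
  # two constants: degenerate range maps to all-zero
  clab <- labeled_sample(matrix(0.4, 8, 8), rand_mask(8, 8), "c")
  expect_equal(pixmix2(clab, matrix(0.3, 8, 8))$image, matrix(0, 8, 8))
  # clip mode clamps instead
  expect_equal(pixmix2(clab, matrix(0.3, 8, 8),
                       mix_params(pixmix2_overflow = "clip"))$image,
               matrix(0.7, 8, 8))
  # random pair vs sum + min-max rescale oracle
  unl <- rand_image()
  lab2 <- rand_labeled()
  expect_identical(pixmix2(lab2, unl)$image,
                   oracle_pixmix2(lab2$image, unl))
})

test_that("all five strategies keep the mask bit-identical and in range", {
  for (seed in 1:25) {
    pp <- phantom_pair(seed, 48, 48)
    for (st in c("pixmix", "segmix2", "lesionblend", "lesionblend2",
                 "pixmix2")) {
      aug <- apply_mixed_strategy(st, pp$lab, pp$unl)
      expect_identical(aug$mask, pp$lab$mask)
      expect_true(all(aug$image >= 0 & aug$image <= 1),
                  label = paste(st, "range safety, seed", seed))
    }
  }
})

test_that("convex strategies stay within the pixelwise envelope", {
  withr::local_seed(5)
  for (rep in 1:10) {
    lab <- rand_labeled()
    unl <- rand_image()
    lo <- pmin(lab$image, unl); hi <- pmax(lab$image, unl)
    for (st in c("pixmix", "lesionblend", "lesionblend2")) {
      img <- apply_mixed_strategy(st, lab, unl)$image
      expect_true(all(img >= lo - 1e-12 & img <= hi + 1e-12), label = st)
    }
  }
})

test_that("operators are deterministic: identical inputs, identical output", {
  withr::local_seed(6)
  lab <- rand_labeled()
  unl <- rand_image()
  for (st in c("pixmix", "segmix2", "lesionblend", "lesionblend2",
               "pixmix2")) {
    a <- apply_mixed_strategy(st, lab, unl)
    b <- apply_mixed_strategy(st, lab, unl)
    expect_identical(a$image, b$image, label = st)
  }
})

test_that("segmix2 at gamma 1 and vanishing sigma is hard copy-paste", {
  pp <- phantom_pair(42, 48, 48)
  aug <- segmix2(pp$lab, pp$unl, mix_params(gamma = 1, sigma = 0.01))
  hard <- pp$lab$mask * pp$lab$image + (1 - pp$lab$mask) * pp$unl
  expect_lt(max(abs(aug$image - hard)), 1 / 255)
})
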
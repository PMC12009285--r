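test_that("binary thresholding is exact and monotone in the threshold", {
  img <- matrix(c(100, 50, 200, 220), 2, 2)
  expect_identical(apply_threshold(img, 150), matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_true(all(apply_threshold(img, 0) == 1))        # nothing below 0
  expect_true(all(apply_threshold(img, 256) == 0))      # everything below 2^r
  # nesting: lower thresholds produce supersets
  set.seed(4)
  rnd <- gray_image(matrix(sample(0:255, 400, TRUE), 20, 20))
  prev <- apply_threshold(rnd, 0)
  for (i in 1:256) {
    cur <- apply_threshold(rnd, i)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("Otsu between-class variance has its closed form on two levels", {
  two <- gray_image(matrix(c(rep(50, 50), rep(200, 50)), 10, 10))
  expect_equal(otsu_objective(two, 125), 0.25 * 150^2)  # 5625
  expect_equal(otsu_objective(two, 40), 0)              # one class empty
  vals <- vapply(1:255, function(i) otsu_objective(two, i), numeric(1))
  best <- which(vals == max(vals))                      # thresholds 1..255
  expect_true(all(best > 50 & best <= 200))
  expect_error(otsu_objective(gray_image(matrix(7, 4, 4)), 100),
               "degenerate histogram")
})

test_that("optimizer-driven threshold attains the exhaustive Otsu optimum", {
  for (s in 1:5) {
    ph <- lesion_phantom(seed = s)
    got <- optimal_threshold(ph$image, config = optimizer_config(seed = s))
    oracle <- exhaustive_otsu(ph$image)
    expect_equal(got$fitness_value, oracle$value)
    # returned threshold sits strictly between the background and lesion modes
    expect_gt(got$threshold, 0)
    expect_lt(got$threshold, 255)
  }
})

test_that("thresholds agree with the independent EBImage Otsu oracle", {
  skip_if_not_installed("EBImage")
  ph <- lesion_phantom(seed = 9)
  oracle <- exhaustive_otsu(ph$image)
  eb <- EBImage::otsu(EBImage::Image(t(as.matrix(ph$image)) / 255),
                      range = c(0, 1), levels = 256) * 255
  # conventions differ by one level (foreground > t vs >= I)
  expect_lte(abs(oracle$threshold - eb), 2)
})

test_that("supervised mode recovers a self-consistent reference exactly", {
  ph <- lesion_phantom(seed = 2)
  ref <- apply_threshold(ph$image, 150)
  got <- optimal_threshold(ph$image, fitness = "dice", reference = ref,
                           config = optimizer_config(seed = 1))
  expect_equal(got$fitness_value, 1.0)
  expect_identical(got$mask, ref)
})

test_that("degenerate and invalid segmentation inputs error", {
  expect_error(optimal_threshold(gray_image(matrix(9, 8, 8))),
               "degenerate histogram")
  expect_error(optimal_threshold(lesion_phantom(1)$image, fitness = "dice"),
               "reference")
  expect_error(optimal_threshold(lesion_phantom(1)$image, fitness = "dice",
                                 reference = matrix(0, 2, 2)), "shape")
})

test_that("overlap coefficients count pixels correctly", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(mask_overlap(a, a)$dice, 1)
  expect_equal(mask_overlap(a, 1 - a)$jaccard, 0)
  # pred covers half of ref with nothing extra: dice 2/3, jaccard 1/2
  ref <- matrix(c(1, 1, 0, 0), 2, 2)
  pred <- matrix(c(1, 0, 0, 0), 2, 2)
  ov <- mask_overlap(pred, ref)
  expect_equal(ov$dice, 2 / 3)
  expect_equal(ov$jaccard, 1 / 2)
  expect_equal(mask_overlap(matrix(0, 2, 2), matrix(0, 2, 2))$dice, 1)
  expect_error(mask_overlap(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("dice dominates jaccard on random mask pairs", {
  set.seed(8)
  for (i in 1:50) {
    a <- matrix(rbinom(64, 1, 0.4), 8, 8)
    b <- matrix(rbinom(64, 1, 0.4), 8, 8)
    ov <- mask_overlap(a, b)
    expect_gte(ov$dice, ov$jaccard)
    expect_true(ov$dice >= 0 && ov$dice <= 1)
    expect_true(ov$jaccard >= 0 && ov$jaccard <= 1)
  }
})
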
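test_that("a lesion-free phantom has an empty mask and normal label", {
  p <- generate_phantom(phantom_spec(noise_sigma = 0, seed = 1))
  expect_true(all(p$mask == 0))
  expect_equal(p$label, "normal")
})

test_that("the mask matches the analytic half-maximum disk area", {
  # non-integer radii avoid the knife-edge where lattice points sit exactly
  # on the half-maximum contour (excluded by the strict inequality)
  for (r in c(5.5, 7.5, 9.5)) {
    p <- generate_phantom(phantom_spec(
      lesions = list(list(center = c(32, 32), radius = r, delta = 60)),
      noise_sigma = 0, seed = 2))
    expect_lt(abs(sum(p$mask) - pi * r^2) / (pi * r^2), 0.1)
    expect_equal(p$label, "abnormal")
  }
})

test_that("generation is a pure function of the spec", {
  spec <- phantom_spec(lesions = list(list(center = c(20, 40), radius = 6,
                                           delta = 60)), seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(as.matrix(a$image), as.matrix(b$image))
  expect_identical(a$mask, b$mask)
})

test_that("invalid lesions are rejected", {
  expect_error(phantom_spec(lesions = list(list(center = c(100, 100),
                                                radius = 5, delta = 60))),
               "outside")
  expect_error(phantom_spec(lesions = list(list(center = c(10, 10),
                                                radius = 5, delta = -1))),
               "hyperthermic")
  expect_error(phantom_spec(lesions = list(list(center = c(10, 10)))),
               "needs")
})

test_that("cohorts have exact class counts and a well-formed manifest", {
  d1 <- file.path(tempdir(), "coh1")
  m <- generate_cohort(5, 5, d1, seed = 3)
  expect_equal(nrow(m), 10L)
  expect_equal(sum(m$label == "normal"), 5L)
  expect_equal(sum(m$label == "abnormal"), 5L)
  expect_true(all(file.exists(file.path(d1, m$image_path))))
  expect_true(all(file.exists(file.path(d1, m$mask_path))))
  m2 <- generate_cohort(0, 3, file.path(tempdir(), "coh2"), seed = 3)
  expect_equal(nrow(m2), 3L)
  expect_true(all(m2$label == "abnormal"))
})

test_that("two cohort runs with one seed produce identical files", {
  da <- file.path(tempdir(), "cohA"); db <- file.path(tempdir(), "cohB")
  ma <- generate_cohort(2, 2, da, seed = 7)
  mb <- generate_cohort(2, 2, db, seed = 7)
  expect_identical(ma, mb)
  for (p in c(ma$image_path, ma$mask_path, "manifest.csv")) {
    expect_identical(unname(tools::md5sum(file.path(da, p))),
                     unname(tools::md5sum(file.path(db, p))))
  }
})

test_that("PNG round trip preserves images and masks", {
  p <- generate_phantom(phantom_spec(lesions = list(list(center = c(30, 30),
                                                         radius = 6,
                                                         delta = 60)),
                                     seed = 5))
  f <- file.path(tempdir(), "rt.png")
  write_gray(p$image, f)
  expect_identical(as.matrix(read_gray(f)), as.matrix(p$image))
  fm <- file.path(tempdir(), "rtm.png")
  write_mask(p$mask, fm)
  expect_identical(read_mask(fm), p$mask * 1L)
})

test_that("raising lesion contrast raises class separability", {
  # quiet background so the dial effect is isolated from background structure
  mean_var <- vapply(c(20, 40, 60), function(delta) {
    mean(vapply(1:5, function(s) {
      p <- generate_phantom(phantom_spec(
        gradient_amplitude = 5, mode_amplitude = 2,
        lesions = list(list(center = c(32, 32), radius = 7, delta = delta)),
        noise_sigma = 5, seed = s))
      otsu_objective(p$image, 120 + delta / 2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_var) > 0))
})
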
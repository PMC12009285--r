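# Shared fixtures, all generated in code.

# bimodal image: two intensity populations around lo and hi
bimodal_image <- function(lo = 80, hi = 180, n = 32, sd = 4, seed = 1) {
  set.seed(seed)
  half <- n * n / 2
  px <- clamp_int(round(c(rnorm(half, lo, sd), rnorm(half, hi, sd))), 0, 255)
  gray_image(matrix(sample(px), n, n))
}

clamp_int <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# a single-lesion phantom with default study conditions
lesion_phantom <- function(seed = 1, delta = 60, noise = 5, radius = 7) {
  generate_phantom(phantom_spec(
    lesions = list(list(center = c(32, 32), radius = radius, delta = delta)),
    noise_sigma = noise, seed = seed))
}

# exhaustive-search oracle for the Otsu threshold
exhaustive_otsu <- function(img) {
  vals <- vapply(0:max_gray(img), function(i) otsu_objective(img, i), numeric(1))
  list(threshold = which.max(vals) - 1L, value = max(vals))
}

# linearly separable two-class features
separable_features <- function(n = 30, d = 16, gap = 4, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(rnorm(n * d), n, d)
  X[y == "b", 1:4] <- X[y == "b", 1:4] + gap
  list(X = X, y = y)
}
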
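test_that("each head separates a linearly separable problem", {
  sep <- separable_features(n = 30, d = 16, seed = 1)
  heads <- fit_heads(sep$X, sep$y, hidden = 32, epochs = 80, seed = 5)
  expect_named(heads, c("vgg_like", "resnet_like", "densenet_like"))
  for (sc in score_heads(heads, sep$X)) {
    expect_equal(rowSums(sc), rep(1, nrow(sep$X)), tolerance = 1e-9)
    acc <- mean(colnames(sc)[apply(sc, 1, which.max)] == sep$y)
    expect_gte(acc, 0.95)
  }
})

test_that("one sample per class trains and predicts without crashing", {
  X <- rbind(rep(0, 8), rep(5, 8))
  y <- factor(c("a", "b"))
  heads <- fit_heads(X, y, hidden = 8, epochs = 60, seed = 1)
  pred <- predict_ensemble(heads, X)
  expect_equal(pred$class, c("a", "b"))
})

test_that("head fitting is deterministic given the master seed", {
  sep <- separable_features(seed = 2)
  h1 <- fit_heads(sep$X, sep$y, seed = 7)
  h2 <- fit_heads(sep$X, sep$y, seed = 7)
  expect_identical(h1, h2)
  # heads differ from one another (distinct derived seeds)
  expect_false(identical(h1$vgg_like$W1, h1$resnet_like$W1))
})

test_that("higher-score decision sums head scores with argmax + low-index ties", {
  d <- decide(list(c(0.9, 0.1), c(0.4, 0.6), c(0.45, 0.55)))
  expect_equal(d$aggregate, matrix(c(1.75, 1.25), 1))
  expect_equal(d$class, 1L)                     # sums favour the first class
  expect_equal(decide(list(c(0.9, 0.1), c(0.9, 0.1), c(0.9, 0.1)))$class, 1L)
  expect_equal(decide(list(c(0.5, 0.5), c(0.5, 0.5)))$class, 1L)  # tie rule
  expect_error(decide(list(c(0.5, 0.5), c(1, 0, 0))), "class counts")
})

test_that("sum-rule decision agrees with unanimous per-head argmax", {
  set.seed(6)
  for (i in 1:20) {
    s <- lapply(1:3, function(k) {
      v <- runif(3); v / sum(v)
    })
    tops <- vapply(s, which.max, integer(1))
    if (length(unique(tops)) == 1L) {
      expect_equal(decide(s)$class, tops[1])
    }
  }
})

test_that("max-rule variant differs only in aggregation", {
  s <- list(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7))
  expect_equal(decide(s, rule = "max")$aggregate, matrix(c(0.9, 0.8), 1))
})

test_that("accuracy is the fraction of correct decisions", {
  expect_equal(accuracy_fitness(rep("a", 5), rep("a", 5)), 1)
  expect_equal(accuracy_fitness(rep("a", 5), rep("b", 5)), 0)
  pred <- c(rep("a", 14), rep("b", 6))
  truth <- c(rep("a", 14), rep("a", 6))
  expect_equal(accuracy_fitness(pred, truth), 0.7)
  expect_error(accuracy_fitness(character(0), character(0)), "empty")
})

test_that("hyperparameter tuning reaches high validation accuracy when separable", {
  sep <- separable_features(n = 40, d = 12, seed = 3)
  set.seed(3)
  f2 <- sep$X + matrix(rnorm(length(sep$X), sd = 0.1), nrow(sep$X))
  f3 <- sep$X + matrix(rnorm(length(sep$X), sd = 0.1), nrow(sep$X))
  fit <- optimize_hyperparameters(sep$X, f2, f3, sep$y,
                                  train_idx = c(1:14, 21:34),
                                  val_idx = c(15:20, 35:40),
                                  config = optimizer_config(
                                    population_size = 6, max_iterations = 3,
                                    max_seeds = 4, seed = 2))
  expect_gte(fit$accuracy, 0.95)
  hp <- fit$hp
  expect_true(hp$epochs >= 50 && hp$epochs <= 100)
  expect_true(hp$hidden >= 5 && hp$hidden <= 255)
  expect_true(hp$activation %in% c("relu", "sigmoid", "tanh"))
  expect_true(all(hp$weights >= 0 & hp$weights <= 1))
})

test_that("a collapsed search space returns its single point", {
  sep <- separable_features(n = 20, d = 8, seed = 4)
  space <- hp_space(weights = c(0.5, 0.5), epochs = c(60, 60),
                    hidden = c(16, 16), activations = "tanh")
  fit <- optimize_hyperparameters(sep$X, sep$X, sep$X, sep$y,
                                  train_idx = 1:14, val_idx = 15:20,
                                  space = space,
                                  config = optimizer_config(seed = 1))
  expect_equal(fit$hp$weights, rep(0.5, 3))
  expect_equal(fit$hp$epochs, 60L)
  expect_equal(fit$hp$hidden, 16L)
  expect_equal(fit$hp$activation, "tanh")
  expect_null(fit$history)
})

test_that("tuned hyperparameters stay within bounds across seeds", {
  sep <- separable_features(n = 20, d = 8, seed = 5)
  for (s in 1:2) {
    fit <- optimize_hyperparameters(sep$X, sep$X, sep$X, sep$y,
                                    train_idx = 1:14, val_idx = 15:20,
                                    config = optimizer_config(
                                      population_size = 4, max_iterations = 2,
                                      max_seeds = 3, seed = s))
    expect_true(fit$hp$epochs >= 50 && fit$hp$epochs <= 100)
    expect_true(fit$hp$hidden >= 5 && fit$hp$hidden <= 255)
  }
})

test_that("empty training input errors", {
  expect_error(fit_heads(matrix(numeric(0), 0, 4), factor(character(0))),
               "empty")
})
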
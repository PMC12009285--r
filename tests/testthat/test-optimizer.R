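test_that("fitness angle normalizes onto [0, 360] with degenerate guard", {
  expect_equal(compute_angle(1, 1, 5), 0)
  expect_equal(compute_angle(5, 1, 5), 360)
  expect_equal(compute_angle(3, 1, 5), 180)
  expect_equal(compute_angle(2, 2, 2), 0)   # degenerate population
  expect_error(compute_angle(NaN, 1, 5), "finite")
  expect_error(compute_angle(1, Inf, 5), "finite")
})

test_that("routing sends angles strictly above 180 to the swarm branch", {
  expect_identical(route_update(360), "RHSO")
  expect_identical(route_update(0), "DA")
  expect_identical(route_update(180), "DA")   # boundary is dandelion
  # exhaustive over a fine grid: predicate is exactly angle > 180
  for (a in seq(0, 360, by = 0.5)) {
    expect_identical(route_update(a), if (a > 180) "RHSO" else "DA")
  }
})

test_that("angle perturbation clamps into [0, 360]", {
  expect_equal(perturb_angle(360, delta = 20), 360)
  expect_equal(perturb_angle(0, delta = -20), 0)
  expect_equal(perturb_angle(123.4, delta = 0), 123.4)
})

test_that("leader update contracts its previous position with greedy acceptance", {
  b <- rhdao_bounds(-5, 5, 3)
  sphere <- function(y) sum(y^2)
  pos <- c(2, -3, 1)
  up <- rhso_leader_update(pos, sphere(pos), sphere, b, l1 = 1)
  expect_equal(up$position, pos)                       # identity at l1 = 1
  up <- rhso_leader_update(pos, sphere(pos), sphere, b, l1 = 0)
  expect_equal(up$position, c(0, 0, 0))                # origin at l1 = 0
  # greedy: a worse proposal is rejected
  away <- function(y) sum((y - 2)^2)
  up <- rhso_leader_update(c(2, 2, 2), away(c(2, 2, 2)), away, b, l1 = 0)
  expect_equal(up$position, c(2, 2, 2))
  expect_false(up$accepted)
})

test_that("member update follows the circular-motion contraction", {
  b <- rhdao_bounds(-5, 5, 2)
  sphere <- function(y) sum(y^2)
  pos <- c(3, -2)
  up <- rhso_member_update(pos, sphere(pos), sphere, b, s2 = 0)
  expect_equal(up$position, pos)                       # circle = 0 identity
  up <- rhso_member_update(pos, sphere(pos), sphere, b, s2 = 1)
  expect_equal(up$position, c(0, 0))                   # full contraction
})

test_that("circular-motion radius equals |s2| identically", {
  for (a in seq(0, 360, by = 15)) {
    expect_equal(rhso_circle(0.5, a), 0.5, tolerance = 1e-14)
  }
  set.seed(42)
  s2 <- runif(1000); ang <- runif(1000, 0, 360)
  err <- abs(vapply(seq_len(1000),
                    function(i) rhso_circle(s2[i], ang[i]), numeric(1)) - s2)
  expect_lt(max(err), 1e-12)
})

test_that("dandelion seed counts are fitness-proportional with clamping", {
  expect_equal(da_seed_count(1, 1, 9, min_seeds = 2, max_seeds = 10), 10)
  expect_equal(da_seed_count(9, 1, 9, min_seeds = 2, max_seeds = 10), 2)
  expect_equal(da_seed_count(5, 1, 9, min_seeds = 2, max_seeds = 10), 5)
})

test_that("assistant radius: first-generation diameter, weighted decay, floor", {
  b <- rhdao_bounds(0, 255, 2)
  expect_equal(da_assistant_radius(NA, 0.5, 1, 1, first_iter = TRUE, b), 255)
  expect_equal(da_assistant_radius(10, 0.5, 3, 1, first_iter = FALSE, b), 7)
  r <- da_assistant_radius(10, 0, 2, 2, first_iter = FALSE, b)
  expect_equal(r, 1e-6 * 255)                          # floored, never zero
})

test_that("core radius grows on improvement and withers otherwise", {
  b <- rhdao_bounds(-5, 5, 4)
  expect_equal(da_core_radius(NA, FALSE, TRUE, bounds = b), 10)
  expect_equal(da_core_radius(10, TRUE, FALSE, f = 1.1, bounds = b), 11)
  expect_equal(da_core_radius(10, FALSE, FALSE, v = 0.8, bounds = b), 8)
})

test_that("optimizer finds a 1-D quadratic optimum reliably", {
  hits <- 0L
  for (s in 1:20) {
    r <- rhdao_optimize(function(y) (y - 3)^2, rhdao_bounds(0, 10, 1),
                        optimizer_config(seed = s))
    hits <- hits + (abs(r$best_position - 3) < 0.1)
  }
  expect_gte(hits, 18L)
})

test_that("optimizer history is non-increasing and the run is deterministic", {
  cfg <- optimizer_config(seed = 11)
  a <- rhdao_optimize(function(y) sum(y^2), rhdao_bounds(-5, 5, 3), cfg)
  b <- rhdao_optimize(function(y) sum(y^2), rhdao_bounds(-5, 5, 3), cfg)
  expect_identical(a$best_position, b$best_position)
  expect_identical(a$history, b$history)
  expect_false(is.unsorted(rev(a$history$best_fitness)))
})

test_that("every evaluated position stays inside the bounds", {
  lo <- c(-1, 0, 2); hi <- c(1, 3, 5)
  seen_bad <- FALSE
  instrumented <- function(y) {
    if (any(y < lo - 1e-12) || any(y > hi + 1e-12)) seen_bad <<- TRUE
    sum((y - c(0, 1, 3))^2)
  }
  rhdao_optimize(instrumented, rhdao_bounds(lo, hi, 3),
                 optimizer_config(seed = 2, max_iterations = 10))
  expect_false(seen_bad)
})

test_that("degenerate constant fitness runs entirely on the dandelion branch", {
  r <- rhdao_optimize(function(y) 5, rhdao_bounds(0, 1, 2),
                      optimizer_config(seed = 1, max_iterations = 5))
  expect_equal(r$best_fitness, 5)
  expect_true(all(r$history$rhso_updates == 0))  # all angles 0 -> DA
})

test_that("pure ablation modes exercise only their own branch", {
  rs <- rhdao_optimize(function(y) sum(y^2), rhdao_bounds(-5, 5, 2),
                       optimizer_config(seed = 2, mode = "rhso",
                                        max_iterations = 8))
  expect_true(all(rs$history$da_updates == 0))
  da <- rhdao_optimize(function(y) sum(y^2), rhdao_bounds(-5, 5, 2),
                       optimizer_config(seed = 2, mode = "da",
                                        max_iterations = 8))
  expect_true(all(da$history$rhso_updates == 0))
})

test_that("non-finite fitness aborts with a diagnostic naming the position", {
  expect_error(
    rhdao_optimize(function(y) if (y[1] > 0.5) NaN else sum(y^2),
                   rhdao_bounds(0, 1, 1),
                   optimizer_config(seed = 1, max_iterations = 3)),
    "non-finite fitness at position")
})

test_that("configuration invariants are enforced", {
  expect_error(optimizer_config(growth_factor = 1.2), "growth_factor")
  expect_error(optimizer_config(withering_factor = 0.7), "withering_factor")
  expect_error(optimizer_config(min_seeds = 5, max_seeds = 3))
  expect_error(rhdao_bounds(c(0, 1), c(1, 1)), "lower < upper")
})
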
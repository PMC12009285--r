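#' Box bounds for the optimizer
#'
#' @param lower,upper numeric vectors of equal length with `lower < upper`
#'   element-wise. Scalars are recycled to `dim`.
#' @param dim problem dimension (only needed when `lower`/`upper` are scalars).
#' @return a `rhdao_bounds` object.
#' @examples
#' rhdao_bounds(-5, 5, dim = 5)
#' @export
rhdao_bounds <- function(lower, upper, dim = max(length(lower), length(upper))) {
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (dim < 1L) stop("`dim` must be >= 1", call. = FALSE)
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (!all(lower < upper)) stop("need lower < upper element-wise", call. = FALSE)
  structure(list(lower = lower, upper = upper, dim = dim),
            class = "rhdao_bounds")
}

#' Optimizer configuration
#'
#' Controls the hybrid rock-hyrax/dandelion optimizer. Defaults follow the
#' method's stated settings: 25 iterations, a population of 30, dandelion seed
#' counts between 2 and 10, growth factor in `[1, 1.1]` and withering factor
#' in `[0.8, 1)`.
#'
#' @param population_size number of candidates per generation.
#' @param max_iterations number of generations.
#' @param seed integer RNG seed; the whole run is deterministic given it.
#' @param min_seeds,max_seeds dandelion seed-count limits.
#' @param growth_factor core-dandelion radius growth `f`, in `[1, 1.1]`.
#' @param withering_factor core-dandelion radius withering `v`, in `[0.8, 1)`.
#' @param mode `"rhdao"` (angle-routed hybrid), `"rhso"` or `"da"` (pure
#'   single-strategy ablation modes).
#' @param recentered logical; if `TRUE` the swarm member contraction is applied
#'   to the offset from the leader instead of to the raw position (off by
#'   default; the literal rule contracts toward the origin).
#' @return an `optimizer_config` list.
#' @export
optimizer_config <- function(population_size = 30L, max_iterations = 25L,
                             seed = 1L, min_seeds = 2L, max_seeds = 10L,
                             growth_factor = 1.05, withering_factor = 0.9,
                             mode = c("rhdao", "rhso", "da"),
                             recentered = FALSE) {
  mode <- match.arg(mode)
  stopifnot(population_size >= 1, max_iterations >= 1,
            min_seeds >= 1, max_seeds >= min_seeds)
  if (growth_factor < 1 || growth_factor > 1.1) {
    stop("`growth_factor` must be in [1, 1.1]", call. = FALSE)
  }
  if (withering_factor < 0.8 || withering_factor >= 1) {
    stop("`withering_factor` must be in [0.8, 1)", call. = FALSE)
  }
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 min_seeds = as.integer(min_seeds),
                 max_seeds = as.integer(max_seeds),
                 growth_factor = growth_factor,
                 withering_factor = withering_factor,
                 mode = mode, recentered = recentered),
            class = "optimizer_config")
}

#' Normalized fitness angle
#'
#' Maps a candidate's fitness onto `[0, 360]` degrees relative to the best and
#' worst fitness in the population: `angle = (CF - BF) / (WF - BF) * 360`.
#' The angle decides which update family handles the candidate (see
#' [route_update()]). A degenerate population (`WF == BF`) yields 0.
#'
#' @param cf current candidate fitness.
#' @param bf,wf best and worst population fitness (`wf >= bf`).
#' @return angle in degrees, clamped to `[0, 360]`.
#' @examples
#' compute_angle(3, 1, 5) # 180
#' @export
compute_angle <- function(cf, bf, wf) {
  if (!all(is.finite(c(cf, bf, wf)))) {
    stop("fitness values must be finite", call. = FALSE)
  }
  if (wf < bf) stop("need wf >= bf", call. = FALSE)
  if (wf == bf) return(0)
  clamp((cf - bf) / (wf - bf) * 360, 0, 360)
}

#' Route a candidate by its angle
#'
#' Swarm (RHSO) updates handle a candidate strictly above 180 degrees (the
#' worse half of the population); dandelion sowing handles the rest,
#' including the boundary.
#'
#' @param angle degrees in `[0, 360]`.
#' @return `"RHSO"` or `"DA"`.
#' @export
route_update <- function(angle) {
  stopifnot(is.finite(angle), angle >= 0, angle <= 360)
  if (angle > 180) "RHSO" else "DA"
}

#' Perturb an angle within the clamped range
#'
#' Each generation the routing angle is jittered by a uniform offset and
#' clamped back into `[0, 360]` (values above 360 are set to 360, below 0 to
#' 0). The default offset range is +/- 36 degrees, 10% of the angle range.
#'
#' @param angle degrees.
#' @param delta offset to add; by default drawn uniformly from
#'   `[offset_low, offset_high]`.
#' @param offset_low,offset_high bounds of the random offset.
#' @return perturbed angle in `[0, 360]`.
#' @export
perturb_angle <- function(angle, delta = stats::runif(1, offset_low, offset_high),
                          offset_low = -36, offset_high = 36) {
  clamp(angle + delta, 0, 360)
}

#' Rock-hyrax circular-motion radius
#'
#' `circle = sqrt((s2 cos a)^2 + (s2 sin a)^2)`, which collapses to `|s2|`
#' identically; kept as the explicit two-component form so the identity is
#' testable.
#'
#' @param s2 radius scalar in `[0, 1]`.
#' @param move_angle move angle in degrees.
#' @return the circular-motion radius.
#' @export
rhso_circle <- function(s2, move_angle) {
  m1 <- s2 * cospi(move_angle / 180)
  m2 <- s2 * sinpi(move_angle / 180)
  sqrt(m1^2 + m2^2)
}

#' Rock-hyrax leader update
#'
#' Proposes `l1 * position` (a random contraction of the leader's previous
#' position), clamps to bounds, and keeps the better of proposal and
#' incumbent (greedy acceptance).
#'
#' @param position,fitness_value the incumbent leader.
#' @param fitness objective function (minimized).
#' @param bounds a [rhdao_bounds()].
#' @param l1 contraction factor, by default uniform on `[0, 1]`.
#' @return list with `position`, `fitness`, and `accepted`.
#' @export
rhso_leader_update <- function(position, fitness_value, fitness, bounds,
                               l1 = stats::runif(1)) {
  prop <- clamp(l1 * position, bounds$lower, bounds$upper)
  fp <- fitness(prop)
  if (fp < fitness_value) {
    list(position = prop, fitness = fp, accepted = TRUE)
  } else {
    list(position = position, fitness = fitness_value, accepted = FALSE)
  }
}

#' Rock-hyrax member update
#'
#' Member position is contracted by the circular-motion radius:
#' `y <- y - circle * y = (1 - circle) * y`. With `recentered = TRUE` the
#' contraction is applied to the offset from the leader instead:
#' `y <- leader + (1 - circle) * (y - leader)`. Greedy acceptance.
#'
#' @inheritParams rhso_leader_update
#' @param leader_position leader position (used by the recentered variant).
#' @param s2 radius scalar, default uniform `[0, 1]`.
#' @param move_angle move angle in degrees, default uniform `[0, 360]`.
#' @param recentered logical.
#' @return list with `position`, `fitness`, and `accepted`.
#' @export
rhso_member_update <- function(position, fitness_value, fitness, bounds,
                               leader_position = NULL,
                               s2 = stats::runif(1),
                               move_angle = stats::runif(1, 0, 360),
                               recentered = FALSE) {
  circle <- rhso_circle(s2, move_angle)
  prop <- if (recentered && !is.null(leader_position)) {
    leader_position + (1 - circle) * (position - leader_position)
  } else {
    position - circle * position
  }
  prop <- clamp(prop, bounds$lower, bounds$upper)
  fp <- fitness(prop)
  if (fp < fitness_value) {
    list(position = prop, fitness = fp, accepted = TRUE)
  } else {
    list(position = position, fitness = fitness_value, accepted = FALSE)
  }
}

#' Dandelion seed count
#'
#' Fitter dandelions sow more seeds:
#' `n = floor(max_seeds * (h_max - h_y + eps) / (h_max - h_min + eps))`,
#' never fewer than `min_seeds`. `eps` guards the degenerate population where
#' all fitnesses coincide.
#'
#' @param h_y this dandelion's fitness.
#' @param h_min,h_max population extremes (`h_min <= h_y <= h_max`).
#' @param min_seeds,max_seeds seed-count limits.
#' @param epsilon small positive constant; defaults to the smallest positive
#'   normalized double.
#' @return integer seed count.
#' @export
da_seed_count <- function(h_y, h_min, h_max, min_seeds = 2L, max_seeds = 10L,
                          epsilon = .Machine$double.xmin) {
  stopifnot(h_min <= h_y, h_y <= h_max, max_seeds >= min_seeds, min_seeds >= 1)
  n <- floor(max_seeds * (h_max - h_y + epsilon) / (h_max - h_min + epsilon))
  as.integer(max(n, min_seeds))
}

#' Assistant-dandelion sowing radius
#'
#' First generation: the search-space diameter `max(upper - lower)`. After
#' that a weighted decay plus the gap between the core dandelion's and this
#' dandelion's position infinity-norms:
#' `omega * prev + (||y_core||_inf - ||y_self||_inf)`, floored at a small
#' positive fraction of the range so the radius never collapses to zero.
#'
#' @param prev_radius previous radius.
#' @param omega weight factor in `[0, 1]` (decays with evaluations used).
#' @param core_norm,self_norm infinity-norms of the core and this dandelion.
#' @param first_iter logical.
#' @param bounds a [rhdao_bounds()].
#' @param floor_frac radius floor as a fraction of `max(upper - lower)`.
#' @return positive radius.
#' @export
da_assistant_radius <- function(prev_radius, omega, core_norm, self_norm,
                                first_iter, bounds, floor_frac = 1e-6) {
  rng <- max(bounds$upper - bounds$lower)
  if (first_iter) return(rng)
  max(omega * prev_radius + (core_norm - self_norm), floor_frac * rng)
}

#' Core-dandelion sowing radius
#'
#' First generation: the search-space diameter. Afterwards the radius grows by
#' `f` when the core's fitness improved this generation and withers by `v`
#' otherwise.
#'
#' @param prev_radius previous radius.
#' @param improved logical; did the core fitness strictly improve.
#' @param first_iter logical.
#' @param f growth factor in `[1, 1.1]`.
#' @param v withering factor in `[0.8, 1)`.
#' @param bounds a [rhdao_bounds()].
#' @return positive radius.
#' @export
da_core_radius <- function(prev_radius, improved, first_iter, f = 1.05,
                           v = 0.9, bounds) {
  if (first_iter) return(max(bounds$upper - bounds$lower))
  if (improved) prev_radius * f else prev_radius * v
}

#' Hybrid rock-hyrax/dandelion optimization
#'
#' Bounded derivative-free minimization. Each generation every candidate is
#' assigned a normalized fitness angle ([compute_angle()]), jittered
#' ([perturb_angle()]), and routed ([route_update()]): angles above 180 take a
#' rock-hyrax swarm step (leader contraction or circular-motion member
#' contraction, greedy), the rest sow dandelion seeds (fitness-proportional
#' seed counts inside adaptive radii). The next generation is the elitist
#' truncation of parents and seeds, so the best-so-far history is
#' non-increasing. Pure `"rhso"` and `"da"` modes bypass the routing for
#' ablation.
#'
#' @param fitness function mapping a position vector to a finite scalar
#'   (minimized; wrap with negation to maximize).
#' @param bounds a [rhdao_bounds()].
#' @param config an [optimizer_config()].
#' @param init optional matrix of initial positions (rows), injected into the
#'   initial population (useful to guarantee a baseline configuration is
#'   never lost thanks to elitism).
#' @return list with `best_position`, `best_fitness`, `history` (tibble with
#'   `iteration`, `best_fitness`, `rhso_updates`, `da_updates`), and
#'   `evaluations`.
#' @examples
#' res <- rhdao_optimize(function(y) sum((y - 3)^2), rhdao_bounds(0, 10, 1),
#'                       optimizer_config(seed = 7))
#' res$best_position
#' @export
rhdao_optimize <- function(fitness, bounds, config = optimizer_config(),
                           init = NULL) {
  stopifnot(inherits(bounds, "rhdao_bounds"), inherits(config, "optimizer_config"))
  set.seed(config$seed)
  d <- bounds$dim
  np <- config$population_size
  he <- 0L
  he_max <- np * config$max_iterations * max(config$max_seeds, 1L)

  # evaluate with bound/finiteness checks; shield the optimizer's RNG stream
  # from any randomness the objective itself consumes
  evalf <- function(pos) {
    st <- .Random.seed
    v <- fitness(pos)
    assign(".Random.seed", st, envir = globalenv())
    he <<- he + 1L
    if (length(v) != 1L || !is.finite(v)) {
      stop("non-finite fitness at position [",
           paste(signif(pos, 6), collapse = ", "), "]", call. = FALSE)
    }
    as.numeric(v)
  }

  P <- matrix(stats::runif(np * d, rep(bounds$lower, each = np),
                           rep(bounds$upper, each = np)), nrow = np)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    k <- min(nrow(init), np)
    P[seq_len(k), ] <- clamp(init[seq_len(k), , drop = FALSE],
                             rep(bounds$lower, each = k),
                             rep(bounds$upper, each = k))
  }
  fit <- apply(P, 1, evalf)
  radii <- rep(max(bounds$upper - bounds$lower), np)  # assistant radii per slot
  core_radius <- max(bounds$upper - bounds$lower)
  core_fit_prev <- NA_real_

  hist_best <- numeric(config$max_iterations)
  hist_rhso <- integer(config$max_iterations)
  hist_da <- integer(config$max_iterations)

  for (l in seq_len(config$max_iterations)) {
    bf <- min(fit); wf <- max(fit)
    leader_idx <- which.min(fit)  # lowest index on ties
    branch <- switch(config$mode,
      rhso = rep("RHSO", np),
      da = rep("DA", np),
      rhdao = vapply(seq_len(np), function(i) {
        route_update(perturb_angle(compute_angle(fit[i], bf, wf)))
      }, character(1))
    )
    hist_rhso[l] <- sum(branch == "RHSO")
    hist_da[l] <- sum(branch == "DA")

    # --- swarm branch: in-place greedy updates -------------------------------
    for (i in which(branch == "RHSO")) {
      upd <- if (i == leader_idx) {
        rhso_leader_update(P[i, ], fit[i], evalf, bounds)
      } else {
        rhso_member_update(P[i, ], fit[i], evalf, bounds,
                           leader_position = P[leader_idx, ],
                           recentered = config$recentered)
      }
      P[i, ] <- upd$position
      fit[i] <- upd$fitness
    }

    # --- dandelion branch: sow seeds, elitist truncation ---------------------
    da_set <- which(branch == "DA")
    seed_pos <- NULL; seed_fit <- NULL; seed_rad <- NULL
    if (length(da_set) > 0L) {
      h_min <- min(fit[da_set]); h_max <- max(fit[da_set])
      core <- da_set[which.min(fit[da_set])]
      omega <- clamp(1 - he / he_max, 0, 1)
      improved <- is.finite(core_fit_prev) && fit[core] < core_fit_prev
      core_radius <- da_core_radius(core_radius, improved, first_iter = (l == 1L),
                                    f = config$growth_factor,
                                    v = config$withering_factor, bounds = bounds)
      core_fit_prev <- fit[core]
      core_norm <- max(abs(P[core, ]))
      for (i in da_set) {
        if (i == core) {
          B <- core_radius
        } else {
          radii[i] <- da_assistant_radius(radii[i], omega, core_norm,
                                          max(abs(P[i, ])),
                                          first_iter = (l == 1L),
                                          bounds = bounds)
          B <- radii[i]
        }
        n <- da_seed_count(fit[i], h_min, h_max,
                           config$min_seeds, config$max_seeds)
        off <- matrix(stats::runif(n * d, -B, B), nrow = n)
        sp <- clamp(sweep(off, 2, P[i, ], "+"),
                    rep(bounds$lower, each = n), rep(bounds$upper, each = n))
        sf <- apply(sp, 1, evalf)
        seed_pos <- rbind(seed_pos, sp)
        seed_fit <- c(seed_fit, sf)
        seed_rad <- c(seed_rad, rep(radii[i], n))
      }
    }

    if (!is.null(seed_pos)) {
      all_pos <- rbind(P, seed_pos)
      all_fit <- c(fit, seed_fit)
      all_rad <- c(radii, seed_rad)
      keep <- order(all_fit)[seq_len(np)]  # stable: parents win ties
      P <- all_pos[keep, , drop = FALSE]
      fit <- all_fit[keep]
      radii <- all_rad[keep]
    }
    hist_best[l] <- min(fit)
  }

  best <- which.min(fit)
  list(best_position = P[best, ],
       best_fitness = fit[best],
       history = tibble::tibble(iteration = seq_len(config$max_iterations),
                                best_fitness = hist_best,
                                rhso_updates = hist_rhso,
                                da_updates = hist_da),
       evaluations = he)
}
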
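#' Binary thresholding
#'
#' Pixel-wise classification against a scalar threshold `I`: intensity below
#' `I` maps to 0 (background), at or above `I` maps to 1 (foreground — the
#' hot/hyperthermic side). Deterministic and exact.
#'
#' @param img a `gray_image` or matrix.
#' @param threshold scalar threshold `I`.
#' @return 0/1 integer matrix of the same shape.
#' @examples
#' apply_threshold(matrix(c(100, 50, 200, 220), 2, 2), 150)
#' @export
apply_threshold <- function(img, threshold) {
  img <- as_gray_image(img)
  m <- (as.matrix(img) >= threshold) * 1L
  dim(m) <- dim(img)
  m
}

# Between-class variance from a per-level histogram. `levels` are the gray
# values (0..maxg), `counts` their frequencies.
.otsu_from_hist <- function(counts, levels, threshold) {
  total <- sum(counts)
  lo <- levels < threshold
  w0 <- sum(counts[lo]) / total
  w1 <- 1 - w0
  if (w0 == 0 || w1 == 0) return(0)
  mu0 <- sum(counts[lo] * levels[lo]) / sum(counts[lo])
  mu1 <- sum(counts[!lo] * levels[!lo]) / sum(counts[!lo])
  w0 * w1 * (mu0 - mu1)^2
}

#' Otsu between-class variance of a threshold
#'
#' The unsupervised segmentation objective: the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` of the two intensity classes induced by the
#' threshold. Higher is better; an empty class scores 0.
#'
#' @param img a `gray_image` or matrix with at least two distinct levels.
#' @param threshold scalar threshold.
#' @return non-negative between-class variance.
#' @export
otsu_objective <- function(img, threshold) {
  img <- as_gray_image(img)
  counts <- tabulate(as.matrix(img) + 1L, nbins = max_gray(img) + 1L)
  if (sum(counts > 0) < 2L) stop("degenerate histogram", call. = FALSE)
  .otsu_from_hist(counts, 0:max_gray(img), threshold)
}

#' Mask overlap coefficients
#'
#' Dice `2|A&B| / (|A| + |B|)` and Jaccard `|A&B| / |A or B|` for two binary
#' masks of equal shape; both defined as 1 when both masks are empty.
#'
#' @param pred,ref 0/1 matrices of equal shape.
#' @return tibble with columns `dice` and `jaccard`.
#' @export
mask_overlap <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("mask shapes differ", call. = FALSE)
  stopifnot(all(pred %in% c(0, 1)), all(ref %in% c(0, 1)))
  inter <- sum(pred == 1 & ref == 1)
  sa <- sum(pred); sb <- sum(ref)
  uni <- sa + sb - inter
  tibble::tibble(
    dice = if (sa + sb == 0) 1 else 2 * inter / (sa + sb),
    jaccard = if (uni == 0) 1 else inter / uni
  )
}

#' Optimizer-driven optimal binary thresholding
#'
#' Chooses the threshold by running the hybrid optimizer ([rhdao_optimize()])
#' over the 1-D threshold space against a pluggable fitness: unsupervised
#' Otsu between-class variance (default) or supervised Dice against a
#' reference mask. Candidate thresholds are rounded to integer gray levels and
#' memoized; when the nominal evaluation budget
#' (`population_size * max_iterations`) covers the whole integer grid, any
#' unvisited levels are swept afterwards, so the returned threshold is
#' guaranteed to attain the exhaustive-search optimum.
#'
#' @param img a `gray_image` or matrix.
#' @param fitness `"otsu"` or `"dice"`.
#' @param reference reference 0/1 mask (required for `"dice"`).
#' @param config an [optimizer_config()].
#' @param bounds threshold search range `c(lo, hi)`; defaults to the full gray
#'   range. `hot_range = TRUE` selects the `[200, 255]` preset used for
#'   8-bit clinical thermograms, where lesions occupy the top of the scale.
#' @param hot_range logical preset switch.
#' @return list with integer `threshold`, `mask`, `fitness_value` (on the
#'   maximization scale), and the optimizer `history`.
#' @export
optimal_threshold <- function(img, fitness = c("otsu", "dice"),
                              reference = NULL, config = optimizer_config(),
                              bounds = NULL, hot_range = FALSE) {
  img <- as_gray_image(img)
  fitness <- match.arg(fitness)
  maxg <- max_gray(img)
  if (is.null(bounds)) bounds <- if (hot_range) c(200, 255) else c(0, maxg)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])

  counts <- tabulate(as.matrix(img) + 1L, nbins = maxg + 1L)
  if (fitness == "otsu" && sum(counts > 0) < 2L) {
    stop("degenerate histogram", call. = FALSE)
  }
  if (fitness == "dice") {
    if (is.null(reference)) stop("`reference` mask required", call. = FALSE)
    if (!all(dim(reference) == dim(img))) {
      stop("reference mask shape differs from image", call. = FALSE)
    }
  }
  levels <- 0:maxg
  score_int <- function(ti) {                      # maximization scale
    if (fitness == "otsu") {
      .otsu_from_hist(counts, levels, ti)
    } else {
      mask_overlap(apply_threshold(img, ti), reference)$dice
    }
  }
  cache <- new.env(parent = emptyenv())
  obj <- function(pos) {                           # minimized by the optimizer
    ti <- as.character(round(pos[1]))
    if (is.null(cache[[ti]])) cache[[ti]] <- score_int(round(pos[1]))
    -cache[[ti]]
  }
  res <- rhdao_optimize(obj, rhdao_bounds(bounds[1], bounds[2], 1L), config)

  grid <- seq(ceiling(bounds[1]), floor(bounds[2]))
  budget <- config$population_size * config$max_iterations
  if (budget >= length(grid)) {
    for (ti in grid) {
      key <- as.character(ti)
      if (is.null(cache[[key]])) cache[[key]] <- score_int(ti)
    }
  }
  keys <- ls(cache)
  vals <- vapply(keys, function(k) cache[[k]], numeric(1))
  best <- which.max(vals)
  thr <- as.integer(keys[best])
  list(threshold = thr,
       mask = apply_threshold(img, thr),
       fitness_value = vals[[best]],
       history = res$history)
}
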
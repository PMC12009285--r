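#' Stacked weighted feature fusion
#'
#' Element-wise weighted sum of the three branch feature vectors (or matrices
#' with images as rows): `SF = W1*f1 + W2*f2 + W3*f3`. Setting
#' `literal_typo = TRUE` instead applies the second weight to the third
#' branch (`W1*f1 + W2*f3 + W3*f3`) — a transcription defect this fusion is
#' sometimes stated with — for forensic comparison against implementations
#' that contain it.
#'
#' @param f1,f2,f3 numeric vectors (or matrices) of equal shape.
#' @param weights numeric `c(W1, W2, W3)`, each typically in `[0, 1]` (not
#'   required to sum to 1).
#' @param literal_typo logical; see above.
#' @return the fused vector/matrix `SF`.
#' @examples
#' fuse(c(1, 2), c(3, 4), c(5, 6), c(0.5, 0.3, 0.2)) # 2.4 3.4
#' @export
fuse <- function(f1, f2, f3, weights, literal_typo = FALSE) {
  if (length(f1) != length(f2) || length(f2) != length(f3)) {
    stop("feature lengths differ", call. = FALSE)
  }
  stopifnot(length(weights) == 3L, all(is.finite(weights)))
  if (literal_typo) {
    weights[1] * f1 + weights[2] * f3 + weights[3] * f3
  } else {
    weights[1] * f1 + weights[2] * f2 + weights[3] * f3
  }
}

#' Optimize the three fusion weights
#'
#' Runs the hybrid optimizer over `[0, 1]^3` maximizing a user-supplied
#' evaluator (weights -> validation accuracy, negated internally since the
#' optimizer minimizes). The equal-weight baseline `(1/3, 1/3, 1/3)` is
#' injected into the initial population, so elitism guarantees the returned
#' weights never score below it. The default evaluator performs a stratified
#' train/validation split, fits the ensemble heads on fused training
#' features, and scores validation accuracy.
#'
#' @param f1,f2,f3 per-image feature matrices (rows = images).
#' @param labels factor (or coercible) class labels, at least two classes.
#' @param evaluator optional function `weights -> accuracy`; overrides the
#'   default head-based evaluator.
#' @param config an [optimizer_config()].
#' @param split_frac fraction of samples used for training in the default
#'   evaluator's stratified split.
#' @return list with `weights` (named W1..W3), `accuracy` (evaluator value at
#'   the optimum), and the optimizer `history`.
#' @export
optimize_fusion_weights <- function(f1, f2, f3, labels = NULL,
                                    evaluator = NULL,
                                    config = optimizer_config(),
                                    split_frac = 0.7) {
  if (is.null(evaluator)) {
    labels <- as.factor(labels)
    if (nlevels(droplevels(labels)) < 2L) {
      stop("need at least two classes", call. = FALSE)
    }
    sp <- stratified_split(labels, c(split_frac, 1 - split_frac),
                           seed = config$seed)
    evaluator <- function(w) {
      SF <- fuse(f1, f2, f3, w)
      heads <- fit_heads(SF[sp[[1]], , drop = FALSE], labels[sp[[1]]],
                         seed = config$seed)
      pred <- predict_ensemble(heads, SF[sp[[2]], , drop = FALSE])
      mean(pred$class == labels[sp[[2]]])
    }
  }
  res <- rhdao_optimize(function(w) -evaluator(w),
                        rhdao_bounds(0, 1, 3L), config,
                        init = rbind(rep(1 / 3, 3)))
  list(weights = stats::setNames(res$best_position, c("W1", "W2", "W3")),
       accuracy = -res$best_fitness,
       history = res$history)
}

#' Stratified index split
#'
#' Deterministically partitions sample indices into groups with (approximately)
#' the requested fractions within every class label.
#'
#' @param labels factor of class labels.
#' @param fracs numeric fractions summing to 1 (e.g. `c(0.5, 0.25, 0.25)`).
#' @param seed integer seed.
#' @return list of integer index vectors, one per fraction.
#' @export
stratified_split <- function(labels, fracs, seed = 1L) {
  stopifnot(abs(sum(fracs) - 1) < 1e-8)
  labels <- as.factor(labels)
  out <- vector("list", length(fracs))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    n <- length(idx)
    sizes <- diff(round(cumsum(c(0, fracs)) * n))
    at <- cumsum(c(0, sizes))
    for (g in seq_along(fracs)) {
      out[[g]] <- c(out[[g]], idx[seq_len(sizes[g]) + at[g]])
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  lapply(out, sort)
}
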
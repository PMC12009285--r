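# Ensemble of three small feed-forward classifier heads over the fused
# feature, with a higher-score (sum-of-scores, argmax) decision rule and
# metaheuristic tuning of the fusion weights and head hyperparameters.

.activations <- list(
  relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
  sigmoid = list(f = function(z) 1 / (1 + exp(-z)), df = function(z, a) a * (1 - a)),
  tanh = list(f = tanh, df = function(z, a) 1 - a^2)
)

# One-hidden-layer MLP with softmax output, trained by full-batch gradient
# descent with a fixed step schedule. Deterministic given `seed`.
.fit_mlp <- function(X, y, hidden, activation, epochs, seed, lr = 0.5) {
  y <- as.factor(y)
  K <- nlevels(y)
  n <- nrow(X); d <- ncol(X)
  act <- .activations[[activation]]
  ctr <- colMeans(X)
  scl <- pmax(apply(X, 2, stats::sd), 1e-8)
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1

  .with_fixed_rng(seed, function() {
    W1 <- matrix(stats::rnorm(hidden * d, sd = 1 / sqrt(d)), hidden, d)
    b1 <- stats::rnorm(hidden, sd = 0.01)
    W2 <- matrix(stats::rnorm(K * hidden, sd = 1 / sqrt(hidden)), K, hidden)
    b2 <- rep(0, K)
    for (ep in seq_len(epochs)) {
      Z1 <- tcrossprod(Xs, W1) + matrix(b1, n, hidden, byrow = TRUE)
      A1 <- act$f(Z1)
      Z2 <- tcrossprod(A1, W2) + matrix(b2, n, K, byrow = TRUE)
      Z2 <- Z2 - apply(Z2, 1, max)
      P <- exp(Z2); P <- P / rowSums(P)
      G2 <- (P - Y) / n
      dW2 <- crossprod(G2, A1)
      db2 <- colSums(G2)
      G1 <- (G2 %*% W2) * act$df(Z1, A1)
      dW1 <- crossprod(G1, Xs)
      db1 <- colSums(G1)
      step <- lr / (1 + ep / 50)
      W2 <- W2 - step * dW2; b2 <- b2 - step * db2
      W1 <- W1 - step * dW1; b1 <- b1 - step * db1
    }
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = ctr,
                   scale = scl, activation = activation, levels = levels(y)),
              class = "thermofuse_mlp")
  })
}

.predict_mlp <- function(model, X) {
  X <- matrix(X, ncol = length(model$center))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  act <- .activations[[model$activation]]
  A1 <- act$f(tcrossprod(Xs, model$W1) +
                matrix(model$b1, nrow(Xs), length(model$b1), byrow = TRUE))
  Z2 <- tcrossprod(A1, model$W2) +
    matrix(model$b2, nrow(Xs), length(model$b2), byrow = TRUE)
  Z2 <- Z2 - apply(Z2, 1, max)
  P <- exp(Z2); P <- P / rowSums(P)
  colnames(P) <- model$levels
  P
}

#' Hyperparameter search space
#'
#' Bounds of the tuned genes: the three fusion weights in `[0, 1]`, the epoch
#' count in `[50, 100]`, the hidden-neuron count in `[5, 255]`, and a
#' categorical activation gene decoded by flooring over
#' `{relu, sigmoid, tanh}`.
#'
#' @param weights,epochs,hidden two-element numeric ranges.
#' @param activations character vector of candidate activations.
#' @return an `hp_space` list of ranges.
#' @export
hp_space <- function(weights = c(0, 1), epochs = c(50, 100),
                     hidden = c(5, 255),
                     activations = c("relu", "sigmoid", "tanh")) {
  stopifnot(all(weights >= 0), all(weights <= 1), diff(epochs) >= 0,
            diff(hidden) >= 0, all(activations %in% names(.activations)))
  structure(list(weights = weights, epochs = epochs, hidden = hidden,
                 activations = activations), class = "hp_space")
}

# decode a real gene vector into a hyperparameter list
.decode_hp <- function(g, space) {
  act_i <- min(floor(g[6]) + 1L, length(space$activations))
  list(weights = g[1:3],
       epochs = as.integer(round(clamp(g[4], space$epochs[1], space$epochs[2]))),
       hidden = as.integer(round(clamp(g[5], space$hidden[1], space$hidden[2]))),
       activation = space$activations[act_i])
}

#' Fit the three ensemble classifier heads
#'
#' Trains three small one-hidden-layer feed-forward heads (tagged after the
#' three backbone families they stand in for) on the fused feature matrix,
#' each with a head-specific seed derived from the master seed, so the whole
#' fit is deterministic.
#'
#' @param X fused feature matrix (rows = samples).
#' @param labels class labels (factor or coercible), at least one sample.
#' @param hidden hidden-neuron count (5..255).
#' @param activation `"relu"`, `"sigmoid"` or `"tanh"`.
#' @param epochs training passes (50..100 in the tuned space).
#' @param seed master seed.
#' @return list of three fitted heads with tags `vgg_like`, `resnet_like`,
#'   `densenet_like`.
#' @export
fit_heads <- function(X, labels, hidden = 64L, activation = "relu",
                      epochs = 75L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(nrow(X) == length(labels))
  tags <- c("vgg_like", "resnet_like", "densenet_like")
  heads <- lapply(seq_along(tags), function(k) {
    .fit_mlp(X, labels, hidden = hidden, activation = activation,
             epochs = epochs, seed = seed + 1009L * k)
  })
  names(heads) <- tags
  heads
}

#' Score a sample set with every head
#'
#' @param heads output of [fit_heads()].
#' @param X feature matrix.
#' @return list of per-head score matrices (rows sum to 1).
#' @export
score_heads <- function(heads, X) lapply(heads, function(h) .predict_mlp(h, X))

#' Higher-score ensemble decision
#'
#' Aggregates the per-head class-score vectors by element-wise summation and
#' predicts the argmax class; exact ties resolve to the lowest class index.
#' A `max`-rule variant (aggregate by element-wise maximum) is available.
#'
#' @param scores list of per-head score vectors (or matrices with samples as
#'   rows), all with the same class count.
#' @param rule `"sum"` (default) or `"max"`.
#' @return list with `aggregate` (matrix) and `class` (predicted labels, or
#'   indices when scores are unnamed).
#' @examples
#' decide(list(c(0.9, 0.1), c(0.4, 0.6), c(0.45, 0.55)))$class
#' @export
decide <- function(scores, rule = c("sum", "max")) {
  rule <- match.arg(rule)
  scores <- lapply(scores, function(s) if (is.matrix(s)) s else matrix(s, 1))
  nc <- vapply(scores, ncol, integer(1))
  if (length(unique(nc)) != 1L) stop("class counts differ", call. = FALSE)
  agg <- scores[[1]]
  for (s in scores[-1]) agg <- if (rule == "sum") agg + s else pmax(agg, s)
  idx <- apply(agg, 1, which.max)  # which.max: lowest index on ties
  cls <- if (!is.null(colnames(agg))) colnames(agg)[idx] else idx
  list(aggregate = agg, class = cls)
}

#' Predict with the fitted ensemble
#'
#' @param heads output of [fit_heads()].
#' @param X feature matrix.
#' @param rule aggregation rule passed to [decide()].
#' @return list with `aggregate` scores and predicted `class`.
#' @export
predict_ensemble <- function(heads, X, rule = "sum") {
  decide(score_heads(heads, X), rule = rule)
}

#' Classification accuracy
#'
#' Fraction of correct ensemble decisions, `(TP + TN) / total` in the binary
#' case and fraction correct for multi-class labels.
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy_fitness <- function(pred, truth) {
  if (length(truth) == 0L) stop("empty validation set", call. = FALSE)
  stopifnot(length(pred) == length(truth))
  mean(as.character(pred) == as.character(truth))
}

#' Jointly tune fusion weights and head hyperparameters
#'
#' Runs the hybrid optimizer over the 6-gene space (three fusion weights,
#' epochs, hidden neurons, activation index), maximizing ensemble validation
#' accuracy. The space's midpoint configuration is injected into the initial
#' population so, by elitism, the tuned result never scores below it.
#' Degenerate (zero-width) gene ranges are held fixed; if every gene is
#' fixed, that single configuration is evaluated and returned directly.
#'
#' @param f1,f2,f3 per-branch feature matrices (rows = samples).
#' @param labels class labels.
#' @param train_idx,val_idx integer index vectors of the split.
#' @param space an [hp_space()].
#' @param config an [optimizer_config()].
#' @return list with `hp` (decoded best hyperparameters), `accuracy`
#'   (validation accuracy), `heads` (refit on the training rows at the
#'   optimum), `weights`, and the optimizer `history` (NULL when the space is
#'   a single point).
#' @export
optimize_hyperparameters <- function(f1, f2, f3, labels, train_idx, val_idx,
                                     space = hp_space(),
                                     config = optimizer_config()) {
  labels <- as.factor(labels)
  lower <- c(rep(space$weights[1], 3), space$epochs[1], space$hidden[1], 0)
  act_hi <- if (length(space$activations) == 1L) 0 else
    length(space$activations) - 1e-9
  upper <- c(rep(space$weights[2], 3), space$epochs[2], space$hidden[2],
             act_hi)
  evalg <- function(g) {
    hp <- .decode_hp(g, space)
    SF <- fuse(f1, f2, f3, hp$weights)
    heads <- fit_heads(SF[train_idx, , drop = FALSE], labels[train_idx],
                       hidden = hp$hidden, activation = hp$activation,
                       epochs = hp$epochs, seed = config$seed)
    pred <- predict_ensemble(heads, SF[val_idx, , drop = FALSE])
    accuracy_fitness(pred$class, labels[val_idx])
  }
  free <- which(upper - lower > 1e-12)
  if (length(free) == 0L) {
    g <- lower
    hp <- .decode_hp(g, space)
  } else {
    mid <- (lower + upper) / 2
    obj <- function(gf) {
      g <- lower; g[free] <- gf
      -evalg(g)
    }
    res <- rhdao_optimize(obj, rhdao_bounds(lower[free], upper[free],
                                            length(free)),
                          config, init = rbind(mid[free]))
    g <- lower; g[free] <- res$best_position
    hp <- .decode_hp(g, space)
  }
  SF <- fuse(f1, f2, f3, hp$weights)
  heads <- fit_heads(SF[train_idx, , drop = FALSE], labels[train_idx],
                     hidden = hp$hidden, activation = hp$activation,
                     epochs = hp$epochs, seed = config$seed)
  pred <- predict_ensemble(heads, SF[val_idx, , drop = FALSE])
  list(hp = hp, accuracy = accuracy_fitness(pred$class, labels[val_idx]),
       heads = heads, weights = hp$weights,
       history = if (length(free) > 0L) res$history else NULL)
}
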
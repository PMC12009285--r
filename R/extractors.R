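# Three deterministic feature-extraction branches standing behind a single
# contract. Each branch mirrors the architectural idea of a deep backbone
# family (small-filter stacks / residual skips / dense connectivity + global
# average pooling) at desk scale, with a fixed seeded filter bank so that
# extraction is a pure function. Real pretrained backbones can be plugged in
# through the same contract.

# Deterministic weight construction: run `fn` under a fixed local RNG stream
# without disturbing the caller's stream.
.with_fixed_rng <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.extractor_cache <- new.env(parent = emptyenv())

.cached <- function(key, make) {
  if (is.null(.extractor_cache[[key]])) .extractor_cache[[key]] <- make()
  .extractor_cache[[key]]
}

# 2-D 'same' convolution with edge-replicate padding (k is a small
# odd-sized kernel); replication keeps constant inputs constant
.conv2same <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  H <- nrow(x); W <- ncol(x)
  ridx <- clamp(seq_len(H + 2 * ph) - ph, 1, H)
  cidx <- clamp(seq_len(W + 2 * pw) - pw, 1, W)
  xp <- x[ridx, cidx, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (k[i, j] != 0) {
        out <- out + k[i, j] * xp[i:(i + H - 1), j:(j + W - 1)]
      }
    }
  }
  out
}

# Block-mean downsample to a target grid (pads by edge replication).
.block_mean <- function(x, gr, gc) {
  H <- nrow(x); W <- ncol(x)
  bh <- ceiling(H / gr); bw <- ceiling(W / gc)
  ridx <- pmin(seq_len(bh * gr), H)
  cidx <- pmin(seq_len(bw * gc), W)
  xp <- x[ridx, cidx, drop = FALSE]
  rg <- rep(seq_len(gr), each = bh)
  cg <- rep(seq_len(gc), each = bw)
  m <- rowsum(xp, rg)                 # sum rows into gr groups
  m <- t(rowsum(t(m), cg)) / (bh * bw)
  m
}

.pool2 <- function(x) .block_mean(x, max(1L, nrow(x) %/% 2L),
                                  max(1L, ncol(x) %/% 2L))

.check_img <- function(img) {
  img <- as_gray_image(img)
  if (length(img) == 0L) stop("empty image", call. = FALSE)
  as.matrix(img) / max_gray(img)
}

# pad/trim a raw feature vector to the declared dimension via a fixed seeded
# linear projection (identity when lengths already match)
.fit_dim <- function(v, output_dim, tag) {
  if (length(v) == output_dim) return(v)
  P <- .cached(sprintf("proj_%s_%d_%d", tag, length(v), output_dim), function() {
    .with_fixed_rng(42L, function() {
      matrix(stats::rnorm(output_dim * length(v), sd = 1 / sqrt(length(v))),
             output_dim, length(v))
    })
  })
  as.numeric(P %*% v)
}

#' Branch-1 features: stacked small-filter convolution and pooling
#'
#' A VGG-style stand-in: two stages of fixed, seeded, non-negative 3x3 filter
#' banks with 2x2 mean pooling; the feature vector collects per-channel
#' statistics (mean, sd, max, min) from both stages. The non-negative bank
#' makes the response monotone in overall image brightness. Deterministic:
#' the same image always yields the same vector.
#'
#' @param img a `gray_image` or matrix.
#' @param output_dim feature-vector length (default 64).
#' @return numeric feature vector `f1` of length `output_dim`.
#' @export
extract_branch1 <- function(img, output_dim = 64L) {
  x <- .check_img(img)
  nb <- 8L
  bank <- .cached("b1_bank", function() {
    .with_fixed_rng(101L, function() {
      lapply(seq_len(nb), function(i) {
        k <- abs(matrix(stats::rnorm(9), 3, 3)); k / sum(k)
      })
    })
  })
  stats1 <- function(m) c(mean(m), stats::sd(as.vector(m)), max(m), min(m))
  feats <- numeric(0)
  maps <- lapply(bank, function(k) .conv2same(x, k))
  maps <- lapply(maps, .pool2)
  feats <- c(feats, unlist(lapply(maps, stats1)))
  maps2 <- lapply(seq_along(maps), function(i) .pool2(.conv2same(maps[[i]], bank[[i]])))
  feats <- c(feats, unlist(lapply(maps2, stats1)))
  .fit_dim(feats, output_dim, "b1")
}

# One residual stage: y = F(n; W) + n with F(n) = tanh(W n + b). With W = 0
# and b = 0 the stage is the pure identity skip.
.residual_stage <- function(n, W, b = 0, skip = TRUE) {
  f <- tanh(as.numeric(W %*% n) + b)
  if (skip) f + n else f
}

#' Branch-2 features: residual stages over an intensity embedding
#'
#' A ResNet-style stand-in honoring the residual mapping `y = F(n; W) + n`:
#' the image is embedded as a block-mean intensity vector `n`, then passed
#' through two residual stages with fixed seeded weights, each adding its
#' input back through the identity skip. Deterministic.
#'
#' @inheritParams extract_branch1
#' @return numeric feature vector `f2` of length `output_dim`.
#' @export
extract_branch2 <- function(img, output_dim = 64L) {
  x <- .check_img(img)
  # location-invariant intensity embedding: quantile profile, histogram of
  # the active (nonzero) region, and global shape statistics
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = 32), names = FALSE)
  active <- x[x > 0]
  if (length(active) == 0) active <- 0
  hb <- tabulate(pmin(floor(active * 24) + 1L, 24L), nbins = 24L) / length(x)
  st <- c(mean(x), stats::sd(as.vector(x)), max(x), min(x),
          mean(active), stats::sd(active), mean(x > 0), mean(x > 0.5))
  st[!is.finite(st)] <- 0
  n <- .fit_dim(c(qs, hb, st), output_dim, "b2in")
  Ws <- .cached(sprintf("b2_W_%d", output_dim), function() {
    .with_fixed_rng(202L, function() {
      lapply(1:2, function(i) {
        matrix(stats::rnorm(output_dim^2, sd = 0.5 / sqrt(output_dim)),
               output_dim, output_dim)
      })
    })
  })
  for (W in Ws) n <- .residual_stage(n, W)
  n
}

#' Branch-3 features: dense connectivity with global average pooling
#'
#' A DenseNet-style stand-in: the downsampled image is the first channel;
#' each of three stages convolves the concatenation of *all* previously
#' produced channels with fixed seeded 3x3 kernels and appends its new
#' channels (ReLU), so stage `k`'s input width equals the sum of all previous
#' stage output widths. The feature vector is the global average pool of
#' every channel. Deterministic. The returned vector carries
#' `stage_input_widths` / `stage_output_widths` attributes so the dense
#' wiring is structurally checkable.
#'
#' @inheritParams extract_branch1
#' @return numeric feature vector `f3` of length `output_dim`.
#' @export
extract_branch3 <- function(img, output_dim = 64L) {
  x <- .check_img(img)
  growth <- max(1L, ceiling((output_dim - 1L) / 3L))
  maps <- list(.block_mean(x, 16L, 16L))
  widths_out <- 1L
  widths_in <- integer(0)
  kernels <- .cached(sprintf("b3_K_%d", growth), function() {
    .with_fixed_rng(303L, function() {
      lapply(1:3, function(s) {
        cin <- 1L + (s - 1L) * growth
        array(stats::rnorm(3 * 3 * cin * growth, sd = 1 / sqrt(9 * cin)),
              dim = c(3, 3, cin, growth))
      })
    })
  })
  for (s in 1:3) {
    K <- kernels[[s]]
    cin <- dim(K)[3]
    widths_in <- c(widths_in, length(maps))
    stopifnot(cin == length(maps))  # dense concatenation of all prior outputs
    new_maps <- lapply(seq_len(dim(K)[4]), function(j) {
      acc <- 0
      for (ci in seq_len(cin)) acc <- acc + .conv2same(maps[[ci]], K[, , ci, j])
      pmax(acc, 0)
    })
    maps <- c(maps, new_maps)
    widths_out <- c(widths_out, dim(K)[4])
  }
  gap <- vapply(maps, mean, numeric(1))
  out <- .fit_dim(gap, output_dim, "b3")
  structure(out, stage_input_widths = widths_in,
            stage_output_widths = widths_out)
}

#' Extract all three feature branches
#'
#' Convenience wrapper returning the `f1`, `f2`, `f3` vectors for one image.
#' By default extraction consumes the segmented image (element-wise
#' `image * mask`); pass `mask = NULL` to extract from the raw image.
#'
#' @param img a `gray_image` or matrix.
#' @param mask optional 0/1 lesion mask applied multiplicatively before
#'   extraction.
#' @param output_dim per-branch feature length.
#' @return named list with `f1`, `f2`, `f3`.
#' @export
extract_features <- function(img, mask = NULL, output_dim = 64L) {
  img <- as_gray_image(img)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(img)))
    img <- gray_image(as.matrix(img) * mask, bit_depth = bit_depth(img))
  }
  list(f1 = extract_branch1(img, output_dim),
       f2 = extract_branch2(img, output_dim),
       f3 = as.numeric(extract_branch3(img, output_dim)))
}

#' Feature matrix for a set of images
#'
#' Runs [extract_features()] over a list of images (optionally masked) and
#' stacks each branch into an `n x output_dim` matrix.
#'
#' @param imgs list of images.
#' @param masks optional list of masks (same length).
#' @param output_dim per-branch feature length.
#' @return list of matrices `f1`, `f2`, `f3` (rows = images).
#' @export
extract_feature_matrix <- function(imgs, masks = NULL, output_dim = 64L) {
  fs <- lapply(seq_along(imgs), function(i) {
    extract_features(imgs[[i]], if (is.null(masks)) NULL else masks[[i]],
                     output_dim)
  })
  list(f1 = do.call(rbind, lapply(fs, `[[`, "f1")),
       f2 = do.call(rbind, lapply(fs, `[[`, "f2")),
       f3 = do.call(rbind, lapply(fs, `[[`, "f3")))
}
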
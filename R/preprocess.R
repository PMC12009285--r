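#' CLAHE parameters
#'
#' Tile grid, histogram bin count, and the clip-limit parameterization
#' `beta = (tile_px / N) * (1 + alpha/100 * (L_max - 1))`: with `clip_factor`
#' `alpha = 0` the clip limit is exactly the flat-histogram level
#' `tile_px / N`; larger `alpha` allows proportionally taller histogram peaks
#' up to the maximal slope `L_max`.
#'
#' @param tile_rows,tile_cols tile grid (`A` x `B` tiles).
#' @param bins number of histogram bins `N` per tile.
#' @param clip_factor clip factor `alpha` (percent), `>= 0`.
#' @param max_slope maximally allowed slope `L_max`, `>= 1`.
#' @return a `clahe_params` list.
#' @export
clahe_params <- function(tile_rows = 8L, tile_cols = 8L, bins = 256L,
                         clip_factor = 40, max_slope = 4) {
  stopifnot(tile_rows >= 1, tile_cols >= 1, bins >= 2,
            clip_factor >= 0, max_slope >= 1)
  structure(list(tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols),
                 bins = as.integer(bins),
                 clip_factor = clip_factor, max_slope = max_slope),
            class = "clahe_params")
}

#' CLAHE clip limit
#'
#' `beta = (tile_pixel_count / N) * (1 + alpha/100 * (L_max - 1))`. The limit
#' is never below the flat level `tile_pixel_count / N` (attained exactly at
#' `alpha = 0`).
#'
#' @param params a [clahe_params()].
#' @param tile_pixel_count pixels per tile (`> 0`).
#' @return the clip limit (in histogram counts, possibly fractional).
#' @examples
#' clahe_clip_limit(clahe_params(bins = 64, clip_factor = 0), 64) # 1
#' @export
clahe_clip_limit <- function(params, tile_pixel_count) {
  stopifnot(inherits(params, "clahe_params"), tile_pixel_count > 0)
  (tile_pixel_count / params$bins) *
    (1 + params$clip_factor / 100 * (params$max_slope - 1))
}

# Equalization mapping for one histogram: level j -> round(cdf_j * maxg / total).
# `counts` has one entry per gray level (length maxg + 1).
.he_mapping <- function(counts, total, maxg) {
  round(cumsum(counts) * maxg / total)
}

#' Global histogram equalization
#'
#' Monotone gray-level remap proportional to the cumulative distribution:
#' `M0(j) = round(G_j * (2^r - 1) / (Q * y))` with `G_j` the cumulative pixel
#' count up to level `j`, `Q x y` the image size and `r` the bit depth.
#' Exactly idempotent on the levels present in an image (a second application
#' is the identity).
#'
#' @param img a `gray_image` or plain matrix (assumed 8-bit).
#' @return equalized `gray_image` of the same shape and bit depth.
#' @examples
#' hist_equalize(gray_image(matrix(c(0, 0, 255, 255), 2, 2)))
#' @export
hist_equalize <- function(img) {
  img <- as_gray_image(img)
  maxg <- max_gray(img)
  counts <- tabulate(as.matrix(img) + 1L, nbins = maxg + 1L)
  m0 <- .he_mapping(counts, length(img), maxg)
  out <- matrix(m0[as.matrix(img) + 1L], nrow(img), ncol(img))
  gray_image(out, bit_depth = bit_depth(img))
}

# Clip a histogram at `limit` and redistribute the excess uniformly over all
# bins (single pass; a few counts may end slightly above the limit, which is
# the standard behaviour).
.clip_hist <- function(counts, limit) {
  excess <- sum(pmax(counts - limit, 0))
  pmin(counts, limit) + excess / length(counts)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is split into an `A x B` grid of equal tiles (edge-reflected
#' padding when the dimensions do not divide evenly). Each tile's histogram is
#' clipped at the [clahe_clip_limit()] with the excess redistributed uniformly,
#' then turned into an equalization mapping; per-pixel output is the bilinear
#' blend of the four neighbouring tile mappings (edge tiles replicate).
#' Output has the same shape and bit depth as the input, and a 1x1 grid with a
#' very large clip factor reproduces global [hist_equalize()].
#'
#' @param img a `gray_image` or plain matrix (assumed 8-bit).
#' @param params a [clahe_params()].
#' @return enhanced `gray_image`.
#' @export
clahe <- function(img, params = clahe_params()) {
  img <- as_gray_image(img)
  stopifnot(inherits(params, "clahe_params"))
  A <- params$tile_rows; B <- params$tile_cols; N <- params$bins
  if (A > nrow(img) || B > ncol(img)) {
    stop("tile grid larger than image", call. = FALSE)
  }
  maxg <- max_gray(img)
  px <- as.matrix(img)

  # pad by edge reflection so tiles divide evenly
  th <- ceiling(nrow(px) / A); tw <- ceiling(ncol(px) / B)
  H <- th * A; W <- tw * B
  ridx <- c(seq_len(nrow(px)), rev(seq_len(nrow(px))))[seq_len(H)]
  cidx <- c(seq_len(ncol(px)), rev(seq_len(ncol(px))))[seq_len(W)]
  pad <- px[ridx, cidx, drop = FALSE]

  tile_px <- th * tw
  beta <- clahe_clip_limit(params, tile_px)
  bin_of <- function(v) pmin(floor(v * N / (maxg + 1L)), N - 1L)  # 0-based

  # per-tile mappings: bin -> output level
  M <- matrix(0, nrow = A * B, ncol = N)
  for (a in seq_len(A)) {
    for (b in seq_len(B)) {
      tile <- pad[((a - 1) * th + 1):(a * th), ((b - 1) * tw + 1):(b * tw)]
      counts <- tabulate(bin_of(tile) + 1L, nbins = N)
      clipped <- .clip_hist(counts, beta)
      M[(a - 1) * B + b, ] <- round(cumsum(clipped) * maxg / tile_px)
    }
  }

  # bilinear blend of the four neighbouring tile mappings
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  rf <- (rows - 0.5) / th - 0.5   # fractional tile-row coordinate (0-based)
  cf <- (cols - 0.5) / tw - 0.5
  r0 <- clamp(floor(rf), 0, A - 1); r1 <- clamp(r0 + 1, 0, A - 1)
  c0 <- clamp(floor(cf), 0, B - 1); c1 <- clamp(c0 + 1, 0, B - 1)
  wr <- clamp(rf - floor(rf), 0, 1); wr[rf < 0] <- 0; wr[rf > A - 1] <- 1
  wc <- clamp(cf - floor(cf), 0, 1); wc[cf < 0] <- 0; wc[cf > B - 1] <- 1

  bins <- bin_of(pad) + 1L
  gather <- function(tr, tc) matrix(M[cbind(as.vector(tr * B + tc + 1L),
                                            as.vector(bins))], H, W)
  out <- (1 - wr) * ((1 - wc) * gather(r0, c0) + wc * gather(r0, c1)) +
         wr       * ((1 - wc) * gather(r1, c0) + wc * gather(r1, c1))
  out <- clamp(round(out), 0, maxg)
  gray_image(out[seq_len(nrow(px)), seq_len(ncol(px)), drop = FALSE],
             bit_depth = bit_depth(img))
}
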
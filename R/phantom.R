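# Seeded generator of synthetic breast thermograms: a smooth warm background
# (mean level + linear gradient + a few low-frequency cosine modes), zero or
# more hyperthermic Gaussian lesion bumps, optional radial vignetting, and
# additive sensor noise, quantized to the requested bit depth. Ground truth
# is the half-maximum level set of each noiseless lesion bump.

#' Phantom specification
#'
#' @param size image size `c(H, W)`.
#' @param background_mean mean background gray level.
#' @param gradient_amplitude amplitude of a random linear temperature
#'   gradient across the field of view.
#' @param n_modes number of low-frequency cosine background modes (2-4 mimic
#'   smooth body-surface temperature variation).
#' @param mode_amplitude amplitude of each cosine mode.
#' @param lesions list of lesions, each `list(center = c(row, col),
#'   radius = r, delta = d)`: `radius` is the half-maximum radius of the
#'   Gaussian bump (so the true mask of an isolated lesion is a disk of area
#'   `pi * r^2`) and `delta > 0` its hyperthermic peak excess. `NULL` or
#'   `list()` for a normal (lesion-free) phantom.
#' @param noise_sigma sd of additive Gaussian sensor noise (gray levels).
#' @param vignette_strength peak darkening at the corners (gray levels).
#' @param bit_depth 8 (default) or 16.
#' @param seed integer seed; the generated triple is a pure function of the
#'   spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(64, 64), background_mean = 120,
                         gradient_amplitude = 20, n_modes = 3,
                         mode_amplitude = 10, lesions = NULL,
                         noise_sigma = 5, vignette_strength = 0,
                         bit_depth = 8L, seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 8), noise_sigma >= 0,
            vignette_strength >= 0, n_modes >= 0)
  for (ls in lesions) {
    if (is.null(ls$center) || is.null(ls$radius) || is.null(ls$delta)) {
      stop("each lesion needs center, radius, delta", call. = FALSE)
    }
    if (ls$delta <= 0) stop("lesion delta must be > 0 (hyperthermic)",
                            call. = FALSE)
    if (any(ls$center < 1) || ls$center[1] > size[1] || ls$center[2] > size[2]) {
      stop("lesion center outside image", call. = FALSE)
    }
  }
  structure(list(size = as.integer(size), background_mean = background_mean,
                 gradient_amplitude = gradient_amplitude,
                 n_modes = as.integer(n_modes),
                 mode_amplitude = mode_amplitude,
                 lesions = if (is.null(lesions)) list() else lesions,
                 noise_sigma = noise_sigma,
                 vignette_strength = vignette_strength,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one synthetic thermogram phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a `gray_image`), `mask` (0/1 ground truth:
#'   pixels where some lesion's noiseless contribution exceeds half its
#'   peak), and `label` (`"abnormal"` iff at least one lesion).
#' @examples
#' p <- generate_phantom(phantom_spec(lesions = list(
#'   list(center = c(32, 32), radius = 7, delta = 60)), seed = 3))
#' sum(p$mask)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  .with_fixed_rng(spec$seed, function() {
    theta <- stats::runif(1, 0, 2 * pi)
    bg <- spec$background_mean +
      spec$gradient_amplitude * ((rr / H - 0.5) * cos(theta) +
                                   (cc / W - 0.5) * sin(theta))
    for (m in seq_len(spec$n_modes)) {
      fx <- sample(0:2, 1); fy <- sample(0:2, 1)
      ph <- stats::runif(1, 0, 2 * pi)
      bg <- bg + spec$mode_amplitude *
        cos(2 * pi * (fx * rr / H + fy * cc / W) + ph)
    }
    lesion_field <- matrix(0, H, W)
    mask <- matrix(0L, H, W)
    for (ls in spec$lesions) {
      sigma <- ls$radius / sqrt(2 * log(2))  # half-max at distance `radius`
      d2 <- (rr - ls$center[1])^2 + (cc - ls$center[2])^2
      bump <- ls$delta * exp(-d2 / (2 * sigma^2))
      lesion_field <- lesion_field + bump
      mask[bump > ls$delta / 2] <- 1L
    }
    vig <- if (spec$vignette_strength > 0) {
      dn <- ((rr - (H + 1) / 2)^2 / (H / 2)^2 + (cc - (W + 1) / 2)^2 / (W / 2)^2)
      -spec$vignette_strength * dn / 2
    } else 0
    noise <- if (spec$noise_sigma > 0) {
      matrix(stats::rnorm(H * W, sd = spec$noise_sigma), H, W)
    } else 0
    maxg <- 2^spec$bit_depth - 1
    img <- gray_image(clamp(round(bg + lesion_field + vig + noise), 0, maxg),
                      bit_depth = spec$bit_depth)
    list(image = img, mask = mask,
         label = if (length(spec$lesions) >= 1L) "abnormal" else "normal")
  })
}

# deterministic per-image seed derivation, kept below 2^31
.derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483647)
}

# random lesion set for an abnormal cohort member
.random_lesions <- function(size, seed) {
  .with_fixed_rng(seed, function() {
    k <- sample(1:2, 1, prob = c(0.7, 0.3))
    lapply(seq_len(k), function(j) {
      r <- stats::runif(1, 5, 9)
      margin <- ceiling(2 * r)
      list(center = c(sample(margin:(size[1] - margin), 1),
                      sample(margin:(size[2] - margin), 1)),
           radius = r,
           delta = 60)
    })
  })
}

#' Generate a cohort of phantoms with manifest
#'
#' Writes `n_normal` lesion-free and `n_abnormal` lesion-bearing phantoms
#' (plus ground-truth masks) as PNG files under `out_dir`, with a
#' `manifest.csv` of `image_path, mask_path, label`. Per-image seeds are
#' derived deterministically from the master seed, so two runs with the same
#' arguments produce byte-identical files.
#'
#' @param n_normal,n_abnormal class counts (total at least 2).
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param size image size `c(H, W)`.
#' @param noise_sigma sensor-noise sd passed to every phantom.
#' @param ... further arguments forwarded to [phantom_spec()].
#' @return the manifest as a tibble (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_cohort <- function(n_normal, n_abnormal, out_dir, seed = 1L,
                            size = c(64, 64), noise_sigma = 5, ...) {
  stopifnot(n_normal >= 0, n_abnormal >= 0, n_normal + n_abnormal >= 2)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  labels <- c(rep("normal", n_normal), rep("abnormal", n_abnormal))
  rows <- lapply(seq_along(labels), function(i) {
    si <- .derive_seed(seed, i)
    lesions <- if (labels[i] == "abnormal") {
      .random_lesions(size, .derive_seed(si, 1L))
    } else NULL
    ph <- generate_phantom(phantom_spec(size = size, lesions = lesions,
                                        noise_sigma = noise_sigma,
                                        seed = si, ...))
    ip <- file.path("images", sprintf("img_%03d.png", i))
    mp <- file.path("masks", sprintf("mask_%03d.png", i))
    write_gray(ph$image, file.path(out_dir, ip))
    write_mask(ph$mask, file.path(out_dir, mp))
    tibble::tibble(image_path = ip, mask_path = mp, label = ph$label)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
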
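# The five mixed-sample augmentation operators. Each takes one labeled
# sample (I_L, T_L), one unlabeled image I_U of identical dimensions, and a
# parameter set, and returns a pseudolabeled sample whose mask is the
# labeled mask object itself: the segmentation target is never altered.
# All arithmetic is in the float [0, 1] domain.

MIXED_STRATEGIES <- c("pixmix", "segmix2", "lesionblend", "lesionblend2",
                      "pixmix2")
BASELINE_STRATEGIES <- c("rotation", "translation", "gaussian_noise")

#' Mixing parameters for the mixed-sample strategies
#'
#' `alpha` is the fraction of labeled-image features kept and `beta` the
#' fraction imported from the unlabeled image (PixMix); they must sum to 1.
#' The defaults `alpha = 0.8`, `beta = 0.2` are the configuration found
#' optimal in the original ablation. `gamma` weights the lesion-interior
#' blend in SegMix2 (no canonical value exists; 0.5 is the symmetric
#' default). `sigma` is the Gaussian mask-smoothing scale in pixels used to
#' feather lesion boundaries (default 5 px at 224x224).
#'
#' @param alpha,beta PixMix weights in `[0, 1]` with `alpha + beta = 1`.
#' @param gamma SegMix2 interior blend weight in `[0, 1]`.
#' @param sigma Mask smoothing scale in pixels, > 0.
#' @param pixmix2_overflow How PixMix2 maps the raw sum back into `[0, 1]`:
#'   `"rescale"` (min-max, default) or `"clip"`.
#' @return A `us_mix_params` list.
#' @export
mix_params <- function(alpha = 0.8, beta = 1 - alpha, gamma = 0.5,
                       sigma = 5, pixmix2_overflow = c("rescale", "clip")) {
  pixmix2_overflow <- match.arg(pixmix2_overflow)
  for (nm in c("alpha", "beta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop_usmix("`", nm, "` must be a single value in [0, 1].")
    }
  }
  if (abs(alpha + beta - 1) > 1e-8) {
    stop_usmix("`alpha` + `beta` must equal 1 (got ", alpha + beta, ").")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_usmix("`sigma` must be a single positive value.")
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, sigma = sigma,
         pixmix2_overflow = pixmix2_overflow),
    class = "us_mix_params"
  )
}

# --- Gaussian smoothing -----------------------------------------------------

# Separable Gaussian convolution, kernel truncated at 4*sigma (radius >= 1),
# symmetric (reflective) boundary handling. A normalized kernel leaves
# constant fields unchanged, so an all-ones mask smooths to all ones.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w / sum(w)
}

reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j >= n, 2 * n - 1 - j, j) + 1
}

conv_rows <- function(x, w) {
  n <- nrow(x)
  r <- (length(w) - 1L) %/% 2L
  xp <- x[reflect_index((1 - r):(n + r), n), , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (k in seq_along(w)) {
    out <- out + w[k] * xp[k:(k + n - 1L), , drop = FALSE]
  }
  out
}

gaussian_smooth <- function(x, sigma) {
  w <- gaussian_kernel_1d(sigma)
  t(conv_rows(t(conv_rows(x, w)), w))
}

#' Gaussian-smooth a binary mask into a soft blending mask
#'
#' Convolves the `{0, 1}` lesion mask with a normalized 2-D Gaussian
#' (separable, truncated at 4 sigma, reflective borders) to obtain the soft
#' mask used as continuous per-pixel blend weights. Values stay in `[0, 1]`
#' and approach the hard mask as `sigma` shrinks.
#'
#' @param mask Binary mask matrix.
#' @param sigma Smoothing scale in pixels, > 0.
#' @return A matrix in `[0, 1]` with attribute `"sigma"`.
#' @export
smooth_mask <- function(mask, sigma) {
  check_binary_mask(mask)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_usmix("`sigma` must be a single positive value.")
  }
  out <- soft_mask_matrix(mask, sigma)
  attr(out, "sigma") <- sigma
  out
}

# Attribute-free soft mask used inside the blend operators, so output images
# stay plain matrices.
soft_mask_matrix <- function(mask, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop_usmix("`sigma` must be a single positive value.")
  }
  clamp01(gaussian_smooth(mask, sigma))
}

# Common head for the five operators.
mix_inputs <- function(labeled, unlabeled) {
  lab <- as_sample(labeled)
  unl <- as_unlabeled(unlabeled)
  check_gray_image(unl$image, arg = "unlabeled image")
  check_same_dim(lab$image, unl$image, c("labeled image", "unlabeled image"))
  list(lab = lab, unl = unl)
}

#' PixMix: global convex blend of a labeled and an unlabeled image
#'
#' `I_aug = alpha * I_L + beta * I_U`, `T_aug = T_L`. The whole unlabeled
#' image leaks into the labeled one at weight `beta` while the mask is kept
#' untouched, so the sample is pseudolabeled by its labeled source.
#'
#' @param labeled A labeled sample (see [as_sample()]).
#' @param unlabeled An unlabeled image: matrix, pool row, or list with
#'   `$image`.
#' @param params A [mix_params()] object.
#' @return A `us_aug_sample` whose `mask` is identical to the input mask.
#' @examples
#' ds <- make_dataset(1, 1, seed = 1, height = 32, width = 32)
#' aug <- pixmix(ds$labeled[1, ], ds$unlabeled[1, ], mix_params(alpha = 0.8))
#' identical(aug$mask, ds$labeled$mask[[1]])
#' @export
pixmix <- function(labeled, unlabeled, params = mix_params()) {
  x <- mix_inputs(labeled, unlabeled)
  img <- params$alpha * x$lab$image + params$beta * x$unl$image
  augmented_sample(img, x$lab$mask, "pixmix", x$lab$source_id,
                   x$unl$source_id,
                   params = list(alpha = params$alpha, beta = params$beta))
}

#' SegMix2: transplant the blended lesion onto an unlabeled image
#'
#' `I_aug = (1 - T_L') * I_U + T_L' * I_L'` with
#' `I_L' = gamma * I_L + (1 - gamma) * I_U`, where `T_L'` is the
#' Gaussian-smoothed mask; `T_aug = T_L`. The labeled lesion (optionally
#' diluted by `gamma`) is carried onto the unlabeled background.
#'
#' @inheritParams pixmix
#' @return A `us_aug_sample` with the unaltered source mask.
#' @export
segmix2 <- function(labeled, unlabeled, params = mix_params()) {
  x <- mix_inputs(labeled, unlabeled)
  tlp <- soft_mask_matrix(x$lab$mask, params$sigma)
  ilp <- params$gamma * x$lab$image + (1 - params$gamma) * x$unl$image
  img <- (1 - tlp) * x$unl$image + tlp * ilp
  augmented_sample(img, x$lab$mask, "segmix2", x$lab$source_id,
                   x$unl$source_id,
                   params = list(gamma = params$gamma, sigma = params$sigma))
}

#' LesionBlend: keep the labeled lesion, swap in an unlabeled background
#'
#' `I_aug = T_L' * I_L + (1 - T_L') * I_U`, `T_aug = T_L`. The smoothed mask
#' feathers the transition so no hard seam appears at the lesion boundary.
#'
#' @inheritParams pixmix
#' @return A `us_aug_sample` with the unaltered source mask.
#' @export
lesionblend <- function(labeled, unlabeled, params = mix_params()) {
  x <- mix_inputs(labeled, unlabeled)
  tlp <- soft_mask_matrix(x$lab$mask, params$sigma)
  img <- tlp * x$lab$image + (1 - tlp) * x$unl$image
  augmented_sample(img, x$lab$mask, "lesionblend", x$lab$source_id,
                   x$unl$source_id, params = list(sigma = params$sigma))
}

#' LesionBlend2: keep the labeled background, fill the lesion from the pool
#'
#' `I_aug = (1 - T_L') * I_L + T_L' * I_U`, `T_aug = T_L` — the exact
#' complement of [lesionblend()]: pixelwise,
#' `lesionblend + lesionblend2 = I_L + I_U`.
#'
#' @inheritParams pixmix
#' @return A `us_aug_sample` with the unaltered source mask.
#' @export
lesionblend2 <- function(labeled, unlabeled, params = mix_params()) {
  x <- mix_inputs(labeled, unlabeled)
  tlp <- soft_mask_matrix(x$lab$mask, params$sigma)
  img <- (1 - tlp) * x$lab$image + tlp * x$unl$image
  augmented_sample(img, x$lab$mask, "lesionblend2", x$lab$source_id,
                   x$unl$source_id, params = list(sigma = params$sigma))
}

#' PixMix2: direct image sum, renormalized to the unit range
#'
#' `I_aug = I_L + I_U`, `T_aug = T_L`. The raw sum lives in `[0, 2]`; with
#' `pixmix2_overflow = "rescale"` (default) it is min-max rescaled back to
#' `[0, 1]` (a constant sum maps to all-zero), with `"clip"` it is clamped.
#'
#' @inheritParams pixmix
#' @return A `us_aug_sample` with the unaltered source mask.
#' @export
pixmix2 <- function(labeled, unlabeled, params = mix_params()) {
  x <- mix_inputs(labeled, unlabeled)
  s <- x$lab$image + x$unl$image
  img <- if (params$pixmix2_overflow == "clip") pmin(s, 1) else normalize_minmax(s)
  augmented_sample(img, x$lab$mask, "pixmix2", x$lab$source_id,
                   x$unl$source_id,
                   params = list(pixmix2_overflow = params$pixmix2_overflow))
}

#' Apply a mixed-sample strategy by name
#'
#' @param strategy One of `"pixmix"`, `"segmix2"`, `"lesionblend"`,
#'   `"lesionblend2"`, `"pixmix2"`.
#' @inheritParams pixmix
#' @return A `us_aug_sample`.
#' @export
apply_mixed_strategy <- function(strategy, labeled, unlabeled,
                                 params = mix_params()) {
  strategy <- match.arg(strategy, MIXED_STRATEGIES)
  fn <- switch(strategy, pixmix = pixmix, segmix2 = segmix2,
               lesionblend = lesionblend, lesionblend2 = lesionblend2,
               pixmix2 = pixmix2)
  fn(labeled, unlabeled, params)
}
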
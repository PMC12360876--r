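# Traditional augmentation baselines: rotation, translation, additive
# Gaussian noise, and the horizontal-flip preprocessing step. Geometric
# operators transform image and mask with the same draw (joint-transform
# contract); the noise operator never touches the mask.

#' Parameters for the traditional augmentation baselines
#'
#' Defaults follow the standard comparison protocol: rotation angles uniform
#' in 15-345 degrees (deliberately avoiding near-identity rotations),
#' translations up to +/-20% of each axis, zero-mean Gaussian noise with
#' variance drawn from 10-50 on the 8-bit intensity scale, and horizontal
#' flips with probability 0.5.
#'
#' @param angle_range Length-2 numeric, degrees, within `[0, 360)`,
#'   `min < max`.
#' @param shift_fraction Maximum shift per axis as a fraction of the axis
#'   length, in `[0, 0.5]`.
#' @param noise_var_range Length-2 numeric, noise variance bounds on the
#'   0-255 scale, non-negative.
#' @param flip_prob Horizontal flip probability in `[0, 1]`.
#' @return A `us_baseline_params` list.
#' @export
baseline_params <- function(angle_range = c(15, 345), shift_fraction = 0.20,
                            noise_var_range = c(10, 50), flip_prob = 0.5) {
  if (length(angle_range) != 2L || any(angle_range < 0) ||
      any(angle_range >= 360) || angle_range[1] >= angle_range[2]) {
    stop_usmix("`angle_range` must be two increasing values within [0, 360).")
  }
  if (length(shift_fraction) != 1L || shift_fraction < 0 ||
      shift_fraction > 0.5) {
    stop_usmix("`shift_fraction` must lie in [0, 0.5].")
  }
  if (length(noise_var_range) != 2L || any(noise_var_range < 0) ||
      noise_var_range[1] > noise_var_range[2]) {
    stop_usmix("`noise_var_range` must be two non-decreasing values >= 0.")
  }
  if (length(flip_prob) != 1L || flip_prob < 0 || flip_prob > 1) {
    stop_usmix("`flip_prob` must lie in [0, 1].")
  }
  structure(
    list(angle_range = angle_range, shift_fraction = shift_fraction,
         noise_var_range = noise_var_range, flip_prob = flip_prob),
    class = "us_baseline_params"
  )
}

# --- deterministic geometric cores -----------------------------------------

# Rotate by `angle` degrees (counter-clockwise) about the image center via
# inverse mapping. Images: bilinear with zero fill; masks: nearest-neighbor
# with zero fill, re-binarized.
rotate_matrix <- function(x, angle, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  h <- nrow(x); w <- ncol(x)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  gr <- matrix(seq_len(h) - cr, h, w)
  gc <- matrix(seq_len(w) - cc, h, w, byrow = TRUE)
  # inverse rotation of output coordinates into the source frame
  sr <- co * gr + si * gc + cr
  sc <- -si * gr + co * gc + cc
  if (kind == "mask") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- matrix(0, h, w)
    out[ok] <- x[cbind(ri[ok], ci[ok])]
    (out >= 0.5) * 1
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    val <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      v <- matrix(0, h, w)
      v[ok] <- x[cbind(ri[ok], ci[ok])]
      v
    }
    out <- val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
      val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
    clamp01(out)
  }
}

# Integer-pixel shift with zero fill; positive dr moves content down,
# positive dc moves content right.
shift_matrix <- function(x, dr, dc) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- x[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Rotate a labeled sample by a fixed angle
#'
#' Deterministic core of [rotate_pair()]: rotates image (bilinear) and mask
#' (nearest-neighbor, re-binarized) jointly about the image center,
#' zero-filling pixels that come from outside the frame.
#'
#' @param sample A labeled sample.
#' @param angle Rotation angle in degrees (counter-clockwise).
#' @return A `us_aug_sample` with `strategy = "rotation"`.
#' @export
rotate_by <- function(sample, angle) {
  s <- as_sample(sample)
  augmented_sample(
    rotate_matrix(s$image, angle, "image"),
    rotate_matrix(s$mask, angle, "mask"),
    "rotation", s$source_id, params = list(angle = angle)
  )
}

#' Shift a labeled sample by an integer pixel offset
#'
#' Deterministic core of [translate_pair()]: shifts image and mask jointly,
#' zero-filling vacated pixels (lesion pixels pushed out of frame are lost).
#'
#' @param sample A labeled sample.
#' @param dr,dc Integer shifts (rows down, columns right).
#' @return A `us_aug_sample` with `strategy = "translation"`.
#' @export
shift_by <- function(sample, dr, dc) {
  s <- as_sample(sample)
  augmented_sample(
    shift_matrix(s$image, dr, dc),
    shift_matrix(s$mask, dr, dc),
    "translation", s$source_id, params = list(dr = dr, dc = dc)
  )
}

#' Random rotation baseline
#'
#' Draws an angle uniformly from `params$angle_range` and applies
#' [rotate_by()]. Fully reproducible from `rng_seed`.
#'
#' @param sample A labeled sample.
#' @param rng_seed Integer seed for the angle draw.
#' @param params A [baseline_params()] object.
#' @return A `us_aug_sample` recording the drawn angle and the seed.
#' @export
rotate_pair <- function(sample, rng_seed, params = baseline_params()) {
  angle <- with_seed(rng_seed,
                     runif(1, params$angle_range[1], params$angle_range[2]))
  out <- rotate_by(sample, angle)
  out$params <- list(angle = angle, angle_range = params$angle_range)
  out$seed <- as.integer(rng_seed)
  out
}

#' Random translation baseline
#'
#' Shifts are drawn uniformly and independently per axis from
#' `[-shift_fraction * dim, +shift_fraction * dim]` and rounded to integer
#' pixels (half away from zero), so the mask is never resampled.
#'
#' @inheritParams rotate_pair
#' @return A `us_aug_sample` recording the drawn shifts and the seed.
#' @export
translate_pair <- function(sample, rng_seed, params = baseline_params()) {
  s <- as_sample(sample)
  f <- params$shift_fraction
  sh <- with_seed(rng_seed, c(
    runif(1, -f * nrow(s$image), f * nrow(s$image)),
    runif(1, -f * ncol(s$image), f * ncol(s$image))
  ))
  dr <- round_half_away(sh[1]); dc <- round_half_away(sh[2])
  out <- shift_by(s, dr, dc)
  out$params <- list(dr = dr, dc = dc, shift_fraction = f)
  out$seed <- as.integer(rng_seed)
  out
}

#' Additive Gaussian-noise baseline
#'
#' A variance is drawn uniformly from `params$noise_var_range` (0-255
#' intensity scale), converted to the unit domain as `var / 255^2`, and
#' zero-mean Gaussian noise of that variance is added pixelwise; the result
#' is clipped to `[0, 1]`. The mask is returned untouched.
#'
#' @inheritParams rotate_pair
#' @return A `us_aug_sample` with the identical input mask.
#' @export
gaussian_noise_pair <- function(sample, rng_seed, params = baseline_params()) {
  s <- as_sample(sample)
  img <- with_seed(rng_seed, {
    v <- runif(1, params$noise_var_range[1], params$noise_var_range[2])
    sdev <- sqrt(v) / 255
    clamp01(s$image + matrix(rnorm(length(s$image), 0, sdev),
                             nrow(s$image), ncol(s$image)))
  })
  out <- augmented_sample(img, s$mask, "gaussian_noise", s$source_id,
                          params = list(noise_var_range = params$noise_var_range),
                          seed = as.integer(rng_seed))
  out
}

#' Random horizontal flip (preprocessing step)
#'
#' With probability `flip_prob`, both image and mask are mirrored
#' left-right; otherwise the sample passes through unchanged.
#'
#' @param sample A labeled sample.
#' @param rng_seed Integer seed for the Bernoulli draw.
#' @param flip_prob Flip probability in `[0, 1]`.
#' @return A `us_aug_sample` with `strategy = "hflip"` and a `flipped` flag
#'   in `params`.
#' @export
hflip_pair <- function(sample, rng_seed, flip_prob = 0.5) {
  if (flip_prob < 0 || flip_prob > 1) {
    stop_usmix("`flip_prob` must lie in [0, 1].")
  }
  s <- as_sample(sample)
  do_flip <- with_seed(rng_seed, runif(1) < flip_prob)
  img <- if (do_flip) mirror_lr(s$image) else s$image
  msk <- if (do_flip) mirror_lr(s$mask) else s$mask
  augmented_sample(img, msk, "hflip", s$source_id,
                   params = list(flip_prob = flip_prob, flipped = do_flip),
                   seed = as.integer(rng_seed))
}

#' Apply a traditional baseline strategy by name
#'
#' @param strategy One of `"rotation"`, `"translation"`, `"gaussian_noise"`.
#' @inheritParams rotate_pair
#' @return A `us_aug_sample`.
#' @export
apply_baseline_strategy <- function(strategy, sample, rng_seed,
                                    params = baseline_params()) {
  strategy <- match.arg(strategy, BASELINE_STRATEGIES)
  fn <- switch(strategy, rotation = rotate_pair,
               translation = translate_pair,
               gaussian_noise = gaussian_noise_pair)
  fn(sample, rng_seed = rng_seed, params = params)
}
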
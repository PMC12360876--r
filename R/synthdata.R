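# Synthetic ultrasound-like phantoms: a speckle-textured background with
# one bright-or-dark elliptical lesion whose boundary is Gaussian-feathered,
# plus the exact hard-ellipse indicator as ground-truth mask. Lesion-free
# phantoms serve as the unlabeled pool. Speckle is modeled as unit-mean
# multiplicative gamma noise, lightly smoothed to give it spatial grain.

PHANTOM_BASE_INTENSITY <- 0.4
PHANTOM_SPECKLE_SMOOTH_SIGMA <- 1.0

#' Specify a synthetic lesion phantom
#'
#' @param height,width Frame size in pixels (default 224, the standard
#'   working resolution).
#' @param lesion_axes Semi-axes `(a, b)` of the elliptical lesion in pixels
#'   (rows, cols), each >= 3.
#' @param lesion_center Center `(row, col)`; default frame center. The
#'   lesion must fit inside the frame with a margin of at least 2 px.
#' @param lesion_contrast Signed intensity offset of the lesion in
#'   `[-0.5, 0.5]` (negative = hypoechoic/dark lesion, the common case in
#'   breast ultrasound; positive = bright).
#' @param edge_sigma Gaussian feathering width of the lesion boundary in
#'   pixels.
#' @param speckle_scale Relative standard deviation of the multiplicative
#'   gamma speckle (0 disables speckle).
#' @param seed Integer seed; the phantom is a pure function of its spec.
#' @return A `us_phantom_spec` list.
#' @export
phantom_spec <- function(height = 224, width = 224, lesion_axes = c(30, 22),
                         lesion_center = NULL, lesion_contrast = -0.25,
                         edge_sigma = 2, speckle_scale = 0.3, seed = 1L) {
  if (is.null(lesion_center)) {
    lesion_center <- c((height + 1) / 2, (width + 1) / 2)
  }
  if (any(lesion_axes < 3)) stop_usmix("Lesion semi-axes must be >= 3 px.")
  if (abs(lesion_contrast) > 0.5) {
    stop_usmix("`lesion_contrast` must lie in [-0.5, 0.5].")
  }
  a <- lesion_axes[1]; b <- lesion_axes[2]
  cr <- lesion_center[1]; cc <- lesion_center[2]
  if (cr - a < 3 || cr + a > height - 2 || cc - b < 3 || cc + b > width - 2) {
    stop_usmix("Lesion (center ", cr, ",", cc, "; semi-axes ", a, ",", b,
               ") does not fit in the ", height, "x", width,
               " frame with a 2 px margin.")
  }
  structure(
    list(height = height, width = width, lesion_axes = lesion_axes,
         lesion_center = lesion_center, lesion_contrast = lesion_contrast,
         edge_sigma = edge_sigma, speckle_scale = speckle_scale,
         seed = as.integer(seed)),
    class = "us_phantom_spec"
  )
}

# Speckled lesion-free background field in [0, 1].
phantom_background <- function(height, width, seed, speckle_scale = 0.3) {
  with_seed(seed, {
    if (speckle_scale > 0) {
      shape <- 1 / speckle_scale^2
      s <- matrix(rgamma(height * width, shape = shape, rate = shape),
                  height, width)
      s <- gaussian_smooth(s, PHANTOM_SPECKLE_SMOOTH_SIGMA)
    } else {
      s <- matrix(1, height, width)
    }
    clamp01(PHANTOM_BASE_INTENSITY * s)
  })
}

ellipse_indicator <- function(height, width, center, axes) {
  gr <- matrix(seq_len(height) - center[1], height, width)
  gc <- matrix(seq_len(width) - center[2], height, width, byrow = TRUE)
  ((gr / axes[1])^2 + (gc / axes[2])^2 <= 1) * 1
}

#' Synthesize one labeled phantom
#'
#' The background is a smoothed multiplicative-gamma speckle field; the
#' lesion region is offset by `lesion_contrast` through a Gaussian-feathered
#' edge of width `edge_sigma`; the returned mask is the exact hard ellipse
#' indicator used to synthesize the image.
#'
#' @param spec A [phantom_spec()].
#' @param source_id Identifier for the sample.
#' @return A `us_sample`; bit-identical for identical specs.
#' @export
make_phantom <- function(spec, source_id = sprintf("phantom_%06d", spec$seed)) {
  bg <- phantom_background(spec$height, spec$width, spec$seed,
                           spec$speckle_scale)
  mask <- ellipse_indicator(spec$height, spec$width, spec$lesion_center,
                            spec$lesion_axes)
  feather <- gaussian_smooth(mask, spec$edge_sigma)
  img <- clamp01(bg + spec$lesion_contrast * feather)
  labeled_sample(img, mask, source_id = source_id)
}

#' Generate a reproducible phantom dataset
#'
#' Draws per-phantom specs (semi-axes uniform in `axes_range`, contrast of
#' random sign with magnitude uniform in `contrast_range`, centers uniform
#' over the positions where the lesion fits) with per-sample seeds derived
#' from `seed`, then synthesizes `n_labeled` lesion phantoms and
#' `n_unlabeled` lesion-free pool images. The axis range is truncated when
#' the frame is too small to hold its upper end.
#'
#' @param n_labeled,n_unlabeled Counts (>= 1 labeled; >= 0 unlabeled).
#' @param seed Integer master seed; `(n, seed)` fully determine the dataset.
#' @param height,width Frame size in pixels.
#' @param axes_range Semi-axis bounds in pixels (default 8-40).
#' @param contrast_range Bounds on `|lesion_contrast|` (default 0.1-0.3).
#' @param edge_sigma,speckle_scale Passed to [phantom_spec()].
#' @return A list with `labeled` (dataset tibble), `unlabeled` (pool
#'   tibble) and `spec_log` (tibble of drawn parameters).
#' @export
make_dataset <- function(n_labeled, n_unlabeled, seed, height = 224,
                         width = 224, axes_range = c(8, 40),
                         contrast_range = c(0.1, 0.3), edge_sigma = 2,
                         speckle_scale = 0.3) {
  if (n_labeled < 1) stop_usmix("`n_labeled` must be >= 1.")
  ax_hi <- min(axes_range[2], floor((min(height, width) - 6) / 2))
  ax_lo <- min(axes_range[1], ax_hi)
  if (ax_hi < 3) stop_usmix("Frame too small for any lesion.")
  draws <- with_seed(seed, {
    a <- runif(n_labeled, ax_lo, ax_hi)
    b <- runif(n_labeled, ax_lo, ax_hi)
    mag <- runif(n_labeled, contrast_range[1], contrast_range[2])
    sgn <- sample(c(-1, 1), n_labeled, replace = TRUE)
    cr <- runif(n_labeled, a + 3, height - 2 - a)
    cc <- runif(n_labeled, b + 3, width - 2 - b)
    seeds <- sample.int(.Machine$integer.max - 1L, n_labeled + n_unlabeled)
    list(a = a, b = b, contrast = sgn * mag, cr = cr, cc = cc, seeds = seeds)
  })
  specs <- purrr::map(seq_len(n_labeled), function(i) {
    phantom_spec(height = height, width = width,
                 lesion_axes = c(draws$a[i], draws$b[i]),
                 lesion_center = c(draws$cr[i], draws$cc[i]),
                 lesion_contrast = draws$contrast[i],
                 edge_sigma = edge_sigma, speckle_scale = speckle_scale,
                 seed = draws$seeds[i])
  })
  labeled <- dplyr::bind_rows(purrr::imap(specs, function(sp, i) {
    dataset_row(make_phantom(sp, source_id = sprintf("lab_%04d", i)))
  }))
  unlabeled <- tibble::tibble(
    source_id = sprintf("unl_%04d", seq_len(n_unlabeled)),
    image = purrr::map(seq_len(n_unlabeled), function(i) {
      phantom_background(height, width, draws$seeds[n_labeled + i],
                         speckle_scale)
    })
  )
  spec_log <- tibble::tibble(
    source_id = sprintf("lab_%04d", seq_len(n_labeled)),
    axis_a = draws$a, axis_b = draws$b, center_row = draws$cr,
    center_col = draws$cc, contrast = draws$contrast,
    edge_sigma = edge_sigma, speckle_scale = speckle_scale,
    seed = draws$seeds[seq_len(n_labeled)]
  )
  list(labeled = labeled, unlabeled = unlabeled, spec_log = spec_log)
}

#' Write a phantom dataset to the standard directory layout
#'
#' Creates `images/`, `masks/` and `unlabeled/` under `out_dir` plus a
#' `spec_log.csv` of the drawn phantom parameters.
#'
#' @param dataset Result of [make_dataset()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "unlabeled"), recursive = TRUE,
             showWarnings = FALSE)
  purrr::pwalk(
    list(dataset$labeled$source_id, dataset$labeled$image,
         dataset$labeled$mask),
    function(stem, img, msk) {
      write_gray_png(img, file.path(out_dir, "images", paste0(stem, ".png")))
      write_gray_png(msk, file.path(out_dir, "masks", paste0(stem, ".png")))
    }
  )
  purrr::pwalk(list(dataset$unlabeled$source_id, dataset$unlabeled$image),
               function(stem, img) {
                 write_gray_png(img, file.path(out_dir, "unlabeled",
                                               paste0(stem, ".png")))
               })
  readr::write_csv(dataset$spec_log, file.path(out_dir, "spec_log.csv"))
  invisible(out_dir)
}
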
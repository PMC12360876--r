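# Dataset I/O. Directory layout:
#   images/  *.png   grayscale (or RGB) lesion images
#   masks/   *.png   binary masks, one per image, same file stem
#   unlabeled/ *.png lesion-free pool images
# Everything is normalized on load to the internal representation: float
# matrices in [0, 1], masks in {0, 1}.

# Raw luminance matrix from a PNG file, values on the scale png::readPNG
# returns (0..1 for 8-bit). RGB is collapsed with BT.601 luminance weights;
# an alpha channel is dropped.
read_png_luminance <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    ch <- dim(px)[3]
    if (ch >= 3L) {
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    } else {
      px <- px[, , 1]
    }
  }
  px
}

# Per-file min-max normalization; constant images map to all-zero.
normalize_minmax <- function(x) {
  rng <- max(x) - min(x)
  if (rng == 0) return(array(0, dim(x)))
  (x - min(x)) / rng
}

read_gray_png <- function(path) {
  img <- normalize_minmax(read_png_luminance(path))
  check_gray_image(img, arg = basename(path))
  img
}

# Masks binarize at half the file's dynamic range (robust to anti-aliased
# PNGs); constant files become all-background.
read_mask_png <- function(path) {
  v <- read_png_luminance(path)
  rng <- max(v) - min(v)
  if (rng == 0) {
    m <- array(0, dim(v))
  } else {
    m <- (v >= min(v) + 0.5 * rng) * 1
  }
  m
}

list_png_stems <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", ignore.case = TRUE))
  stats::setNames(files, tools::file_path_sans_ext(files))
}

#' Load a labeled image/mask dataset from disk
#'
#' Reads every PNG under `images_dir` and its mask (same file stem) under
#' `masks_dir`. Images are min-max normalized per file to `[0, 1]` (RGB files
#' are first converted to luminance); masks are binarized at half their
#' dynamic range.
#'
#' @param images_dir,masks_dir Directories of PNG files with matching stems.
#' @return A dataset tibble (see [samples_tibble()]) with one row per stem,
#'   sorted by stem, `strategy = "original"`.
#' @export
load_labeled_dataset <- function(images_dir, masks_dir) {
  imgs <- list_png_stems(images_dir)
  if (length(imgs) == 0L) stop_usmix("No PNG images in ", images_dir, ".")
  msks <- list_png_stems(masks_dir)
  missing <- setdiff(names(imgs), names(msks))
  if (length(missing) > 0L) {
    stop_usmix("Missing mask file(s) for stem(s): ",
               paste(missing, collapse = ", "), ".")
  }
  rows <- purrr::map(names(imgs), function(stem) {
    img <- read_gray_png(file.path(images_dir, imgs[[stem]]))
    msk <- read_mask_png(file.path(masks_dir, msks[[stem]]))
    if (!identical(dim(img), dim(msk))) {
      stop_usmix("Image/mask dimension mismatch for stem '", stem, "': ",
                 nrow(img), "x", ncol(img), " vs ",
                 nrow(msk), "x", ncol(msk), ".")
    }
    dataset_row(labeled_sample(img, msk, source_id = stem))
  })
  dplyr::bind_rows(rows)
}

#' Load an unlabeled image pool from disk
#'
#' @param images_dir Directory of PNG files.
#' @return A tibble with columns `source_id` and `image` (list of matrices).
#' @export
load_unlabeled_pool <- function(images_dir) {
  imgs <- list_png_stems(images_dir)
  if (length(imgs) == 0L) {
    stop_usmix("Unlabeled pool directory ", images_dir, " is empty.")
  }
  tibble::tibble(
    source_id = names(imgs),
    image = purrr::map(names(imgs), function(stem) {
      read_gray_png(file.path(images_dir, imgs[[stem]]))
    })
  )
}

# --- resizing ---------------------------------------------------------------

# Map output pixel centers onto input pixel centers (1-based, center-aligned).
resize_src_coords <- function(n_out, n_in) {
  s <- n_in / n_out
  pmin(pmax((seq_len(n_out) - 0.5) * s + 0.5, 1), n_in)
}

resize_bilinear <- function(x, height, width) {
  r <- resize_src_coords(height, nrow(x))
  c <- resize_src_coords(width, ncol(x))
  r0 <- pmin(floor(r), nrow(x) - 1L); r1 <- r0 + 1; fr <- r - r0
  c0 <- pmin(floor(c), ncol(x) - 1L); c1 <- c0 + 1; fc <- c - c0
  if (nrow(x) == 1L) { r0 <- r1 <- rep(1, height); fr <- rep(0, height) }
  if (ncol(x) == 1L) { c0 <- c1 <- rep(1, width); fc <- rep(0, width) }
  a <- x[r0, c0, drop = FALSE] * (1 - fr) + x[r1, c0, drop = FALSE] * fr
  b <- x[r0, c1, drop = FALSE] * (1 - fr) + x[r1, c1, drop = FALSE] * fr
  sweep(a, 2, 1 - fc, "*") + sweep(b, 2, fc, "*")
}

resize_nearest <- function(x, height, width) {
  r <- pmin(pmax(round(resize_src_coords(height, nrow(x))), 1), nrow(x))
  c <- pmin(pmax(round(resize_src_coords(width, ncol(x))), 1), ncol(x))
  x[r, c, drop = FALSE]
}

#' Resize an image or mask
#'
#' Images are resampled with bilinear interpolation; masks use
#' nearest-neighbor and are re-binarized, so the output stays in `{0, 1}`.
#' The standard working resolution in this package is 224x224.
#'
#' @param x Numeric matrix (image in `[0,1]` or mask in `{0,1}`).
#' @param height,width Target dimensions (>= 8).
#' @param kind `"image"` (bilinear) or `"mask"` (nearest-neighbor).
#' @return A `height` x `width` matrix.
#' @export
resize_to <- function(x, height, width, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (height < 8 || width < 8) {
    stop_usmix("Target dimensions must be at least 8x8.")
  }
  if (identical(c(nrow(x), ncol(x)), c(as.integer(height), as.integer(width)))) {
    return(x)
  }
  if (kind == "mask") {
    out <- resize_nearest(x, height, width)
    (out >= 0.5) * 1
  } else {
    clamp01(resize_bilinear(x, height, width))
  }
}

#' Resize a labeled sample (image bilinear, mask nearest-neighbor)
#'
#' @param sample A `us_sample` or one-row dataset tibble.
#' @param height,width Target dimensions.
#' @return A `us_sample` at the new resolution.
#' @export
resize_sample <- function(sample, height = 224, width = 224) {
  s <- as_sample(sample)
  labeled_sample(
    resize_to(s$image, height, width, kind = "image"),
    resize_to(s$mask, height, width, kind = "mask"),
    source_id = s$source_id
  )
}

# --- writing ----------------------------------------------------------------

# 8-bit quantization applied before writePNG so the on-disk values are
# exactly round(p * 255).
quantize8 <- function(x) round(x * 255) / 255

write_gray_png <- function(x, path) {
  png::writePNG(quantize8(clamp01(x)), target = path)
}

#' Write a dataset and its provenance manifest to disk
#'
#' Writes `images/<stem>.png` and `masks/<stem>.png` (8-bit grayscale) for
#' every row and a `manifest.csv` recording strategy, sources, parameters
#' (as JSON) and seed, from which every augmented sample can be regenerated
#' bit-exactly with [replay_sample()].
#'
#' @param dataset A dataset tibble (see [samples_tibble()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly written as `manifest.csv`.
#' @export
write_augmented_dataset <- function(dataset, out_dir) {
  stems <- dataset$source_id
  if (anyDuplicated(stems)) {
    stop_usmix("Output stem collision: ",
               paste(unique(stems[duplicated(stems)]), collapse = ", "), ".")
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  purrr::pwalk(list(stems, dataset$image, dataset$mask), function(stem, img, msk) {
    write_gray_png(img, file.path(out_dir, "images", paste0(stem, ".png")))
    write_gray_png(msk, file.path(out_dir, "masks", paste0(stem, ".png")))
  })
  manifest <- tibble::tibble(
    output_stem = stems,
    strategy = dataset$strategy,
    labeled_source = dataset$labeled_source,
    unlabeled_source = dataset$unlabeled_source,
    params_json = purrr::map_chr(dataset$params, function(p) {
      as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA))
    }),
    seed = dataset$seed
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read a dataset manifest written by [write_augmented_dataset()]
#'
#' @param path Path to a `manifest.csv` or its containing directory.
#' @return The manifest tibble.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  readr::read_csv(path, col_types = readr::cols(
    output_stem = readr::col_character(),
    strategy = readr::col_character(),
    labeled_source = readr::col_character(),
    unlabeled_source = readr::col_character(),
    params_json = readr::col_character(),
    seed = readr::col_integer()
  ))
}

#' Regenerate a sample from its manifest record
#'
#' Every augmented sample is a deterministic function of its labeled source,
#' its unlabeled partner (mixed strategies), its parameters, and its seed
#' (traditional baselines), so a manifest row replays to a bit-identical
#' sample.
#'
#' @param manifest_row One row of a manifest tibble.
#' @param labeled Dataset tibble holding the labeled sources.
#' @param pool Unlabeled pool tibble (needed for mixed strategies).
#' @return A `us_sample` or `us_aug_sample`.
#' @export
replay_sample <- function(manifest_row, labeled, pool = NULL) {
  stopifnot(nrow(manifest_row) == 1L)
  strat <- manifest_row$strategy
  lab_row <- labeled[labeled$source_id == manifest_row$labeled_source, ]
  if (nrow(lab_row) != 1L) {
    stop_usmix("Labeled source '", manifest_row$labeled_source,
               "' not found (or not unique) in the labeled dataset.")
  }
  lab <- as_sample(lab_row)
  if (strat == "original") return(lab)
  params <- jsonlite::fromJSON(manifest_row$params_json)
  if (strat %in% MIXED_STRATEGIES) {
    if (is.null(pool)) stop_usmix("A pool is required to replay '", strat, "'.")
    u_row <- pool[pool$source_id == manifest_row$unlabeled_source, ]
    if (nrow(u_row) != 1L) {
      stop_usmix("Unlabeled source '", manifest_row$unlabeled_source,
                 "' not found in the pool.")
    }
    mp <- do.call(mix_params, params[names(params) %in%
                                       c("alpha", "beta", "gamma", "sigma",
                                         "pixmix2_overflow")])
    fn <- switch(strat,
                 pixmix = pixmix, segmix2 = segmix2,
                 lesionblend = lesionblend, lesionblend2 = lesionblend2,
                 pixmix2 = pixmix2)
    return(fn(lab, u_row, mp))
  }
  if (strat %in% BASELINE_STRATEGIES) {
    bp <- do.call(baseline_params, params[names(params) %in%
                                            c("angle_range", "shift_fraction",
                                              "noise_var_range", "flip_prob")])
    fn <- switch(strat,
                 rotation = rotate_pair, translation = translate_pair,
                 gaussian_noise = gaussian_noise_pair)
    return(fn(lab, rng_seed = manifest_row$seed, params = bp))
  }
  if (strat == "hflip") {
    return(hflip_pair(lab, rng_seed = manifest_row$seed,
                      flip_prob = params$flip_prob %||% 0.5))
  }
  stop_usmix("Unknown strategy '", strat, "' in manifest.")
}
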
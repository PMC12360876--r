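#' Construct a labeled image/mask sample
#'
#' A labeled sample pairs a grayscale ultrasound image with its binary lesion
#' mask. Images are numeric matrices in `[0, 1]` (rows = image rows); masks
#' are matrices over `{0, 1}` of the same dimensions.
#'
#' @param image Numeric matrix in `[0, 1]`, at least 8x8.
#' @param mask Numeric matrix over `{0, 1}` with the same dimensions.
#' @param source_id Character identifier (typically the file stem).
#' @return An object of class `us_sample`: a list with elements `image`,
#'   `mask` and `source_id`.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' msk <- matrix(0, 8, 8); msk[3:5, 3:5] <- 1
#' labeled_sample(img, msk, "toy")
#' @export
labeled_sample <- function(image, mask, source_id = "sample") {
  check_gray_image(image)
  check_binary_mask(mask)
  check_same_dim(image, mask, c("image", "mask"))
  structure(
    list(image = image, mask = mask, source_id = as.character(source_id)),
    class = "us_sample"
  )
}

# Internal constructor for augmented (pseudolabeled) samples. The mask is the
# source mask object itself except for the geometric baselines, which
# transform it jointly with the image.
augmented_sample <- function(image, mask, strategy, labeled_source_id,
                             unlabeled_source_id = NA_character_,
                             params = list(), seed = NA_integer_) {
  structure(
    list(
      image = image, mask = mask,
      source_id = NA_character_,
      strategy = strategy,
      labeled_source_id = labeled_source_id,
      unlabeled_source_id = unlabeled_source_id,
      params = params,
      seed = seed
    ),
    class = c("us_aug_sample", "us_sample")
  )
}

#' Coerce to a labeled sample
#'
#' Accepts a `us_sample`, a one-row dataset tibble (as returned by
#' [load_labeled_dataset()] or [make_dataset()]), or a bare list with
#' `image`/`mask` elements.
#'
#' @param x Object to coerce.
#' @return A `us_sample`.
#' @export
as_sample <- function(x) {
  if (inherits(x, "us_sample")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop_usmix("as_sample() needs a single row, got ", nrow(x), ".")
    }
    return(labeled_sample(x$image[[1]], x$mask[[1]],
                          source_id = x$source_id[[1]]))
  }
  if (is.list(x) && !is.null(x$image) && !is.null(x$mask)) {
    return(labeled_sample(x$image, x$mask,
                          source_id = x$source_id %||% "sample"))
  }
  stop_usmix("Cannot interpret object of class '", class(x)[1],
             "' as a labeled sample.")
}

# Pull an unlabeled image out of whatever the caller handed us: a matrix, a
# one-row pool tibble, or a list with $image. Returns list(image, source_id).
as_unlabeled <- function(x) {
  if (is.matrix(x)) return(list(image = x, source_id = NA_character_))
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop_usmix("Expected a single unlabeled image row.")
    return(list(image = x$image[[1]],
                source_id = as.character(x$source_id[[1]])))
  }
  if (is.list(x) && !is.null(x$image)) {
    return(list(image = x$image,
                source_id = as.character(x$source_id %||% NA_character_)))
  }
  stop_usmix("Cannot interpret object of class '", class(x)[1],
             "' as an unlabeled image.")
}

#' @export
print.us_sample <- function(x, ...) {
  cat("<us_sample> ", x$source_id, ": ", nrow(x$image), "x", ncol(x$image),
      ", lesion pixels = ", sum(x$mask), "\n", sep = "")
  invisible(x)
}

#' @export
print.us_aug_sample <- function(x, ...) {
  cat("<us_aug_sample> strategy = ", x$strategy,
      ", labeled source = ", x$labeled_source_id,
      if (!is.na(x$unlabeled_source_id))
        paste0(", unlabeled source = ", x$unlabeled_source_id),
      "\n", sep = "")
  invisible(x)
}

# One tibble schema is used for every dataset in the package.
dataset_row <- function(sample, source_id = NULL) {
  if (inherits(sample, "us_aug_sample")) {
    tibble::tibble(
      source_id = source_id %||% sample$source_id,
      image = list(sample$image),
      mask = list(sample$mask),
      strategy = sample$strategy,
      labeled_source = sample$labeled_source_id,
      unlabeled_source = sample$unlabeled_source_id,
      params = list(sample$params),
      seed = as.integer(sample$seed)
    )
  } else {
    tibble::tibble(
      source_id = source_id %||% sample$source_id,
      image = list(sample$image),
      mask = list(sample$mask),
      strategy = "original",
      labeled_source = sample$source_id,
      unlabeled_source = NA_character_,
      params = list(list()),
      seed = NA_integer_
    )
  }
}

#' Bind samples into a dataset tibble
#'
#' @param samples A list of `us_sample` / `us_aug_sample` objects.
#' @param source_ids Optional character vector of output stems.
#' @return A tibble with columns `source_id`, `image`, `mask`, `strategy`,
#'   `labeled_source`, `unlabeled_source`, `params`, `seed`.
#' @export
samples_tibble <- function(samples, source_ids = NULL) {
  rows <- purrr::imap(samples, function(s, i) {
    dataset_row(s, source_id = if (!is.null(source_ids)) source_ids[[i]])
  })
  dplyr::bind_rows(rows)
}
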
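# Segmentation evaluation: Jaccard index JI = TP / (TP + FP + FN), Dice =
# 2 TP / (2 TP + FP + FN), and the 95th-percentile Hausdorff distance
# between boundary point sets.

#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,truth Binary mask matrices of equal dimensions.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn` summing to
#'   the pixel count.
#' @export
confusion <- function(pred, truth) {
  check_binary_mask(pred, "pred")
  check_binary_mask(truth, "truth")
  check_same_dim(pred, truth, c("pred", "truth"))
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn)
}

counts_of <- function(counts) {
  if (is.matrix(counts)) counts <- confusion_pair_error(counts)
  list(tp = counts$tp, fp = counts$fp, fn = counts$fn)
}

confusion_pair_error <- function(x) {
  stop_usmix("Pass the result of confusion(), not a raw mask.")
}

#' Jaccard index from confusion counts
#'
#' `JI = TP / (TP + FP + FN)`. When both masks are empty the overlap is
#' vacuously perfect: 1 is returned with a warning.
#'
#' @param counts Result of [confusion()] (or any list with `tp`, `fp`,
#'   `fn`).
#' @return A proportion in `[0, 1]`.
#' @export
jaccard <- function(counts) {
  k <- counts_of(counts)
  denom <- k$tp + k$fp + k$fn
  if (denom == 0) {
    warn("Both masks are empty; Jaccard index defined as 1.")
    return(1)
  }
  k$tp / denom
}

#' Dice coefficient from confusion counts
#'
#' `Dice = 2 TP / (2 TP + FP + FN)`; algebraically `2 J / (1 + J)`.
#'
#' @inheritParams jaccard
#' @return A proportion in `[0, 1]`.
#' @export
dice <- function(counts) {
  k <- counts_of(counts)
  denom <- 2 * k$tp + k$fp + k$fn
  if (denom == 0) {
    warn("Both masks are empty; Dice coefficient defined as 1.")
    return(1)
  }
  2 * k$tp / denom
}

#' Extract the boundary pixels of a binary mask
#'
#' Boundary = mask pixels minus the 4-connected erosion of the mask, with
#' the outside of the frame treated as background (so a full-frame mask has
#' its border pixels as boundary).
#'
#' @param mask Non-empty binary mask matrix.
#' @return A tibble with columns `row`, `col` (1-based pixel coordinates).
#' @export
extract_boundary <- function(mask) {
  check_binary_mask(mask)
  if (sum(mask) == 0) stop_usmix("Cannot extract the boundary of an empty mask.")
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  interior <- core * pad[1:h, 2:(w + 1)] * pad[3:(h + 2), 2:(w + 1)] *
    pad[2:(h + 1), 1:w] * pad[2:(h + 1), 3:(w + 2)]
  idx <- which(core == 1 & interior == 0, arr.ind = TRUE)
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]))
}

# Order-statistic percentile with ceiling ("higher") interpolation: always
# an attained distance, equal to the maximum whenever
# p/100 >= (n-1)/n — i.e. for HD95 whenever a boundary has <= 20 points.
percentile_higher <- function(x, p) {
  n <- length(x)
  if (n == 1L) return(x)
  sort(x)[min(n, ceiling(p / 100 * (n - 1)) + 1L)]
}

directed_min_dists <- function(a, b) {
  d2 <- outer(a$row, b$row, "-")^2 + outer(a$col, b$col, "-")^2
  sqrt(apply(d2, 1, min))
}

#' 95th-percentile Hausdorff distance between two masks
#'
#' Boundary point sets are extracted from both masks; in each direction the
#' per-point minimum Euclidean distance to the other boundary is reduced to
#' its `percentile`-th order statistic (ceiling interpolation), and the two
#' directions are combined by `max`. `percentile = 100` gives the classical
#' Hausdorff distance. Distances are in pixel units between pixel centers.
#'
#' If exactly one mask is empty the image diagonal length is returned as a
#' defined penalty; if both are empty the distance is 0.
#'
#' @param pred,truth Binary mask matrices of equal dimensions.
#' @param percentile Percentile in `(0, 100]`, default 95.
#' @return A non-negative distance in pixels; 0 for identical masks.
#' @export
hd95 <- function(pred, truth, percentile = 95) {
  check_binary_mask(pred, "pred")
  check_binary_mask(truth, "truth")
  check_same_dim(pred, truth, c("pred", "truth"))
  if (percentile <= 0 || percentile > 100) {
    stop_usmix("`percentile` must lie in (0, 100].")
  }
  ep <- sum(pred) == 0; et <- sum(truth) == 0
  if (ep && et) return(0)
  if (ep || et) return(sqrt(nrow(pred)^2 + ncol(pred)^2))
  a <- extract_boundary(pred)
  b <- extract_boundary(truth)
  max(percentile_higher(directed_min_dists(a, b), percentile),
      percentile_higher(directed_min_dists(b, a), percentile))
}

#' Evaluate predicted masks against ground truth
#'
#' Accepts either two directories of mask PNGs (matched by file stem) or two
#' dataset/pool-style tibbles with `source_id` and `mask` list-columns.
#'
#' @param pred,truth Directories or tibbles of binary masks.
#' @param percentile Hausdorff percentile (see [hd95()]).
#' @return A tibble of class `us_metrics` with one row per mask pair:
#'   `stem`, `jaccard`, `dice`, `hd95`, `empty_flag` (TRUE when either mask
#'   is empty, i.e. the Hausdorff penalty or the empty-overlap convention
#'   applied).
#' @export
evaluate_masks <- function(pred, truth, percentile = 95) {
  as_mask_set <- function(x, role) {
    if (is.character(x) && length(x) == 1L && dir.exists(x)) {
      stems <- list_png_stems(x)
      if (length(stems) == 0L) stop_usmix("No PNG masks found in ", x, ".")
      tibble::tibble(
        source_id = names(stems),
        mask = purrr::map(names(stems),
                          function(s) read_mask_png(file.path(x, stems[[s]])))
      )
    } else if (is.data.frame(x)) {
      tibble::tibble(source_id = x$source_id, mask = x$mask)
    } else {
      stop_usmix("`", role, "` must be a directory path or a tibble with ",
                 "`source_id` and `mask` columns.")
    }
  }
  p <- as_mask_set(pred, "pred")
  t <- as_mask_set(truth, "truth")
  common <- intersect(p$source_id, t$source_id)
  if (length(common) == 0L) stop_usmix("No common stems to evaluate.")
  rows <- purrr::map(sort(common), function(stem) {
    pm <- p$mask[[match(stem, p$source_id)]]
    tm <- t$mask[[match(stem, t$source_id)]]
    empty <- sum(pm) == 0 || sum(tm) == 0
    cc <- confusion(pm, tm)
    j <- withCallingHandlers(jaccard(cc),
                             warning = function(w) invokeRestart("muffleWarning"))
    d <- withCallingHandlers(dice(cc),
                             warning = function(w) invokeRestart("muffleWarning"))
    tibble::tibble(stem = stem, jaccard = j, dice = d,
                   hd95 = hd95(pm, tm, percentile = percentile),
                   empty_flag = empty)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("us_metrics", class(out))
  out
}

#' @export
tidy.us_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.us_metrics <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    mean_jaccard = mean(x$jaccard), sd_jaccard = sd(x$jaccard),
    mean_dice = mean(x$dice), sd_dice = sd(x$dice),
    mean_hd95 = mean(x$hd95), sd_hd95 = sd(x$hd95),
    n_empty = sum(x$empty_flag)
  )
}

#' Write a per-image metrics report with a mean/stdev footer
#'
#' @param metrics A `us_metrics` tibble from [evaluate_masks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path) {
  body <- tidy(metrics)
  footer <- tibble::tibble(
    stem = c("mean", "stdev"),
    jaccard = c(mean(body$jaccard), sd(body$jaccard)),
    dice = c(mean(body$dice), sd(body$dice)),
    hd95 = c(mean(body$hd95), sd(body$hd95)),
    empty_flag = NA
  )
  readr::write_csv(dplyr::bind_rows(body, footer), path)
  invisible(path)
}
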
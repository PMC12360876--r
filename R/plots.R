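# ggplot2 displays for samples and metric reports.

sample_to_long <- function(image) {
  tibble::tibble(
    row = rep(seq_len(nrow(image)), times = ncol(image)),
    col = rep(seq_len(ncol(image)), each = nrow(image)),
    intensity = as.vector(image)
  )
}

#' Plot a sample as a grayscale raster with its mask outline
#'
#' @param object A `us_sample` or `us_aug_sample`.
#' @param show_mask Overlay the lesion mask outline (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.us_sample <- function(object, show_mask = TRUE, ...) {
  df <- sample_to_long(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity",
                  title = object$strategy %||% object$source_id)
  if (show_mask && sum(object$mask) > 0) {
    mdf <- sample_to_long(object$mask)
    p <- p + ggplot2::geom_contour(
      data = mdf,
      ggplot2::aes(z = .data$intensity),
      breaks = 0.5, colour = "red", linewidth = 0.4
    )
  }
  p
}

#' @export
autoplot.us_aug_sample <- autoplot.us_sample

#' Boxplots of per-image segmentation metrics
#'
#' @param object A `us_metrics` tibble from [evaluate_masks()].
#' @param ... Unused.
#' @return A ggplot object with one panel per metric (overlap metrics share
#'   the unit scale; HD95 is in pixels).
#' @export
autoplot.us_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              cols = c("jaccard", "dice", "hd95"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Segmentation metrics")
}

#' Side-by-side gallery of one labeled sample under every mixed strategy
#'
#' @param labeled A labeled sample.
#' @param unlabeled An unlabeled partner image.
#' @param params A [mix_params()].
#' @return A ggplot object faceted by strategy (original + five strategies).
#' @export
plot_strategy_gallery <- function(labeled, unlabeled,
                                  params = mix_params()) {
  lab <- as_sample(labeled)
  frames <- c(
    list(original = lab),
    stats::setNames(
      purrr::map(MIXED_STRATEGIES, function(st) {
        apply_mixed_strategy(st, lab, unlabeled, params)
      }),
      MIXED_STRATEGIES
    )
  )
  df <- dplyr::bind_rows(purrr::imap(frames, function(s, nm) {
    dplyr::mutate(sample_to_long(s$image), panel = nm)
  }))
  df$panel <- factor(df$panel, levels = names(frames))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel, nrow = 2) +
    ggplot2::theme_void()
}

#' @importFrom rlang .data
NULL
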
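# Dataset-expansion protocol: sample a small labeled fraction (5/10/20% in
# the canonical experiments), then generate pseudolabeled samples with a
# single strategy until the expanded set regains the full training-set size.

ALL_STRATEGIES <- c(MIXED_STRATEGIES, BASELINE_STRATEGIES)

#' Define an expansion plan
#'
#' @param strategy One augmentation strategy per plan (mixed or baseline).
#' @param target_size Total size of the expanded dataset (originals plus
#'   generated samples).
#' @param seed Integer seed governing all pairing and per-sample draws.
#' @param fraction Labeled fraction the plan corresponds to (bookkeeping;
#'   the subset itself is drawn with [sample_subset()]).
#' @param params A [mix_params()] (mixed strategies) or [baseline_params()]
#'   (baselines); defaults are filled in by strategy family.
#' @return A `us_expansion_plan` list.
#' @export
expansion_plan <- function(strategy, target_size, seed, fraction = NA_real_,
                           params = NULL) {
  strategy <- match.arg(strategy, ALL_STRATEGIES)
  if (!is.numeric(target_size) || length(target_size) != 1L ||
      target_size < 1) {
    stop_usmix("`target_size` must be a positive count.")
  }
  if (!is.na(fraction) && (fraction <= 0 || fraction > 1)) {
    stop_usmix("`fraction` must lie in (0, 1].")
  }
  if (is.null(params)) {
    params <- if (strategy %in% MIXED_STRATEGIES) mix_params() else
      baseline_params()
  }
  structure(
    list(strategy = strategy, target_size = as.integer(target_size),
         seed = as.integer(seed), fraction = fraction, params = params),
    class = "us_expansion_plan"
  )
}

#' Draw a random labeled subset
#'
#' Simple random sample without replacement of `round(fraction * n)` items
#' (half-up rounding, so 5% of 414 gives 21). The dataset is sorted by
#' `source_id` before sampling, making the draw independent of input
#' ordering.
#'
#' @param dataset A labeled dataset tibble.
#' @param fraction Proportion in `(0, 1]`.
#' @param seed Integer seed.
#' @return A tibble of the sampled rows, sorted by `source_id`.
#' @export
sample_subset <- function(dataset, fraction, seed) {
  if (fraction <= 0 || fraction > 1) {
    stop_usmix("`fraction` must lie in (0, 1].")
  }
  n <- nrow(dataset)
  k <- round_half_up(fraction * n)
  if (k < 1) {
    stop_usmix("fraction ", fraction, " of ", n,
               " samples yields an empty subset.")
  }
  ds <- dataset[order(dataset$source_id), ]
  idx <- with_seed(seed, sort(sample.int(n, k)))
  ds[idx, ]
}

#' Expand a labeled subset with pseudolabeled samples
#'
#' Returns the subset unchanged plus `target_size - nrow(subset)` generated
#' samples. Labeled sources are cycled round-robin over the subset so each
#' contributes nearly equally; unlabeled partners are drawn uniformly with
#' replacement from the pool, never pairing an image with itself. Mixed
#' strategies are deterministic given their partner; baseline strategies
#' receive per-sample seeds. All draws derive from `plan$seed`, and the
#' pairing sequence depends only on the seed and the subset/pool sizes, so
#' plans differing only in mixing weights share identical pairings.
#'
#' @param subset Labeled dataset tibble (from [sample_subset()]).
#' @param pool Unlabeled pool tibble (`source_id`, `image`).
#' @param plan An [expansion_plan()].
#' @return A dataset tibble of exactly `plan$target_size` rows: the original
#'   subset (`strategy = "original"`) followed by the generated samples.
#' @export
expand_dataset <- function(subset, pool, plan) {
  n_s <- nrow(subset)
  n_p <- nrow(pool)
  if (n_p == 0L) stop_usmix("The unlabeled pool is empty.")
  if (plan$target_size < n_s) {
    stop_usmix("`target_size` (", plan$target_size,
               ") is smaller than the subset (", n_s, ").")
  }
  n_aug <- plan$target_size - n_s
  if (n_aug == 0L) return(subset)

  lab_idx <- rep_len(seq_len(n_s), n_aug)
  lab_ids <- subset$source_id[lab_idx]
  pool_ids <- pool$source_id

  draws <- with_seed(plan$seed, {
    u_idx <- sample.int(n_p, n_aug, replace = TRUE)
    bad <- which(pool_ids[u_idx] == lab_ids)
    guard <- 0L
    while (length(bad) > 0L) {
      guard <- guard + 1L
      if (guard > 1000L) {
        stop_usmix("Cannot avoid self-pairing: the pool offers no partner ",
                   "other than the labeled image itself.")
      }
      u_idx[bad] <- sample.int(n_p, length(bad), replace = TRUE)
      bad <- bad[pool_ids[u_idx[bad]] == lab_ids[bad]]
    }
    list(u_idx = u_idx,
         seeds = sample.int(.Machine$integer.max - 1L, n_aug))
  })

  mixed <- plan$strategy %in% MIXED_STRATEGIES
  aug_rows <- purrr::map(seq_len(n_aug), function(i) {
    lab <- as_sample(subset[lab_idx[i], ])
    if (mixed) {
      s <- apply_mixed_strategy(plan$strategy, lab, pool[draws$u_idx[i], ],
                                params = plan$params)
    } else {
      s <- apply_baseline_strategy(plan$strategy, lab,
                                   rng_seed = draws$seeds[i],
                                   params = plan$params)
    }
    dataset_row(s, source_id = sprintf("%s__%s_%04d", lab$source_id,
                                       plan$strategy, i))
  })
  dplyr::bind_rows(subset, dplyr::bind_rows(aug_rows))
}

#' Sweep PixMix mixing weights over shared pairings
#'
#' Runs [expand_dataset()] once per `alpha` with `beta = 1 - alpha`, reusing
#' the same pairing seed so the per-setting datasets differ only in the
#' mixing weights: between settings `a1` and `a2` every generated image
#' differs pixelwise by exactly `(a1 - a2) * (I_L - I_U)`.
#'
#' @param subset Labeled dataset tibble.
#' @param pool Unlabeled pool tibble.
#' @param alphas Numeric vector of weights in `(0, 1)` (canonical grid:
#'   0.6, 0.7, 0.8).
#' @param seed Shared pairing seed.
#' @param target_size Expanded size per setting.
#' @param sigma Mask-smoothing scale passed through to [mix_params()].
#' @return A tibble with columns `alpha`, `beta` and `dataset` (list of
#'   expanded dataset tibbles).
#' @export
run_alpha_beta_sweep <- function(subset, pool, alphas = c(0.6, 0.7, 0.8),
                                 seed = 1L, target_size, sigma = 5) {
  if (any(alphas <= 0 | alphas >= 1)) {
    stop_usmix("All `alphas` must lie strictly in (0, 1).")
  }
  tibble::tibble(
    alpha = alphas,
    beta = 1 - alphas,
    dataset = purrr::map(alphas, function(a) {
      plan <- expansion_plan("pixmix", target_size = target_size, seed = seed,
                             params = mix_params(alpha = a, sigma = sigma))
      expand_dataset(subset, pool, plan)
    })
  )
}

# When no separate unlabeled pool exists, the labeled images NOT drawn into
# the subset serve as the pool with their masks hidden.
pool_from_remainder <- function(dataset, subset) {
  rest <- dataset[!dataset$source_id %in% subset$source_id, ]
  tibble::tibble(source_id = rest$source_id, image = rest$image)
}
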
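# End-to-end workflow: synth (or load) -> subset -> expand per strategy ->
# optional evaluation, with one master seed, a YAML-able config, and a
# provenance log. Everything written is a pure function of the config, so
# two runs with the same config produce byte-identical artifact trees.

CONFIG_DEFAULTS <- list(
  out_dir = "usmix_run",
  seed = 1L,
  force = FALSE,
  # real data (optional; synthetic phantoms are used when absent)
  images_dir = NULL, masks_dir = NULL, unlabeled_dir = NULL,
  # synthetic data
  n_labeled = 20L, n_unlabeled = 100L, height = 224L, width = 224L,
  # expansion
  fraction = 0.05, strategy = "all", target_size = NULL,
  # mixing / baseline parameters
  alpha = 0.8, beta = NULL, gamma = 0.5, sigma = 5,
  pixmix2_overflow = "rescale",
  angle_range = c(15, 345), shift_fraction = 0.20,
  noise_var_range = c(10, 50), flip_prob = 0.5,
  # evaluation
  hd_percentile = 95, pred_dir = NULL, truth_dir = NULL
)

#' Build and validate a pipeline configuration
#'
#' Settings may come from a YAML file, from named arguments, or both
#' (arguments override the file). Unknown keys are rejected.
#'
#' @param ... Named settings (see Details in [run_pipeline()]).
#' @param file Optional YAML file of settings.
#' @return A validated `us_run_config` list.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- CONFIG_DEFAULTS
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(CONFIG_DEFAULTS))
    if (length(unknown) > 0L) {
      stop_usmix("Unknown config key(s) in ", file, ": ",
                 paste(unknown, collapse = ", "), ".")
    }
    cfg <- modifyList(cfg, from_file)
  }
  args <- list(...)
  if (length(args) > 0L && (is.null(names(args)) || any(names(args) == ""))) {
    stop_usmix("All config settings must be named.")
  }
  unknown <- setdiff(names(args), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L) {
    stop_usmix("Unknown config key(s): ", paste(unknown, collapse = ", "), ".")
  }
  cfg <- modifyList(cfg, args)
  if (is.null(cfg$beta)) cfg$beta <- 1 - cfg$alpha
  if (!cfg$strategy %in% c("all", ALL_STRATEGIES)) {
    stop_usmix("`strategy` must be 'all' or one of: ",
               paste(ALL_STRATEGIES, collapse = ", "), ".")
  }
  if (cfg$fraction <= 0 || cfg$fraction > 1) {
    stop_usmix("`fraction` must lie in (0, 1].")
  }
  # validate parameter blocks eagerly, before any I/O
  mix_params(alpha = cfg$alpha, beta = cfg$beta, gamma = cfg$gamma,
             sigma = cfg$sigma, pixmix2_overflow = cfg$pixmix2_overflow)
  baseline_params(angle_range = cfg$angle_range,
                  shift_fraction = cfg$shift_fraction,
                  noise_var_range = cfg$noise_var_range,
                  flip_prob = cfg$flip_prob)
  structure(cfg, class = "us_run_config")
}

#' Run the full augmentation pipeline
#'
#' Stages: (1) load the labeled dataset and unlabeled pool from
#' `images_dir`/`masks_dir`/`unlabeled_dir`, or synthesize a phantom corpus
#' (written under `out_dir/synth`) when no directories are given; (2) draw
#' the labeled subset of size `round(fraction * n)`; (3) expand the subset
#' to `target_size` (default: the full labeled size) once per strategy
#' (`strategy = "all"` runs the five mixed strategies over a shared
#' subset), writing each expanded dataset with its manifest under
#' `out_dir/expanded_<strategy>`; (4) when `pred_dir` and `truth_dir` are
#' set, evaluate them and write `metrics.csv`. A `run_log.yaml` records
#' every parameter and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `subset`, `manifests` (named by
#'   strategy), `metrics` (or `NULL`) and `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "us_run_config")) config <- do.call(run_config, config)
  out <- config$out_dir
  if (dir.exists(out) && length(list.files(out, recursive = TRUE)) > 0L &&
      !isTRUE(config$force)) {
    stop_usmix("Output directory ", out,
               " is not empty; set force = TRUE to overwrite.")
  }
  if (isTRUE(config$force) && dir.exists(out)) {
    unlink(out, recursive = TRUE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # --- data ---
  if (!is.null(config$images_dir)) {
    labeled <- load_labeled_dataset(config$images_dir, config$masks_dir)
    pool <- if (!is.null(config$unlabeled_dir)) {
      load_unlabeled_pool(config$unlabeled_dir)
    }
  } else {
    synth <- make_dataset(config$n_labeled, config$n_unlabeled,
                          seed = config$seed, height = config$height,
                          width = config$width)
    write_phantom_dataset(synth, file.path(out, "synth"))
    labeled <- synth$labeled
    pool <- if (nrow(synth$unlabeled) > 0L) synth$unlabeled
  }

  # --- subset ---
  subset <- sample_subset(labeled, config$fraction, seed = config$seed)
  readr::write_csv(tibble::tibble(source_id = subset$source_id),
                   file.path(out, "subset.csv"))
  if (is.null(pool)) pool <- pool_from_remainder(labeled, subset)

  # --- expansion ---
  strategies <- if (config$strategy == "all") MIXED_STRATEGIES else
    config$strategy
  target <- config$target_size %||% nrow(labeled)
  manifests <- purrr::map(strategies, function(st) {
    params <- if (st %in% MIXED_STRATEGIES) {
      mix_params(alpha = config$alpha, beta = config$beta,
                 gamma = config$gamma, sigma = config$sigma,
                 pixmix2_overflow = config$pixmix2_overflow)
    } else {
      baseline_params(angle_range = config$angle_range,
                      shift_fraction = config$shift_fraction,
                      noise_var_range = config$noise_var_range,
                      flip_prob = config$flip_prob)
    }
    plan <- expansion_plan(st, target_size = target, seed = config$seed,
                           fraction = config$fraction, params = params)
    expanded <- expand_dataset(subset, pool, plan)
    write_augmented_dataset(expanded, file.path(out, paste0("expanded_", st)))
  })
  names(manifests) <- strategies

  # --- evaluation ---
  metrics <- NULL
  if (!is.null(config$pred_dir) && !is.null(config$truth_dir)) {
    metrics <- evaluate_masks(config$pred_dir, config$truth_dir,
                              percentile = config$hd_percentile)
    write_metrics_report(metrics, file.path(out, "metrics.csv"))
  }

  log <- unclass(config)
  log$target_size_used <- target
  log$n_labeled_loaded <- nrow(labeled)
  log$subset_ids <- subset$source_id
  log$strategies_run <- strategies
  yaml::write_yaml(log[!purrr::map_lgl(log, is.null)],
                   file.path(out, "run_log.yaml"))

  invisible(list(subset = subset, manifests = manifests, metrics = metrics,
                 out_dir = out))
}
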
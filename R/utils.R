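# Shared internal helpers: rounding, clamping, seeded evaluation, validation.

# Half-up rounding (5% of 414 must give 21, not base R's banker's 20).
round_half_up <- function(x) floor(x + 0.5)

# Half-away-from-zero, used for integer pixel shifts.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# All stochastic code runs under withr::with_seed so results are fully
# determined by the seed argument and the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.", class = "usmix_error")
  }
  withr::with_seed(as.integer(seed), code)
}

stop_usmix <- function(...) abort(paste0(...), class = "usmix_error")

check_gray_image <- function(x, arg = "image", min_dim = 8L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_usmix("`", arg, "` must be a numeric matrix.")
  }
  if (nrow(x) < min_dim || ncol(x) < min_dim) {
    stop_usmix("`", arg, "` must be at least ", min_dim, "x", min_dim,
               " pixels, got ", nrow(x), "x", ncol(x), ".")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_usmix("`", arg, "` contains non-finite values.")
  }
  if (min(x) < 0 || max(x) > 1) {
    stop_usmix("`", arg, "` must lie in [0, 1].")
  }
  invisible(x)
}

check_binary_mask <- function(x, arg = "mask") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_usmix("`", arg, "` must be a numeric matrix.")
  }
  if (!all(x == 0 | x == 1)) {
    stop_usmix("`", arg, "` must contain only 0 and 1.")
  }
  invisible(x)
}

check_same_dim <- function(a, b, what = c("image", "image")) {
  if (!identical(dim(a), dim(b))) {
    stop_usmix("Dimension mismatch: ", what[1], " is ",
               nrow(a), "x", ncol(a), " but ", what[2], " is ",
               nrow(b), "x", ncol(b), ".")
  }
  invisible(TRUE)
}

# Mirror the columns of a matrix (left-right flip).
mirror_lr <- function(x) x[, ncol(x):1, drop = FALSE]
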
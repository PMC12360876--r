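# Fixture builders and independent brute-force oracles. The oracles
# deliberately use explicit per-pixel loops (and their own boundary /
# percentile logic) so they share no code path with the package internals.

rand_image <- function(h = 16, w = 16) matrix(runif(h * w), h, w)

rand_mask <- function(h = 16, w = 16, p = 0.3) {
  matrix(as.numeric(runif(h * w) < p), h, w)
}

rand_labeled <- function(h = 16, w = 16, p = 0.3, id = "t") {
  labeled_sample(rand_image(h, w), rand_mask(h, w, p), source_id = id)
}

# Small lesion phantom pair for invariance sweeps.
phantom_pair <- function(seed, h = 64, w = 64) {
  ds <- make_dataset(1, 1, seed = seed, height = h, width = w,
                     axes_range = c(6, 18))
  list(lab = as_sample(ds$labeled[1, ]), unl = ds$unlabeled$image[[1]])
}

# --- per-pixel loop oracles for the five mixing equations -------------------

oracle_pixmix <- function(il, iu, a, b) {
  out <- matrix(0, nrow(il), ncol(il))
  for (i in seq_len(nrow(il))) for (j in seq_len(ncol(il))) {
    out[i, j] <- a * il[i, j] + b * iu[i, j]
  }
  out
}

oracle_segmix2 <- function(tlp, il, iu, g) {
  out <- matrix(0, nrow(il), ncol(il))
  for (i in seq_len(nrow(il))) for (j in seq_len(ncol(il))) {
    out[i, j] <- (1 - tlp[i, j]) * iu[i, j] +
      tlp[i, j] * (g * il[i, j] + (1 - g) * iu[i, j])
  }
  out
}

oracle_lesionblend <- function(tlp, il, iu) {
  out <- matrix(0, nrow(il), ncol(il))
  for (i in seq_len(nrow(il))) for (j in seq_len(ncol(il))) {
    out[i, j] <- tlp[i, j] * il[i, j] + (1 - tlp[i, j]) * iu[i, j]
  }
  out
}

oracle_lesionblend2 <- function(tlp, il, iu) {
  out <- matrix(0, nrow(il), ncol(il))
  for (i in seq_len(nrow(il))) for (j in seq_len(ncol(il))) {
    out[i, j] <- (1 - tlp[i, j]) * il[i, j] + tlp[i, j] * iu[i, j]
  }
  out
}

oracle_pixmix2 <- function(il, iu) {
  s <- matrix(0, nrow(il), ncol(il))
  for (i in seq_len(nrow(il))) for (j in seq_len(ncol(il))) {
    s[i, j] <- il[i, j] + iu[i, j]
  }
  rng <- max(s) - min(s)
  if (rng == 0) return(matrix(0, nrow(il), ncol(il)))
  (s - min(s)) / rng
}

# Peak of a normalized, truncated (4 sigma) discrete 2-D Gaussian kernel,
# by direct evaluation of the separable product.
oracle_gauss_peak <- function(sigma) {
  r <- max(1, ceiling(4 * sigma))
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w <- w / sum(w)
  max(outer(w, w))
}

# --- metric oracles ---------------------------------------------------------

oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
    else if (pred[i, j] == 1) fp <- fp + 1
    else if (truth[i, j] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Boundary pixels by explicit 4-neighbor inspection (outside = background).
oracle_boundary <- function(mask) {
  pts <- NULL
  h <- nrow(mask); w <- ncol(mask)
  at <- function(i, j) if (i < 1 || i > h || j < 1 || j > w) 0 else mask[i, j]
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] == 1 &&
        (at(i - 1, j) == 0 || at(i + 1, j) == 0 ||
         at(i, j - 1) == 0 || at(i, j + 1) == 0)) {
      pts <- rbind(pts, c(i, j))
    }
  }
  pts
}

# All-pairs directed distances with an explicit ceiling-order-statistic
# percentile, combined by max.
oracle_hd <- function(pred, truth, percentile = 95) {
  ep <- sum(pred) == 0; et <- sum(truth) == 0
  if (ep && et) return(0)
  if (ep || et) return(sqrt(nrow(pred)^2 + ncol(pred)^2))
  a <- oracle_boundary(pred); b <- oracle_boundary(truth)
  mins_ab <- numeric(nrow(a)); mins_ba <- numeric(nrow(b))
  for (i in seq_len(nrow(a))) {
    d <- Inf
    for (j in seq_len(nrow(b))) {
      d <- min(d, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
    mins_ab[i] <- d
  }
  for (j in seq_len(nrow(b))) {
    d <- Inf
    for (i in seq_len(nrow(a))) {
      d <- min(d, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
    mins_ba[j] <- d
  }
  q <- function(x) {
    n <- length(x)
    if (n == 1) return(x)
    sort(x)[min(n, ceiling(percentile / 100 * (n - 1)) + 1)]
  }
  max(q(mins_ab), q(mins_ba))
}

# --- PNG fixture helpers ----------------------------------------------------

# Write an 8-bit grayscale PNG from a matrix of integer byte values 0..255.
write_byte_png <- function(bytes, path) {
  png::writePNG(bytes / 255, target = path)
}

# Build an images/masks directory pair from lists of byte matrices.
make_png_dataset <- function(dir, images, masks) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(images)) {
    write_byte_png(images[[nm]], file.path(dir, "images", paste0(nm, ".png")))
  }
  for (nm in names(masks)) {
    write_byte_png(masks[[nm]], file.path(dir, "masks", paste0(nm, ".png")))
  }
  dir
}
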
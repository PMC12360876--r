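# Subset sampling and the expand-to-full-size protocol.

tiny_dataset <- function(n, h = 8, w = 8) {
  samples_tibble(purrr::map(seq_len(n), function(i) {
    img <- matrix(((i - 1) %% 17) / 16, h, w)
    msk <- matrix(0, h, w); msk[3:4, 3:4] <- 1
    labeled_sample(img, msk, sprintf("s%04d", i))
  }))
}

test_that("sample_subset sizes follow half-up rounding", {
  ds <- tiny_dataset(414)
  expect_equal(nrow(sample_subset(ds, 1.0, seed = 1)), 414L)
  expect_equal(nrow(sample_subset(ds, 0.05, seed = 1)), 21L)
  expect_equal(nrow(sample_subset(ds, 0.10, seed = 1)), 41L)
  expect_equal(nrow(sample_subset(ds, 0.20, seed = 1)), 83L)
  expect_error(sample_subset(ds, 0.0005, seed = 1), "empty subset")
  expect_error(sample_subset(ds, 1.5, seed = 1), "\\(0, 1\\]")
})

test_that("subset draws are seeded and order-independent", {
  ds <- tiny_dataset(50)
  a <- sample_subset(ds, 0.2, seed = 9)
  b <- sample_subset(ds, 0.2, seed = 9)
  expect_identical(a$source_id, b$source_id)
  shuffled <- ds[rev(seq_len(nrow(ds))), ]
  c <- sample_subset(shuffled, 0.2, seed = 9)
  expect_identical(a$source_id, c$source_id)
  expect_false(identical(a$source_id,
                         sample_subset(ds, 0.2, seed = 10)$source_id))
})

test_that("expand_dataset conserves size and provenance", {
  withr::local_seed(1)
  ds <- make_dataset(6, 8, seed = 2, height = 32, width = 32,
                     axes_range = c(4, 9))
  subset <- sample_subset(ds$labeled, 0.5, seed = 4)
  # target equal to subset size: nothing generated
  plan0 <- expansion_plan("pixmix", target_size = nrow(subset), seed = 5)
  expect_identical(expand_dataset(subset, ds$unlabeled, plan0), subset)

  plan <- expansion_plan("pixmix", target_size = 17, seed = 5)
  out <- expand_dataset(subset, ds$unlabeled, plan)
  expect_equal(nrow(out), 17L)
  expect_equal(sum(out$strategy == "original"), nrow(subset))
  expect_equal(sum(out$strategy == "pixmix"), 17L - nrow(subset))
  # the subset appears verbatim at the head of the output
  expect_identical(out[seq_len(nrow(subset)), ], subset)
  # every augmented mask is its labeled source's mask, bit-identical
  aug <- out[out$strategy == "pixmix", ]
  for (i in seq_len(nrow(aug))) {
    src <- subset$mask[[match(aug$labeled_source[i], subset$source_id)]]
    expect_identical(aug$mask[[i]], src)
  }
  # pairing reproducibility
  out2 <- expand_dataset(subset, ds$unlabeled, plan)
  expect_identical(out$unlabeled_source, out2$unlabeled_source)
  expect_error(expand_dataset(subset, ds$unlabeled[0, ], plan), "empty")
})

test_that("counts for the canonical 414-case protocol", {
  ds <- tiny_dataset(414)
  pool <- tibble::tibble(source_id = paste0("u", 1:10),
                         image = rep(list(matrix(0.5, 8, 8)), 10))
  for (cfg in list(c(0.05, 21), c(0.10, 41), c(0.20, 83))) {
    subset <- sample_subset(ds, cfg[1], seed = 1)
    expect_equal(nrow(subset), cfg[2])
    plan <- expansion_plan("lesionblend", target_size = 414, seed = 1,
                           params = mix_params(sigma = 1))
    out <- expand_dataset(subset, pool, plan)
    expect_equal(nrow(out), 414L)
    expect_equal(sum(out$strategy == "lesionblend"), 414L - cfg[2])
  }
})

test_that("labeled images never pair with themselves", {
  ds <- tiny_dataset(6)
  # pool IS the labeled set with masks hidden (the remainder convention,
  # here overlapping fully to stress the guard)
  pool <- tibble::tibble(source_id = ds$source_id, image = ds$image)
  plan <- expansion_plan("pixmix", target_size = 60, seed = 3)
  out <- expand_dataset(ds, pool, plan)
  aug <- out[out$strategy == "pixmix", ]
  expect_true(all(aug$unlabeled_source != aug$labeled_source))
})

test_that("round-robin spreads labeled sources nearly equally", {
  ds <- tiny_dataset(5)
  pool <- tibble::tibble(source_id = "u1", image = list(matrix(0.2, 8, 8)))
  plan <- expansion_plan("pixmix", target_size = 22, seed = 1)
  out <- expand_dataset(ds, pool, plan)
  counts <- table(out$labeled_source[out$strategy == "pixmix"])
  expect_lte(max(counts) - min(counts), 1)
})

test_that("alpha sweep shares pairings and differs by exact algebra", {
  ds <- make_dataset(4, 6, seed = 11, height = 32, width = 32,
                     axes_range = c(4, 9))
  subset <- sample_subset(ds$labeled, 0.5, seed = 2)
  sw <- run_alpha_beta_sweep(subset, ds$unlabeled, alphas = c(0.6, 0.7, 0.8),
                             seed = 6, target_size = 12)
  expect_equal(nrow(sw), 3L)
  # single-alpha sweep reproduces a plain expansion
  single <- run_alpha_beta_sweep(subset, ds$unlabeled, alphas = 0.8,
                                 seed = 6, target_size = 12)
  plan <- expansion_plan("pixmix", target_size = 12, seed = 6,
                         params = mix_params(alpha = 0.8))
  expect_identical(single$dataset[[1]],
                   expand_dataset(subset, ds$unlabeled, plan))
  # identical pairings across settings
  expect_identical(sw$dataset[[1]]$unlabeled_source,
                   sw$dataset[[3]]$unlabeled_source)
  # per-pixel difference between alpha = 0.6 and 0.8 equals 0.2 (I_L - I_U)
  d06 <- sw$dataset[[1]]; d08 <- sw$dataset[[3]]
  gen <- which(d06$strategy == "pixmix")
  for (i in gen) {
    il <- subset$image[[match(d06$labeled_source[i], subset$source_id)]]
    iu <- ds$unlabeled$image[[match(d06$unlabeled_source[i],
                                    ds$unlabeled$source_id)]]
    expect_equal(d08$image[[i]] - d06$image[[i]], 0.2 * (il - iu),
                 tolerance = 1e-12)
  }
  expect_error(run_alpha_beta_sweep(subset, ds$unlabeled, alphas = c(0, 0.5),
                                    seed = 1, target_size = 12),
               "strictly")
})
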
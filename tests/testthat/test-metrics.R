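# Dice, Jaccard, boundary extraction and HD95 against brute-force oracles.

test_that("confusion counts match a per-pixel oracle", {
  m <- rand_mask(4, 4)
  cc <- confusion(m, m)
  expect_equal(cc$tp, sum(m))
  expect_equal(cc$fp + cc$fn, 0)
  cc2 <- confusion(matrix(1, 4, 4), matrix(0, 4, 4))
  expect_equal(cc2$fp, 16)
  withr::local_seed(8)
  for (rep in 1:20) {
    p <- rand_mask(8, 8); t <- rand_mask(8, 8)
    got <- confusion(p, t)
    want <- oracle_confusion(p, t)
    expect_equal(unlist(got), want)
    expect_equal(sum(unlist(got)), 64)
  }
  expect_error(confusion(rand_mask(4, 4), rand_mask(5, 5)), "mismatch")
})

test_that("jaccard and dice follow their closed forms", {
  counts <- list(tp = 2, fp = 1, fn = 1)
  expect_equal(jaccard(counts), 2 / (2 + 1 + 1))
  expect_equal(dice(counts), 2 * 2 / (2 * 2 + 1 + 1))
  m <- rand_mask(6, 6, p = 0.5)
  expect_equal(jaccard(confusion(m, m)), 1)
  expect_equal(dice(confusion(m, m)), 1)
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(jaccard(confusion(a, b)), 0)
  expect_warning(j0 <- jaccard(confusion(matrix(0, 4, 4), matrix(0, 4, 4))),
                 "empty")
  expect_equal(j0, 1)
})

test_that("dice equals 2J/(1+J) on random pairs; dice >= jaccard", {
  withr::local_seed(9)
  for (rep in 1:100) {
    cc <- confusion(rand_mask(8, 8), rand_mask(8, 8))
    j <- jaccard(cc); d <- dice(cc)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-14)
    expect_gte(d, j)
  }
})

test_that("boundary extraction is mask minus 4-connected erosion", {
  m <- matrix(0, 8, 8); m[3, 5] <- 1
  b <- extract_boundary(m)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$row, b$col), c(3L, 5L))
  # filled 3x3 square: erosion keeps only the center, 8 perimeter pixels
  sq <- matrix(0, 9, 9); sq[4:6, 4:6] <- 1
  expect_equal(nrow(extract_boundary(sq)), 8L)
  # full-frame mask: only frame-border pixels survive
  full <- matrix(1, 6, 7)
  bf <- extract_boundary(full)
  expect_equal(nrow(bf), 2 * 6 + 2 * 7 - 4)
  expect_true(all(bf$row %in% c(1, 6) | bf$col %in% c(1, 7)))
  expect_error(extract_boundary(matrix(0, 4, 4)), "empty")
  # agreement with the loop oracle on random masks
  withr::local_seed(10)
  for (rep in 1:10) {
    m <- rand_mask(10, 10, 0.4)
    if (sum(m) == 0) next
    got <- as.matrix(extract_boundary(m))
    want <- oracle_boundary(m)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2]), , drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("hd95 matches the all-pairs oracle and its axioms", {
  m <- rand_mask(8, 8, 0.4)
  expect_equal(hd95(m, m), 0)
  # two single pixels at (0,0) and (3,4) offsets: Euclidean distance 5
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1
  expect_equal(hd95(a, b), 5.0)
  expect_equal(hd95(a, b, percentile = 100), 5.0)
  withr::local_seed(12)
  for (rep in 1:30) {
    p <- rand_mask(12, 12, 0.2); t <- rand_mask(12, 12, 0.2)
    got <- hd95(p, t)
    expect_equal(got, oracle_hd(p, t), label = paste("rep", rep))
    expect_equal(got, hd95(t, p))                       # symmetry
    expect_equal(hd95(p, t, 100), oracle_hd(p, t, 100))
  }
})

test_that("hd95 is translation invariant away from the frame", {
  withr::local_seed(13)
  p <- matrix(0, 20, 20); p[5:8, 5:7] <- 1
  t <- matrix(0, 20, 20); t[6:10, 6:9] <- 1
  base <- hd95(p, t)
  sh <- function(x) usmix:::shift_matrix(x, 4, 5)
  expect_equal(hd95(sh(p), sh(t)), base)
})

test_that("empty-mask policy: diagonal penalty, zero for both empty", {
  e <- matrix(0, 6, 8)
  m <- matrix(0, 6, 8); m[3, 3] <- 1
  expect_equal(hd95(e, m), sqrt(6^2 + 8^2))
  expect_equal(hd95(m, e), sqrt(6^2 + 8^2))
  expect_equal(hd95(e, e), 0)
})

test_that("evaluate_masks reports per-image rows with summary methods", {
  dir <- withr::local_tempdir()
  truth_dir <- file.path(dir, "truth"); pred_dir <- file.path(dir, "pred")
  dir.create(truth_dir); dir.create(pred_dir)
  withr::local_seed(14)
  for (i in 1:4) {
    t <- matrix(0, 16, 16); t[4:9, 4:9] <- 1
    p <- usmix:::shift_matrix(t, i %% 3, 0)
    write_byte_png(t * 255, file.path(truth_dir, sprintf("c%d.png", i)))
    write_byte_png(p * 255, file.path(pred_dir, sprintf("c%d.png", i)))
  }
  write_byte_png(matrix(0, 16, 16), file.path(truth_dir, "empty.png"))
  write_byte_png(matrix(0, 16, 16), file.path(pred_dir, "empty.png"))
  rep <- evaluate_masks(pred_dir, truth_dir)
  expect_s3_class(rep, "us_metrics")
  expect_equal(nrow(rep), 5L)
  expect_true(all(rep$jaccard <= rep$dice))
  expect_true(rep$empty_flag[rep$stem == "empty"])
  g <- glance(rep)
  expect_equal(g$n, 5L)
  expect_equal(g$mean_dice, mean(rep$dice))
  td <- tidy(rep)
  expect_false(inherits(td, "us_metrics"))
  out_csv <- file.path(dir, "report.csv")
  write_metrics_report(rep, out_csv)
  body <- readr::read_csv(out_csv, show_col_types = FALSE)
  expect_equal(nrow(body), 7L)   # 5 rows + mean + stdev footer
  expect_equal(body$stem[6:7], c("mean", "stdev"))
})

test_that("a phantom's own mask evaluates to perfect scores", {
  ds <- make_dataset(2, 0, seed = 21, height = 48, width = 48,
                     axes_range = c(5, 12))
  rep <- evaluate_masks(
    tibble::tibble(source_id = ds$labeled$source_id, mask = ds$labeled$mask),
    tibble::tibble(source_id = ds$labeled$source_id, mask = ds$labeled$mask)
  )
  expect_true(all(rep$jaccard == 1 & rep$dice == 1 & rep$hd95 == 0))
})
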
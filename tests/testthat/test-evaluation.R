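test_that("k-fold assignment partitions rows with near-equal sizes", {
  fold <- kfold_assign(8133, k = 10, seed = 1)
  sizes <- as.integer(table(fold))
  expect_identical(sort(sizes), c(rep(813L, 7), rep(814L, 3)))
  expect_identical(sort(unique(fold)), 1:10)
  # n = k: one row per fold
  expect_identical(sort(as.integer(table(kfold_assign(10, 10, 2)))),
                   rep(1L, 10))
  # reproducible, and different under another seed
  expect_identical(kfold_assign(500, 10, 42), kfold_assign(500, 10, 42))
  expect_false(identical(kfold_assign(500, 10, 42), kfold_assign(500, 10, 43)))
  expect_error(kfold_assign(5, 10), "n >= k")
})

make_feature_table <- function(n, seed = 1, cases = 4) {
  set.seed(seed)
  tab <- data.frame(
    case_id = sprintf("case%02d", rep_len(seq_len(cases), n)),
    segment_id = sprintf("s%04d", seq_len(n)),
    area = runif(n, 0.15, 0.35), rising_time = runif(n, 0.15, 0.35),
    width_25 = runif(n, 0.25, 0.45), stringsAsFactors = FALSE)
  tab$width_50 <- tab$width_25 * 0.7
  tab$width_75 <- tab$width_25 * 0.5
  tab
}

test_that("cross-validation generalizes a noiseless linear rule", {
  tab <- make_feature_table(120)
  tab$ref_sbp <- 90 + 40 * tab$area + 30 * tab$rising_time - 20 * tab$width_25
  tab$ref_dbp <- 50 + 20 * tab$area + 10 * tab$width_25
  rec <- cross_validate(tab, model = "mlr", k = 10, seed = 3)
  expect_true(all(abs(rec$ref_sbp - rec$est_sbp) <= 1e-6))
  expect_true(all(abs(rec$ref_dbp - rec$est_dbp) <= 1e-6))
  # every segment appears exactly once with a fold label
  expect_identical(sort(rec$segment_id), sort(tab$segment_id))
  expect_identical(sort(unique(rec$fold)), 1:10)
})

test_that("leave-one-out is the k = n special case", {
  tab <- make_feature_table(12)
  tab$ref_sbp <- 100 + 30 * tab$area
  tab$ref_dbp <- 60 + 10 * tab$width_25
  rec <- cross_validate(tab, model = "mlr", k = 12, seed = 5)
  expect_identical(as.integer(table(rec$fold)), rep(1L, 12))
})

test_that("cross-validation refuses segments without references", {
  tab <- make_feature_table(30)
  tab$ref_sbp <- 100
  tab$ref_dbp <- c(NA, rep(60, 29))
  expect_error(cross_validate(tab), "without reference")
})

test_that("category classification reproduces published case examples", {
  expect_identical(classify_category(188.7, 79.1), "hypertensive")
  expect_identical(classify_category(84.6, 49.3), "hypotensive")
  expect_identical(classify_category(109.4, 59.8), "normotensive")
  # diastolic hypertension alone is enough
  expect_identical(classify_category(120, 95), "hypertensive")
  # boundary behaviour: at the threshold is hypertensive; below hypo bound
  expect_identical(classify_category(140, 70), "hypertensive")
  expect_identical(classify_category(89.99, 60), "hypotensive")
  expect_identical(classify_category(90, 60), "normotensive")
  expect_error(classify_category(NA, 60), "finite")
})

test_that("per-case summaries average qualifying segments", {
  rec <- data.frame(
    case_id = c("c1", "c1", "c2"), segment_id = c("s1", "s2", "s3"),
    ref_sbp = c(100, 110, 130), ref_dbp = c(60, 70, 85),
    est_sbp = c(95, 115, 120), est_dbp = c(58, 75, 80),
    fold = 1L, ref_category = c("normotensive", "normotensive",
                                "normotensive"),
    stringsAsFactors = FALSE)
  cs <- per_case_summary(rec)
  expect_identical(cs$case_id, c("c1", "c2"))
  expect_equal(cs$ref_sbp, c(105, 130))
  expect_equal(cs$diff_sbp, c(105 - 105, 10))
  one <- per_case_summary(rec[3, ])
  expect_equal(one$ref_dbp, 85)
  expect_equal(one$diff_dbp, 5)
})

test_that("category case-counts add up to the unfiltered counts", {
  ds <- default_dataset()
  tt <- truth_table(ds)
  rec <- data.frame(case_id = tt$case_id, segment_id = tt$segment_id,
                    ref_sbp = tt$true_sbp, ref_dbp = tt$true_dbp,
                    est_sbp = tt$true_sbp, est_dbp = tt$true_dbp,
                    fold = 1L, ref_category = tt$true_category,
                    stringsAsFactors = FALSE)
  all_cases <- per_case_summary(rec)
  split_counts <- lapply(c("normotensive", "hypertensive", "hypotensive"),
                         function(cat) per_case_summary(rec, cat))
  # each case's per-category segment counts sum to its total
  for (cid in all_cases$case_id) {
    total <- all_cases$n_segments[all_cases$case_id == cid]
    parts <- vapply(split_counts, function(cs) {
      k <- cs$n_segments[cs$case_id == cid]
      if (length(k)) k else 0L
    }, integer(1))
    expect_identical(sum(parts), total)
  }
})

test_that("difference statistics follow their closed forms", {
  expect_equal(unname(difference_stats(c(0, 0, 0))), c(0, 0))
  d <- 3.7
  st <- difference_stats(c(d, -d))
  expect_equal(st[["mean"]], 0)
  expect_equal(st[["sd"]], d * sqrt(2), tolerance = 1e-12)
  expect_error(difference_stats(5), "at least 2")
})

test_that("Bland-Altman limits are bias +/- 1.96 sd exactly", {
  expect_equal(unname(bland_altman(c(0, 0, 0))), c(0, 0, 0))
  d <- 2.5
  ba <- bland_altman(c(d, -d))
  expect_equal(ba[["upper"]], 1.96 * sqrt(2) * d, tolerance = 1e-12)
  expect_equal(ba[["lower"]], -1.96 * sqrt(2) * d, tolerance = 1e-12)
  set.seed(30)
  x <- rnorm(25, 1, 4)
  ba2 <- bland_altman(x)
  st <- difference_stats(x)
  expect_equal(ba2[["bias"]], st[["mean"]], tolerance = 1e-12)
  expect_equal(ba2[["upper"]] - ba2[["lower"]], 2 * 1.96 * st[["sd"]],
               tolerance = 1e-12)
})

test_that("the ISO verdict is inclusive at its boundaries and monotone", {
  expect_true(iso_check(-0.1, 6.5))
  expect_false(iso_check(21.0, 12.9))
  expect_true(iso_check(5.0, 8.0))
  expect_true(iso_check(-5.0, 8.0))
  expect_false(iso_check(5.01, 8.0))
  expect_false(iso_check(0, 8.01))
  # monotonicity: shrinking |mean| or sd never flips pass -> fail
  set.seed(31)
  for (k in 1:20) {
    m <- runif(1, -8, 8); s <- runif(1, 0, 12)
    if (iso_check(m, s)) {
      expect_true(iso_check(m / 2, s))
      expect_true(iso_check(m, s / 2))
    }
  }
})

test_that("category reports stratify by reference category", {
  ds <- default_dataset()
  tt <- truth_table(ds)
  rec <- data.frame(case_id = tt$case_id, segment_id = tt$segment_id,
                    ref_sbp = tt$true_sbp, ref_dbp = tt$true_dbp,
                    est_sbp = tt$true_sbp + 1, est_dbp = tt$true_dbp - 1,
                    fold = 1L, ref_category = tt$true_category,
                    stringsAsFactors = FALSE)
  rep <- category_report(rec)
  expect_setequal(unique(rep$category),
                  c("overall", "normotensive", "hypertensive", "hypotensive"))
  ov <- rep[rep$category == "overall" & rep$target == "SBP", ]
  expect_equal(ov$mean_diff, -1, tolerance = 1e-9)
  expect_equal(ov$sd_diff, 0, tolerance = 1e-9)
  expect_true(ov$iso_pass)
  # a records set with a single category leaves the others empty
  normo <- rec[rec$ref_category == "normotensive", ]
  rep_n <- category_report(normo)
  hyper_row <- rep_n[rep_n$category == "hypertensive" & rep_n$target == "SBP", ]
  expect_identical(hyper_row$n_cases, 0L)
  expect_true(is.na(hyper_row$sd_diff))
})

test_that("overall means equal a brute-force recomputation from records", {
  ds <- default_dataset()
  tt <- truth_table(ds)
  set.seed(33)
  rec <- data.frame(case_id = tt$case_id, segment_id = tt$segment_id,
                    ref_sbp = tt$true_sbp, ref_dbp = tt$true_dbp,
                    est_sbp = tt$true_sbp + rnorm(nrow(tt), 0, 3),
                    est_dbp = tt$true_dbp + rnorm(nrow(tt), 0, 3),
                    fold = 1L, ref_category = tt$true_category,
                    stringsAsFactors = FALSE)
  rep <- category_report(rec)
  ov <- rep[rep$category == "overall" & rep$target == "SBP", ]
  brute <- vapply(split(rec, rec$case_id),
                  function(g) mean(g$ref_sbp) - mean(g$est_sbp), numeric(1))
  expect_equal(ov$mean_diff, mean(brute), tolerance = 1e-12)
  expect_equal(ov$sd_diff, sd(brute), tolerance = 1e-12)
})

test_that("display rounding is half away from zero at one decimal", {
  expect_identical(round_half_away(c(0.05, -0.05, 2.45, -2.45)),
                   c(0.1, -0.1, 2.5, -2.5))
  expect_identical(round_half_away(21.04), 21.0)
})
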